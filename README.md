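# alpulse

Spiking-network simulation of pulse tracking in the moth antennal lobe
(AL), with the analyses needed to quantify it.

Flying moths encounter odors as brief, wind-borne filaments, so the AL —
the first olfactory relay, organized into glomeruli of excitatory
projection neurons (PNs) and inhibitory local neurons (LNs) — must
resolve both the duration of single odor pulses and the frequency of
pulse trains, while simultaneously receiving mechanosensory excitation
from the air flow itself. `alpulse` implements a six-glomerulus
conductance-based integrate-and-fire model of this circuit (10 PNs +
6 LNs per glomerulus) with:

* fast excitatory, fast inhibitory (GABA-A-like), slow inhibitory
  (GABA-B-like, τ = 750 ms) synaptic currents, all exponential-kernel
  conductances, and a spike-triggered SK-type auto-inhibitory potassium
  current in PNs with a sigmoidal 25 ms half-rise and 250 ms decay;
* inhomogeneous Poisson external input: background drive everywhere
  (λ = 3.6 spikes/ms), focal odor drive to selected glomeruli (peak
  3.6 spikes/ms) and weak global mechanosensory drive (peak
  1.8 spikes/ms), with class-specific rise envelopes and a 384 ms decay;
* the three stimulus scenarios — odor only, mechanosensory only, and
  their literal sum ("additive", odor in a high-wind puff) — plus a
  graded odor-tuning paradigm;
* the four analysis metrics: **response length** (3×-ISI truncation
  rule), **response slope** (OLS of response length on pulse length;
  1 = faithful duration coding), **pulse-following index**
  (autocorrelation at the pulse period minus autocorrelation at the
  pulse-end lag, on 5 ms bins), and **pulse-following rate** (highest
  frequency with trial-mean index ≥ 0.05 — a low-pass cutoff);
* experiment drivers reproducing the in-silico protocols: pulse-length
  sweeps, conductance-strength sweeps (SK / fast / slow inhibition),
  pulse-frequency sweeps, graded odor tuning, and the post-train
  suppression (AHP) measurement.

The dynamics integrate by forward Euler at Δt = 0.1 ms with exact
exponential conductance decay; the 96-neuron network runs at roughly
15× real time on one core, so 50-trial sweeps are minutes, not hours.

## Worked example

```r
library(alpulse)

net <- al_network(seed = 1)          # frozen random wiring + SK strengths
net
#> Antennal lobe network: 60 PN + 36 LN in 6 glomeruli (seed 1, SK gaussian)
#>   synapses: LN_LN=40, LN_PN=851, PN_LN=278, PN_PN=407

# a 4 Hz train of 50 ms pulses, odor to glomeruli 1-3 plus global mech input
sched <- pulse_train(freq_hz = 4, n_pulses = 8, pulse_ms = 50, t_start = 500)
sim <- al_simulate(net, stim_protocol("additive", sched, duration = 5000),
                   stim_seed = 7)
sim
#> Antennal lobe simulation: 5000 ms at dt = 0.1 ms (additive)
#>   11240 spikes (5139 PN, 6101 LN); seeds: network 1, stimulus 7
plot(sim, schedule = sched)          # raster, pulses marked

# how well does a representative odor-receiving PN follow the train?
pulse_following_index(spike_times(sim, probe_neuron(net, "odor")), sched)
#> [1] 0.1103618

# frequency sweep: cutoff frequencies of the two standard probes
freq <- run_frequency_experiment(net, "additive", freqs = 1:10,
                                 n_trials = 20)
freq$rate
#>     odor non_odor
#>        7       10
```

The last line is the model's central contrast: under combined odor +
mechanosensory drive, a strongly (odor-)driven PN stops following pulse
trains at a lower frequency than a weakly (mechanosensorily) driven PN
in a non-odor glomerulus — strong focal drive favors duration coding,
weak global drive favors frequency tracking. At the full 50-trial study
conditions (the reproduction script below) the odor-receiving cutoff
lands at 4–6 Hz against ≥ 8–9 Hz for the non-odor probe.

The index itself is dimensionless: values around 0.1 mean a clearly
pulse-locked raster at that frequency; values at or below the 0.05
cutoff are
indistinguishable from tonic or Poisson firing (the suite verifies the
cutoff sits well above the metric's noise floor on synthetic rasters).

## Command-line use

A thin CLI over the same functions lives at `inst/cli/alpulse.R`
(`simulate`, `length-sweep`, `conductance-sweep`, `freq-sweep`,
`graded-odor`), driven by a YAML config whose keys mirror `al_params()`;
it writes plain CSV tables plus the resolved config:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/alpulse.R", package="alpulse"))')" \
    freq-sweep --config run.yaml --out results/
```

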