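---
title: "Modelling pulse tracking in the moth antennal lobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pulse tracking in the moth antennal lobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpulse)
```

## The scientific problem

Flying insects meet odors as brief, turbulence-fragmented filaments riding
on gusts of wind. Successful plume tracking therefore requires the early
olfactory circuit — the antennal lobe (AL) — to resolve two distinct
temporal features of a stimulus: the *duration* of a single odor pulse
(odor strands are larger near the source) and the *frequency* of a train
of brief pulses (encounter rate also grows toward the source). High-speed
air flow itself excites AL neurons mechanosensorily, so odor arriving in
a wind puff drives the circuit through two channels at once.

`alpulse` implements a spiking circuit model of the moth AL built to study
exactly this question: six glomeruli, each containing 10 excitatory
projection neurons (PNs) and 6 inhibitory local neurons (LNs), with
conductance-based integrate-and-fire dynamics, fast (GABA-A-like) and slow
(GABA-B-like) inhibition, a spike-triggered SK-type auto-inhibitory
potassium current in PNs, and external drive modelled as inhomogeneous
Poisson input spike trains. On top of the simulator it implements the
pulse-tracking analyses used to characterize the model: response length,
response slope, the autocorrelation-based pulse-following index, and the
pulse-following rate.

## The neuron and synapse model

Each neuron's nondimensional membrane potential relaxes toward the leak
potential $V_L = 0$ with time constant $\tau_V = 20$ ms and is driven by
conductance terms $-g_x(t)\,(V - V_x)$ with excitatory/stimulus reversal
$V_{exc} = V_{stim} = 14/3$ and inhibitory/SK reversal
$V_{inh} = V_{SK} = -2/3$. Crossing the threshold $V_{thres} = 1$ emits a
spike and pins the potential at $V_L$ for the 2 ms refractory period.

Every synaptic and stimulus conductance is a sum of unit-integral
exponential kernels $\alpha(t) = H(t)\,\tau^{-1} e^{-t/\tau}$ over the
relevant presynaptic (or external) spike times, weighted by a coupling
strength $S$ chosen by the postsynaptic cell class:

| pathway | $S$ onto PN | $S$ onto LN | $\tau$ (ms) |
|---|---|---|---|
| PN excitation (nicotinic) | 0.01 | 0.006 | 2 |
| LN fast inhibition (GABA-A-like) | 0.0169 | 0.015 | 2 |
| LN slow inhibition (GABA-B-like) | 0.0338 | 0.04 | 750 |
| external stimulus | 0.004 | 0.0031 | 2 |

The SK current exists only in PNs. Its kernel rises sigmoidally —
$\beta(t) = H(t)\,\tau_{SK}^{-1}\,
\mathrm{logistic}\!\big(5 (t - \tau_{rise})/\tau_{rise}\big)$ for
$t \le 2\tau_{rise}$ with $\tau_{rise} = 25$ ms — then decays as
$\tau_{SK}^{-1} e^{-(t - 2\tau_{rise})/\tau_{SK}}$ with
$\tau_{SK} = 250$ ms. The sigmoidal rise lets a PN fire several spikes
before its own activity silences it. The kernel is evaluated exactly as
defined, including its small discontinuity at $2\tau_{rise}$ (the sigmoid
reaches $0.9933/\tau_{SK}$, the exponential branch starts at
$1/\tau_{SK}$). Per-PN SK strengths are drawn once from
$\mathcal{N}(0.5,\,0.2)$ and clamped at zero (negative draws occur with
probability $\Phi(-2.5) \approx 0.006$); a fixed-SK network variant gives
every PN the Gaussian mean, and is the baseline for SK strength sweeps.

## Network architecture

Within a glomerulus, ordered cell pairs connect independently with
probabilities 0.75 (PN→PN), 0.75 (PN→LN), 0.38 (LN→PN) and 0.25 (LN→LN);
across glomeruli only LN→PN synapses exist, at probability 0.38. Autapses
are excluded — the convention for dense random circuits; at these
probabilities their inclusion would be negligible anyway. Synapses are
boolean (per-class strengths, no per-edge weight jitter). A network is a
pure function of `(params, seed)` and is frozen after construction.

## Stimulus model

Every cell receives background Poisson input at
$\lambda_{back} = 3.6$ spikes/ms. A stimulus pulse adds odor input (peak
$\lambda_{odor} = 3.6$ spikes/ms, delivered to the glomeruli selected by
the per-glomerulus gain vector) and/or mechanosensory input (peak
$\lambda_{mech} = 1.8$ spikes/ms, delivered everywhere). Odor is focal
and strong; mechanosensory input is global and weak — that asymmetry is
the heart of the model. The three scenarios are `odor_only`, `mech_only`,
and `additive` (the literal sum of both pulse drives, simulating odor in
a high-wind puff). The standard odor targets glomeruli 1–3 at gain 1; the
graded paradigm spreads gains (0, 0.2, 0.4, 0.6, 0.8, 1) over glomeruli
1–6, keeping the total odor drive equal to the standard paradigm's.

Each pulse contributes temporal envelopes $O(t)$, $M(t) \in [0, 1]$:
sigmoidal or instantaneous rise depending on the pathway (odor→PN
half-rise 35 ms, odor→LN instantaneous; mech→PN instantaneous, mech→LN
half-rise 300 ms) and a common exponential decay with
$\tau_{decay} = 384$ ms referenced to the pulse offset. Envelope tails
from earlier pulses persist and superpose — the total rate sums over all
scheduled pulses.

Two consequences of the printed piecewise envelope deserve emphasis,
because both shape the results:

* **Branch order for short pulses.** The branches are evaluated in their
  stated order: sigmoid while $t \le t_{on} + 2\tau_{rise}$, plateau
  while $t \le t_{off}$, decay afterwards. For a 50 ms pulse the
  mech→LN sigmoid (600 ms window) outlasts the pulse, so LNs keep
  charging long after each brief pulse ends — a train of brief
  mechanosensory pulses is thereby integrated into sustained slow
  inhibition. This is precisely the mechanism that lets weakly-driven
  PNs produce brief, sharply truncated responses that track fast trains.
  The alternative reading (decay from the value attained at offset) was
  implemented and evaluated during development: it yields a
  pulse-length-dependent LN buildup that reproduces the negative
  mechanosensory response slope at zero SK strength (and hence an
  interior maximum in the additive slope-versus-SK curve), but it
  destroys every pulse-train separation between scenarios. One
  definition had to govern both experiment families; the literal branch
  order was chosen because it is what the printed formula computes and
  because the pulse-train results are the model's primary claims. The
  known cost, visible in `run_conductance_sweep("SK", "slope", scenario
  = "additive")`, is that the additive slope curve declines
  monotonically instead of peaking at moderate SK strength.
* **Poisson counts per bin.** Input trains are realized on the
  integration grid: per 0.1 ms bin a Poisson count with mean
  $\lambda(t)\,\Delta t$ (counts, not a Bernoulli flag — peak drive
  reaches $\lambda \Delta t \approx 0.9$), all of a bin's events applied
  at that step.

## Numerical scheme

The membrane equation advances by plain forward Euler at
$\Delta t = 0.1$ ms. Conductance states are stored as single decaying
accumulators: per step they shrink by the exact factor $e^{-\Delta t/\tau}$
(unconditionally stable, and identical to the kernel sum at machine
precision) and each event adds its jump $S/\tau$. The SK conductance,
whose kernel is not exponential, is handled exactly without truncation:
own spikes younger than $2\tau_{rise}$ are evaluated on a precomputed
sigmoid table, and each spike crossing that age is folded into a single
exponential tail accumulator — beyond $2\tau_{rise}$ the kernel *is* a
pure exponential, so this is algebraically exact, which the test suite
verifies against literal kernel sums at $10^{-10}$ tolerance.

Event timing is fixed by three conventions (all covered by tests):
external events in bin $k$ act on step $k$'s membrane update; a spike
fired at step $k$ reaches postsynaptic conductances at step $k+1$ (one
step of synaptic latency, which removes any dependence on within-step
neuron order); a PN's own spike enters its SK sum from the next step.
Threshold crossings are detected at the end-of-step value with no
sub-step interpolation, consistent with plain Euler.

## The analysis metrics

**Response length** (single pulses): among spikes from stimulus onset,
the response ends at the spike preceding the first interspike interval
exceeding three times the mean of the first three intervals; the length
is end minus first spike. Trains with fewer than four spikes fall back to
last-minus-first (zero for at most one spike) so sweeps remain defined as
responses fade. **Response slope** is the OLS slope of response length
against pulse length: one means faithful duration encoding, zero means
none.

**Pulse-following index**: spikes from the first pulse onset over
`n_pulses` periods are binned at 5 ms; the mean-subtracted,
coefficient-normalized autocorrelation is computed (`stats::acf`); the
index is the ACF at the pulse inception-to-inception lag (the period)
minus the ACF at the lag of the first pulse's end (the pulse duration),
each averaged over bins within one bin width, floored at zero. The
trough lag is what gives the metric its discriminative power: a brief
burst that ends with the pulse leaves the pulse-end lag anticorrelated,
while a response that outlasts the pulse — and at high frequency fuses
into tonic firing — raises it. Structureless rasters (homogeneous
Poisson, regular tonic firing) score near zero without bias, so the
fixed 0.05 cutoff separates locking from sampling noise; this was the
deciding constraint among several autocorrelation operationalizations
evaluated against synthetic rasters during development (window extremes,
for instance, are positively biased by roughly 0.16 on Poisson rasters
and were rejected). Known artifact: at 1–2 Hz (few pulses per train,
responses long relative to the pulse) the mean index of a tracking PN
can dip below the cutoff; the pulse-following rate, being the *highest*
frequency at or above cutoff, is unaffected.

**Pulse-following rate**: the highest tested frequency whose trial-mean
index is at or above the 0.05 cutoff (ties count as following), with 0
when none is — a low-pass cutoff frequency for pulse tracking.

**AHP duration**: after an odor pulse train, the slow inhibitory
conductance (built up by LN firing over the train) outlives the decaying
stimulus tail and suppresses PN firing below baseline. The experiment
measures, on the 200 ms sliding-window trial-averaged rate of the probe
PN, the time from final pulse offset until the rate — having fallen
below half its pre-stimulus baseline — sustainably (≥ 300 ms) recovers
above half baseline. Half-baseline is used because the recovery is
asymptotic (the slow conductance decays exponentially), which makes the
literal full-baseline crossing ill-posed: it lands 1–1.5 s after the
suppression epoch has visibly ended. Both durations are returned
(`suppression_ms`, `full_recovery_ms`). The baseline itself is estimated
from the later pre-stimulus window, past the burn-in transient of the
slow conductances (which start at zero).

## Experiment defaults and problem sizes

Grids not printed in the source literature are declared here once:
pulse lengths 25–500 ms in 25 ms steps; pulse frequencies 1–12 Hz in
1 Hz steps; conductance multipliers 0–3 in 0.25 steps; pulse trains fill
a 3000 ms window (so every frequency ≥ 1 Hz yields ≥ 3 pulses) preceded
by 500 ms of baseline and followed by 1500 ms of recording; 50 trials
per condition with the structural seed fixed and a fresh stimulus seed
per trial. The standard probes are a *representative* PN of glomerulus 1
(odor-receiving) and of glomerulus 4 (non-odor): per-PN SK strengths and
LN in-degrees are heterogeneous and both control tracking (weak-SK or
under-inhibited cells fire continuously and track poorly), so the probe
is the PN nearest the glomerulus medians of those two quantities — a
deterministic stand-in for the "representative cell" of a physiology
figure, stable across network seeds. The graded paradigm pools the 10
PNs of each glomerulus before binning.

The bundled reproduction script (`scripts/acceptance.R`) runs the full
50-trial conditions. The test suite exercises the same experiments at
reduced sizes chosen as the package's own testing conditions — 10–30
trials, coarser grids (e.g. frequencies {3, 7} Hz, pulse lengths
100–500 ms in 100 ms steps, SK multipliers {0.25, 1, 2.5}) — which keeps
the default `R CMD check`-style run short while still resolving each
effect well beyond its trial-to-trial noise.

## What the model reproduces, and known limitations

At standard strengths the model shows: sparse baseline activity;
per-pulse PN bursts with an onset inhibitory dip; approximately linear
growth of response length with pulse length for odor-driven PNs (slope
near one at weak SK, declining toward zero as SK strengthens) and flat
response curves for mechanosensory drive; a low pulse-following cutoff
(~4–5 Hz) for odor-driven PNs against tracking beyond 8 Hz for PNs
driven by mechanosensory input alone; improved frequency tracking with
stronger SK or slow inhibition; and a roughly one-second post-train
suppression of PN firing. In the graded paradigm with mechanosensory
input the pulse-following rate declines from the least to the most
odor-driven glomerulus.

Honest caveats, all traceable to documented design choices above:

* The additive slope-versus-SK curve lacks the interior maximum that the
  alternative envelope reading produces; it declines monotonically.
* Several representative-PN indices sit within about one standard error
  of the 0.05 cutoff at 50 trials — the odor-only index at 7 Hz
  (~0.045–0.05, should fail the cutoff), the mech-only index at 3 Hz
  (~0.045, should pass it) and the non-odor additive index at 8 Hz
  (~0.05) — so dichotomous claims at exactly those frequencies can flip
  between seed blocks. The separations all have the expected sign, but
  they are compressed relative to the source model's figures.
* Strong fast inhibition (multiplier 3) truncates responses without
  collapsing the measured pulse-following rate in this implementation.
* In the graded odor-only paradigm several glomeruli saturate the tested
  frequency grid, so the per-glomerulus rate profile is flat at the top
  rather than single-peaked.

The synthetic-raster generator (`make_synthetic_raster`) emulates only
the statistical structure the metrics respond to — pulse-locked bursts,
tonic regular firing, homogeneous Poisson noise — not biophysical spike
patterns; tests built on it validate the metrics, not the circuit. And
the circuit model itself deliberately omits ORN transduction dynamics,
multiglomerular PNs, centrifugal feedback, synaptic plasticity and gap
junctions: it is a minimal architecture for studying how focal odor
drive, global weak mechanosensory drive, and three inhibitory currents
shape temporal stimulus encoding.

## A worked example

```{r example, eval = FALSE}
net <- al_network(seed = 1)
sched <- pulse_train(freq_hz = 4, n_pulses = 8, pulse_ms = 50,
                     t_start = 500)
sim <- al_simulate(net, stim_protocol("additive", sched, duration = 5000),
                   stim_seed = 7, record = probe_neuron(net, "odor"))
plot(sim, schedule = sched)

freq <- run_frequency_experiment(net, "additive", freqs = 1:10,
                                 n_trials = 20)
freq$rate           # pulse-following rates of the two standard probes
plot(freq$index$odor)
```
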