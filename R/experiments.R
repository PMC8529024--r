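#' Probe neurons
#'
#' Standard probe choices for the sweep experiments: a representative PN
#' of glomerulus 1 (`"odor"`, an odor-receiving cell under the standard
#' odor paradigm) or of glomerulus 4 (`"non_odor"`). Because per-PN SK
#' strengths are heterogeneous and strongly shape pulse tracking (weak-SK
#' cells fire continuously and track poorly, strong-SK cells burst), the
#' representative cell is chosen by typicality in the two per-cell
#' quantities that control tracking: the SK strength and the number of
#' LN synapses received. Both are standardized within the glomerulus and
#' the PN closest (in squared distance) to the glomerulus medians is
#' returned, ties broken by lowest id. In fixed-SK networks all PNs have
#' equal SK and the choice reduces to the median LN in-degree.
#'
#' @param network an [al_network()].
#' @param which `"odor"` or `"non_odor"`.
#' @return A neuron id.
#' @export
probe_neuron <- function(network, which = c("odor", "non_odor")) {
  which <- match.arg(which)
  glom <- if (which == "odor") 1L else 4L
  nn <- network$neurons
  ids <- nn$id[nn$class == "PN" & nn$glomerulus == glom]
  if (length(ids) == 0L) stop("no PN available in glomerulus ", glom)
  sk <- nn$sk_strength[ids]
  e <- network$edges
  ln_in <- vapply(ids, function(id)
    sum(e$syn_class == "LN_PN" & e$post == id), numeric(1))
  zdist <- function(v) {
    if (sd(v) == 0) return(rep(0, length(v)))
    ((v - median(v)) / sd(v))^2
  }
  ids[which.min(zdist(sk) + zdist(ln_in))]
}

#' Pulse-frequency sweep
#'
#' For each pulse frequency, runs `n_trials` simulations of a 50 ms pulse
#' train (pulses covering `train_ms`, preceded by `pre_ms` of baseline and
#' followed by `post_ms` of recording) with a fresh stimulus seed per trial,
#' and computes the pulse-following index of each probe. Probes may be
#' single neurons or pooled sets (e.g. all PNs of a glomerulus).
#'
#' @param network an [al_network()].
#' @param scenario stimulus scenario (see [stim_protocol()]).
#' @param freqs pulse frequencies (Hz).
#' @param n_trials trials per frequency.
#' @param probes named list of neuron-id vectors; each probe's spikes are
#'   pooled before the index is computed. Defaults to the standard
#'   odor-receiving and non-odor single-PN probes.
#' @param pulse_ms pulse duration (ms).
#' @param train_ms length of the pulse-delivery window (ms); the number of
#'   pulses per train is `round(train_ms / 1000 * freq)`.
#' @param pre_ms,post_ms baseline before the first pulse and recording
#'   after the window (ms).
#' @param dt integration step (ms).
#' @param bin index bin width (ms).
#' @param stim_seed0 base stimulus seed; trial `i` uses `stim_seed0 + i`.
#' @param odor_gain optional per-glomerulus odor gain vector.
#' @return List with `freqs`, per-probe [metric_series] of the index
#'   (`index`), and per-probe pulse-following `rate` computed from the
#'   trial-mean index curve at the 0.05 cutoff.
#' @export
run_frequency_experiment <- function(network, scenario, freqs = 1:12,
                                     n_trials = 50, probes = NULL,
                                     pulse_ms = 50, train_ms = 3000,
                                     pre_ms = 500, post_ms = 1500,
                                     dt = 0.1, bin = 5, stim_seed0 = 1000L,
                                     odor_gain = NULL) {
  if (is.null(probes)) {
    probes <- list(odor = probe_neuron(network, "odor"),
                   non_odor = probe_neuron(network, "non_odor"))
  }
  stopifnot(n_trials >= 1)
  res <- lapply(freqs, function(f) {
    n_pulses <- round(train_ms / 1000 * f)
    if (n_pulses < 2) {
      stop("frequency ", f, " Hz over ", train_ms,
           " ms yields fewer than 2 pulses")
    }
    sched <- pulse_train(f, n_pulses, pulse_ms, pre_ms)
    duration <- pre_ms + n_pulses * (1000 / f) + post_ms
    duration <- ceiling(duration / dt) * dt
    protocol <- stim_protocol(scenario, sched, duration,
                              odor_gain = odor_gain,
                              n_glomeruli = network$params$n_glomeruli)
    idx <- matrix(NA_real_, n_trials, length(probes))
    for (trial in seq_len(n_trials)) {
      sim <- al_simulate(network, protocol, dt = dt,
                         stim_seed = stim_seed0 + trial)
      for (pi in seq_along(probes)) {
        sp <- sim$raster$time[sim$raster$neuron %in% probes[[pi]]]
        idx[trial, pi] <- pulse_following_index(sp, sched, bin = bin)
      }
    }
    idx
  })
  index <- lapply(seq_along(probes), function(pi) {
    metric_series(freqs, vapply(res, function(m) m[, pi],
                                numeric(n_trials)),
                  xlab = "pulse frequency (Hz)",
                  metric = "pulse-following index")
  })
  names(index) <- names(probes)
  rate <- vapply(index, function(ms) pulse_following_rate(ms), numeric(1))
  list(freqs = freqs, index = index, rate = rate,
       scenario = scenario, n_trials = n_trials)
}

#' Pulse-length sweep
#'
#' For each single-pulse length, runs `n_trials` simulations and measures
#' the probe's spiking response length. The pulse starts at `pre_ms`; the
#' simulation continues `post_ms` past pulse offset so that responses that
#' outlast the pulse are captured.
#'
#' @inheritParams run_frequency_experiment
#' @param pulse_lengths pulse length grid (ms).
#' @param probe a single neuron id (defaults to the odor-receiving probe).
#' @return List with `pulse_lengths`, a [metric_series] of response lengths
#'   (`length`), and the per-trial response `slope` (one OLS slope per
#'   trial across the pulse-length grid) as a [metric_series] when the grid
#'   has at least 3 points.
#' @export
run_length_sweep <- function(network, scenario,
                             pulse_lengths = seq(25, 500, by = 25),
                             n_trials = 50, probe = NULL,
                             pre_ms = 500, post_ms = 1500, dt = 0.1,
                             stim_seed0 = 2000L, odor_gain = NULL) {
  if (is.null(probe)) probe <- probe_neuron(network, "odor")
  stopifnot(length(probe) == 1L, n_trials >= 1)
  lens <- matrix(NA_real_, n_trials, length(pulse_lengths))
  for (li in seq_along(pulse_lengths)) {
    L <- pulse_lengths[li]
    sched <- pulse_schedule(pre_ms, pre_ms + L)
    duration <- pre_ms + L + post_ms
    protocol <- stim_protocol(scenario, sched, duration,
                              odor_gain = odor_gain,
                              n_glomeruli = network$params$n_glomeruli)
    for (trial in seq_len(n_trials)) {
      sim <- al_simulate(network, protocol, dt = dt,
                         stim_seed = stim_seed0 + trial)
      lens[trial, li] <- response_length(spike_times(sim, probe), pre_ms)
    }
  }
  out <- list(
    pulse_lengths = pulse_lengths,
    length = metric_series(pulse_lengths, lens,
                           xlab = "pulse length (ms)",
                           metric = "response length (ms)"),
    scenario = scenario, n_trials = n_trials
  )
  if (length(pulse_lengths) >= 3L) {
    slopes <- apply(lens, 1, function(y)
      response_slope(pulse_lengths, y))
    out$slope <- metric_series(1, matrix(slopes, ncol = 1),
                               xlab = "-", metric = "response slope")
  }
  out
}

#' Conductance-strength sweep
#'
#' Sweeps a dimensionless multiplier on the SK current, the fast inhibitory
#' synapses, or the slow inhibitory synapses (1 = standard strength) and
#' measures either the response slope (via a pulse-length sweep per grid
#' point) or the pulse-following rate (via a pulse-frequency sweep per grid
#' point). Each grid point rebuilds the network with the scaled strengths
#' from the same structural seed, so the wiring is identical along the
#' sweep. Rate sweeps use the fixed-SK network variant, whose standard SK
#' strength is the Gaussian mean.
#'
#' @inheritParams run_frequency_experiment
#' @param target `"SK"`, `"fast_inh"` or `"slow_inh"`.
#' @param metric `"slope"` or `"rate"`.
#' @param multipliers non-negative multiplier grid (should include 1).
#' @param params base parameters.
#' @param net_seed structural seed used at every grid point.
#' @param pulse_lengths pulse-length grid for slope sweeps.
#' @param probe single probe neuron id (default: odor-receiving PN).
#' @param n_trials trials per grid point.
#' @param ... further arguments passed to [run_length_sweep()] or
#'   [run_frequency_experiment()].
#' @return List with `multipliers` and either `slope` (a [metric_series]
#'   over the multiplier grid) or `rate` (numeric vector over the grid,
#'   from the trial-mean index curves) plus the underlying index curves.
#' @export
run_conductance_sweep <- function(target = c("SK", "fast_inh", "slow_inh"),
                                  metric = c("slope", "rate"),
                                  multipliers = seq(0, 3, by = 0.25),
                                  scenario = "odor_only",
                                  params = al_params(), net_seed = 1L,
                                  n_trials = 50,
                                  pulse_lengths = seq(50, 500, by = 50),
                                  freqs = 1:12, probe = NULL, ...) {
  target <- match.arg(target)
  metric <- match.arg(metric)
  if (any(multipliers < 0)) stop("multipliers must be non-negative")
  field <- switch(target, SK = "scale_SK", fast_inh = "scale_inh",
                  slow_inh = "scale_slow")
  build <- function(m) {
    p <- params
    p[[field]] <- m
    p <- do.call(al_params, p[names(formals(al_params))])
    al_network(p, seed = net_seed,
               sk = if (metric == "rate") "fixed" else "gaussian")
  }
  if (metric == "slope") {
    trials <- sapply(multipliers, function(m) {
      net <- build(m)
      sw <- run_length_sweep(net, scenario, pulse_lengths,
                             n_trials = n_trials, probe = probe, ...)
      sw$slope$trials[, 1]
    })
    list(multipliers = multipliers, target = target, scenario = scenario,
         slope = metric_series(multipliers, trials,
                               xlab = paste0(target, " multiplier"),
                               metric = "response slope"))
  } else {
    runs <- lapply(multipliers, function(m) {
      net <- build(m)
      run_frequency_experiment(net, scenario, freqs = freqs,
                               n_trials = n_trials,
                               probes = list(probe = if (is.null(probe))
                                 probe_neuron(net, "odor") else probe),
                               ...)
    })
    list(multipliers = multipliers, target = target, scenario = scenario,
         rate = vapply(runs, function(r) r$rate[["probe"]], numeric(1)),
         index = lapply(runs, function(r) r$index$probe))
  }
}

#' Graded odor-tuning frequency experiment
#'
#' The graded odor paradigm: odor input is delivered to every glomerulus
#' with gains (0, 0.2, 0.4, 0.6, 0.8, 1) for glomeruli 1..6, so the total
#' odor drive matches the standard paradigm (three glomeruli at gain 1),
#' with mechanosensory input absent (`odor_only`) or standard (`additive`).
#' The pulse-following index is computed on the pooled PN activity of each
#' glomerulus.
#'
#' @inheritParams run_frequency_experiment
#' @param scenario `"odor_only"` or `"additive"`.
#' @param odor_gain per-glomerulus gain vector (the graded default above).
#' @return As [run_frequency_experiment()], with one probe per glomerulus
#'   (`glom1` ... `glom6`).
#' @export
run_graded_odor <- function(network, scenario = c("odor_only", "additive"),
                            freqs = 1:12, n_trials = 50,
                            odor_gain = seq(0, 1, length.out = 6), ...) {
  scenario <- match.arg(scenario)
  ng <- network$params$n_glomeruli
  if (length(odor_gain) != ng) {
    stop("odor_gain must have one entry per glomerulus")
  }
  nn <- network$neurons
  probes <- lapply(seq_len(ng), function(g)
    nn$id[nn$class == "PN" & nn$glomerulus == g])
  names(probes) <- paste0("glom", seq_len(ng))
  run_frequency_experiment(network, scenario, freqs = freqs,
                           n_trials = n_trials, probes = probes,
                           odor_gain = odor_gain, ...)
}

#' Post-train suppression (AHP) experiment
#'
#' Runs an odor-containing pulse train and quantifies the
#' after-hyperpolarization: the probe PN's trial-averaged sliding-window
#' firing rate is computed, the baseline is its mean over the later
#' pre-stimulus window, and two durations are measured from the final
#' pulse offset. `suppression_ms` is the length of the suppressed epoch
#' proper -- from when the rate first falls below half the baseline until
#' it first climbs back above half the baseline (a full-width measure that
#' is robust to the slow asymptotic tail of the recovery).
#' `full_recovery_ms` is the stricter time until the rate, having fallen
#' below baseline, first returns all the way to the baseline rate; because
#' the slow inhibitory conductance decays exponentially, the rate
#' approaches baseline asymptotically and this crossing systematically
#' overshoots the suppressed epoch. Both are censored at the end of the
#' recording when the rate never recovers.
#'
#' @inheritParams run_frequency_experiment
#' @param freq pulse frequency (Hz).
#' @param n_pulses number of pulses in the train.
#' @param window sliding rate window (ms).
#' @param probe single probe neuron id.
#' @return List with `suppression_ms`, `full_recovery_ms`, `baseline_hz`,
#'   the rate curve (data.frame `time`, `rate`), `final_offset` and
#'   `censored`.
#' @export
run_ahp_experiment <- function(network, scenario = "odor_only", freq = 4,
                               n_pulses = 8, n_trials = 50, pulse_ms = 50,
                               pre_ms = 1500, post_ms = 2500, dt = 0.1,
                               window = 200, probe = NULL,
                               stim_seed0 = 3000L, odor_gain = NULL) {
  if (is.null(probe)) probe <- probe_neuron(network, "odor")
  sched <- pulse_train(freq, n_pulses, pulse_ms, pre_ms)
  final_offset <- sched$t_off[n_pulses]
  duration <- final_offset + post_ms
  protocol <- stim_protocol(scenario, sched, duration,
                            odor_gain = odor_gain,
                            n_glomeruli = network$params$n_glomeruli)
  trains <- lapply(seq_len(n_trials), function(trial) {
    sim <- al_simulate(network, protocol, dt = dt,
                       stim_seed = stim_seed0 + trial)
    spike_times(sim, probe)
  })
  rate <- sliding_rate(trains, duration, window = window)
  # baseline from the later pre-stimulus window, past the initial
  # burn-in transient of the slow conductances
  baseline <- mean(rate$rate[rate$time + window / 2 <= pre_ms &
                               rate$time - window / 2 >= pre_ms / 3])
  post <- rate[rate$time - window / 2 >= final_offset, ]
  # the stimulus-driven response can outlast the final pulse, so both
  # measures start counting only once the rate has fallen below their
  # respective thresholds
  # recovery must be sustained (>= 300 ms above threshold), so single-bin
  # blips of the trial-averaged rate do not terminate the epoch
  epoch <- function(threshold, sustain_ms = 300) {
    below <- which(post$rate < threshold)
    if (length(below) == 0L) return(list(dur = 0, censored = FALSE))
    k <- max(1L, round(sustain_ms / diff(post$time[1:2])))
    above <- post$rate >= threshold
    for (i in seq(below[1] + 1L, nrow(post))) {
      run <- above[i:min(i + k - 1L, nrow(post))]
      if (all(run)) {
        return(list(dur = post$time[i] - final_offset, censored = FALSE))
      }
    }
    list(dur = duration - final_offset, censored = TRUE)
  }
  half <- epoch(baseline / 2)
  full <- epoch(baseline)
  list(suppression_ms = half$dur, full_recovery_ms = full$dur,
       baseline_hz = baseline, rate = rate,
       final_offset = final_offset, censored = half$censored,
       n_trials = n_trials)
}

#' Synthetic spike rasters with known tracking structure
#'
#' Fixture generator for the analysis metrics: rasters whose
#' pulse-tracking behaviour is known by construction.
#' \describe{
#'   \item{pulse_locked}{inhomogeneous Poisson spiking at `rate_in` during
#'     each pulse and `rate_out` between pulses -- tracks the train.}
#'   \item{tonic}{perfectly regular spiking at the matched mean rate -- no
#'     pulse periodicity.}
#'   \item{poisson}{homogeneous Poisson at the matched mean rate.}
#'   \item{empty}{no spikes.}
#' }
#' The matched mean rate equals the time average of the pulse_locked rate
#' over the schedule window, so all kinds are comparable in spike count.
#'
#' @param kind raster kind, see above.
#' @param schedule a [pulse_schedule()].
#' @param duration raster duration (ms).
#' @param rate_in in-pulse rate (spikes/ms).
#' @param rate_out between-pulse rate (spikes/ms).
#' @param n_trains number of independent trains.
#' @param seed integer seed.
#' @return List of `n_trains` sorted spike-time vectors.
#' @export
make_synthetic_raster <- function(kind = c("pulse_locked", "tonic",
                                           "poisson", "empty"),
                                  schedule, duration,
                                  rate_in = 0.2, rate_out = 0.002,
                                  n_trains = 1, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(schedule, "pulse_schedule"))
  if (kind == "empty") {
    return(replicate(n_trains, numeric(0), simplify = FALSE))
  }
  grid <- seq(0, duration - 1, by = 1)
  in_pulse <- Reduce(`|`, lapply(seq_len(nrow(schedule)), function(i)
    grid >= schedule$t_on[i] & grid < schedule$t_off[i]))
  rate <- ifelse(in_pulse, rate_in, rate_out)
  mean_rate <- mean(rate)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  lapply(seq_len(n_trains), function(i) {
    switch(kind,
      pulse_locked = {
        counts <- rpois(length(grid), rate)
        sort(rep(grid, counts) + runif(sum(counts)))
      },
      poisson = {
        counts <- rpois(length(grid), mean_rate)
        sort(rep(grid, counts) + runif(sum(counts)))
      },
      tonic = {
        isi <- 1 / mean_rate
        seq(isi / 2, duration, by = isi)
      })
  })
}
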