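#' Pulse schedules
#'
#' A pulse schedule is the list of stimulus pulse windows `(t_on, t_off)` in
#' ms. `pulse_schedule()` builds one from explicit onset/offset vectors;
#' `pulse_train()` builds a periodic train of fixed-length pulses from a
#' frequency.
#'
#' @param t_on,t_off numeric vectors of pulse onsets and offsets (ms);
#'   must satisfy `t_on < t_off`, be sorted by onset, and onsets must not
#'   overlap a preceding pulse (envelope tails may, and do, overlap).
#' @return A data.frame of class `pulse_schedule` with columns `t_on`,
#'   `t_off` and attributes `period` (onset-to-onset, NA if fewer than two
#'   pulses or aperiodic) and `pulse_ms`.
#' @examples
#' pulse_train(freq_hz = 4, n_pulses = 8, t_start = 500)
#' @export
pulse_schedule <- function(t_on, t_off) {
  if (length(t_on) != length(t_off)) stop("t_on and t_off lengths differ")
  if (length(t_on) == 0L) stop("schedule must contain at least one pulse")
  if (any(t_off <= t_on)) stop("every pulse needs t_on < t_off")
  if (is.unsorted(t_on, strictly = TRUE) && length(t_on) > 1L) {
    stop("pulses must be sorted by strictly increasing onset")
  }
  if (length(t_on) > 1L && any(t_on[-1] < t_off[-length(t_off)])) {
    stop("pulses must not overlap in onset order")
  }
  dur <- unique(round(t_off - t_on, 10))
  per <- if (length(t_on) > 1L) unique(round(diff(t_on), 10)) else NA_real_
  structure(
    data.frame(t_on = t_on, t_off = t_off),
    period = if (length(per) == 1L) per else NA_real_,
    pulse_ms = if (length(dur) == 1L) dur else NA_real_,
    class = c("pulse_schedule", "data.frame")
  )
}

#' @rdname pulse_schedule
#' @param freq_hz pulse repetition frequency (Hz, onset to onset).
#' @param n_pulses number of pulses in the train.
#' @param pulse_ms pulse duration (ms); 50 ms is the standard train pulse.
#' @param t_start onset of the first pulse (ms).
#' @export
pulse_train <- function(freq_hz, n_pulses, pulse_ms = 50, t_start = 500) {
  stopifnot(freq_hz > 0, n_pulses >= 1, pulse_ms > 0)
  period <- 1000 / freq_hz
  if (pulse_ms >= period) stop("pulse_ms must be shorter than the period")
  on <- t_start + (seq_len(n_pulses) - 1) * period
  pulse_schedule(on, on + pulse_ms)
}

#' Stimulus protocols
#'
#' A protocol binds a scenario to a pulse schedule, a per-glomerulus odor
#' gain vector and a total duration. Scenarios:
#' \describe{
#'   \item{background}{no pulses delivered; every cell receives only the
#'     background rate `lambda_back`.}
#'   \item{odor_only}{odor input (rate `odor_gain[g] * lambda_odor_max`) to
#'     each glomerulus `g`, no mechanosensory input. Simulates odor at low
#'     wind speed.}
#'   \item{mech_only}{mechanosensory input at `lambda_mech_max` to every
#'     glomerulus, no odor. Simulates a non-scented high-speed air puff.}
#'   \item{additive}{literal sum of the odor_only and mech_only pulse drives.
#'     Simulates odor delivered in a high-wind-speed puff.}
#' }
#' The default odor gain targets glomeruli 1-3 at full strength (the
#' standard odor paradigm); the graded odor-tuning paradigm uses
#' `odor_gain = c(0, 0.2, 0.4, 0.6, 0.8, 1)`, which delivers the same total
#' odor drive to the network.
#'
#' @param scenario one of `"background"`, `"odor_only"`, `"mech_only"`,
#'   `"additive"`.
#' @param schedule a [pulse_schedule()] (required except for background).
#' @param duration total simulated duration (ms).
#' @param odor_gain numeric vector, one value in \[0, 1\] per glomerulus,
#'   multiplying `lambda_odor_max`. Forced to zero for scenarios without
#'   odor.
#' @param n_glomeruli number of glomeruli the gain vector must cover.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(scenario = c("odor_only", "mech_only", "additive",
                                       "background"),
                          schedule = NULL, duration,
                          odor_gain = NULL, n_glomeruli = 6) {
  scenario <- match.arg(scenario)
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0)
  if (scenario != "background") {
    if (is.null(schedule)) stop("scenario '", scenario, "' needs a schedule")
    stopifnot(inherits(schedule, "pulse_schedule"))
  }
  if (is.null(odor_gain)) {
    odor_gain <- c(rep(1, min(3, n_glomeruli)),
                   rep(0, max(0, n_glomeruli - 3)))
  }
  if (length(odor_gain) != n_glomeruli) {
    stop("odor_gain must have one entry per glomerulus")
  }
  if (any(odor_gain < 0 | odor_gain > 1)) stop("odor_gain must lie in [0, 1]")
  if (scenario %in% c("background", "mech_only")) {
    odor_gain <- rep(0, n_glomeruli)
  }
  structure(
    list(scenario = scenario, schedule = schedule, duration = duration,
         odor_gain = odor_gain,
         mech_active = scenario %in% c("mech_only", "additive")),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("Stimulus protocol: %s, %g ms\n", x$scenario, x$duration))
  if (!is.null(x$schedule)) {
    cat(sprintf("  %d pulse(s), pulse %g ms, period %s ms\n",
                nrow(x$schedule), attr(x$schedule, "pulse_ms"),
                format(attr(x$schedule, "period"))))
  }
  cat("  odor gain:", paste(format(x$odor_gain), collapse = " "),
      "| mech:", x$mech_active, "\n")
  invisible(x)
}

# shared envelope machinery, the piecewise definition evaluated branch by
# branch in its stated order: 0 before onset; the sigmoidal rise while
# t <= t_on + 2 tau_rise (even past a shorter pulse's offset -- for brief
# pulses the slow rise outlasts the pulse, which is what lets local
# neurons integrate a train of brief mechanosensory pulses into sustained
# inhibitory drive); the plateau while t <= t_off; exponential decay
# (referenced to t_off) afterwards
pulse_envelope <- function(t, t_on, t_off, tau_rise, tau_decay) {
  u <- t - t_on
  v <- numeric(length(t))
  sig <- tau_rise > 0 & u >= 0 & u <= 2 * tau_rise
  plateau <- !sig & u >= 0 & t <= t_off
  decay <- !sig & !plateau & u >= 0
  if (tau_rise > 0) v[sig] <- plogis(5 * (u[sig] - tau_rise) / tau_rise)
  v[plateau] <- 1
  v[decay] <- exp(-(t[decay] - t_off) / tau_decay)
  v
}

#' Stimulus envelopes
#'
#' Temporal envelopes in \[0, 1\] shaping the odor (`odor_envelope`) and
#' mechanosensory (`mech_envelope`) input rate for one pulse. Odor rises
#' sigmoidally for PNs (half-rise `tau_odor_rise_PN` = 35 ms) and
#' instantaneously for LNs; mechanosensory input rises instantaneously for
#' PNs and sigmoidally for LNs (half-rise `tau_mech_rise_LN` = 300 ms).
#' The piecewise branches are evaluated in order: the sigmoidal branch
#' `exp(5 (u - tau_r) / tau_r) / (1 + exp(5 (u - tau_r) / tau_r))` for
#' time `u` since onset while `u <= 2 tau_r`; the plateau value 1 while
#' `t <= t_off`; and the exponential decay `exp(-(t - t_off) /
#' tau_env_decay)` (384 ms) afterwards. For pulses shorter than the full
#' rise (50 ms pulses for odor-to-PN and mechanosensory-to-LN input) the
#' sigmoidal branch outlasts the pulse, so the envelope continues to build
#' after offset before the decay branch takes over -- for LNs this is what
#' integrates a train of brief mechanosensory pulses into sustained drive.
#'
#' @param t time(s) at which to evaluate (ms); vectorized.
#' @param t_on,t_off pulse onset and offset (ms), `t_off > t_on`.
#' @param cell_class `"PN"` or `"LN"`.
#' @param params an [al_params()] object (envelope time constants).
#' @return Numeric vector of envelope values in \[0, 1\].
#' @examples
#' odor_envelope(500, 500, 550, "PN")   # sigmoid toe at onset, ~0.0067
#' mech_envelope(500, 500, 550, "PN")   # instantaneous rise, 1
#' @export
odor_envelope <- function(t, t_on, t_off, cell_class = c("PN", "LN"),
                          params = al_params()) {
  cell_class <- match.arg(cell_class)
  stopifnot(t_off > t_on)
  tau_rise <- if (cell_class == "PN") params$tau_odor_rise_PN else 0
  pulse_envelope(t, t_on, t_off, tau_rise, params$tau_env_decay)
}

#' @rdname odor_envelope
#' @export
mech_envelope <- function(t, t_on, t_off, cell_class = c("PN", "LN"),
                          params = al_params()) {
  cell_class <- match.arg(cell_class)
  stopifnot(t_off > t_on)
  tau_rise <- if (cell_class == "LN") params$tau_mech_rise_LN else 0
  pulse_envelope(t, t_on, t_off, tau_rise, params$tau_env_decay)
}

#' Total external input rate for one cell
#'
#' The inhomogeneous Poisson rate driving a cell: the background rate plus,
#' summed over every scheduled pulse (envelope tails from earlier pulses
#' persist and superpose),
#' `odor_gain[glomerulus] * lambda_odor_max * O(t)` and, when the scenario
#' carries mechanosensory input, `lambda_mech_max * M(t)`.
#'
#' @param cell_class `"PN"` or `"LN"`.
#' @param glomerulus 1-based glomerulus index of the cell.
#' @param t time(s), ms; vectorized.
#' @param protocol a [stim_protocol()].
#' @param params an [al_params()].
#' @return Rate in spikes/ms at each `t`.
#' @examples
#' pr <- stim_protocol("background", duration = 1000)
#' total_rate("PN", 1, 123, pr)  # 3.6
#' @export
total_rate <- function(cell_class = c("PN", "LN"), glomerulus, t, protocol,
                       params = al_params()) {
  cell_class <- match.arg(cell_class)
  stopifnot(inherits(protocol, "stim_protocol"))
  rate <- rep(params$lambda_back, length(t))
  if (protocol$scenario == "background" || is.null(protocol$schedule)) {
    return(rate)
  }
  gain <- protocol$odor_gain[glomerulus]
  for (i in seq_len(nrow(protocol$schedule))) {
    on <- protocol$schedule$t_on[i]
    off <- protocol$schedule$t_off[i]
    if (gain > 0) {
      rate <- rate + gain * params$lambda_odor_max *
        odor_envelope(t, on, off, cell_class, params)
    }
    if (protocol$mech_active) {
      rate <- rate + params$lambda_mech_max *
        mech_envelope(t, on, off, cell_class, params)
    }
  }
  rate
}

# Distinct rate profiles on the integration grid. Cells sharing
# (class, odor gain) share a profile; returns group index per neuron plus a
# groups x steps rate matrix evaluated at bin left edges.
rate_profiles <- function(network, protocol, dt) {
  n_steps <- floor(protocol$duration / dt + 1e-9)
  t <- (seq_len(n_steps) - 1) * dt
  nn <- network$neurons
  gain <- protocol$odor_gain[nn$glomerulus]
  key <- paste(nn$class, format(gain, digits = 12))
  groups <- !duplicated(key)
  key_levels <- key[groups]
  idx <- match(key, key_levels)
  rates <- matrix(0, nrow = length(key_levels), ncol = n_steps)
  for (gidx in seq_along(key_levels)) {
    j <- which(groups)[gidx]
    rates[gidx, ] <- total_rate(nn$class[j], nn$glomerulus[j], t, protocol,
                                network$params)
  }
  list(group = idx, rates = rates, n_steps = n_steps)
}

#' Sample an external input spike train
#'
#' Realizes an inhomogeneous Poisson process on the integration grid: per
#' time bin of width `dt` a Poisson count with mean `rate * dt` is drawn
#' (counts, not a Bernoulli flag -- at peak drive `rate * dt` approaches 1)
#' and that many events are placed at the bin's time. This is the same
#' scheme the simulator uses internally.
#'
#' @param rate_fn a function of time (ms) returning the rate in spikes/ms,
#'   or a numeric vector of per-bin rates (evaluated at bin left edges).
#' @param duration train duration (ms).
#' @param dt bin width (ms); must match the simulation step.
#' @param seed integer seed.
#' @return Sorted numeric vector of event times (ms); one repeated time per
#'   multi-event bin.
#' @export
sample_input_train <- function(rate_fn, duration, dt = 0.1, seed = 1L) {
  n_steps <- floor(duration / dt + 1e-9)
  t <- (seq_len(n_steps) - 1) * dt
  rate <- if (is.function(rate_fn)) rate_fn(t) else rep_len(rate_fn, n_steps)
  if (any(rate < 0)) stop("internal error: negative input rate")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  counts <- rpois(n_steps, rate * dt)
  rep(t + dt, counts)
}
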