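#' Synaptic and SK kernels
#'
#' `alpha_kernel()` is the unit-integral exponential kernel
#' `H(t) / tau * exp(-t / tau)` used for the fast excitatory, fast
#' inhibitory, stimulus and slow inhibitory conductances. `sk_kernel()` is
#' the SK-current kernel: a sigmoidal rise
#' `H(t) / tau_SK * exp(5 (t - tau_rise) / tau_rise) /
#' (1 + exp(5 (t - tau_rise) / tau_rise))` for `t <= 2 tau_rise`, then an
#' exponential decay `1 / tau_SK * exp(-(t - 2 tau_rise) / tau_SK)`. The
#' kernel is (mildly) discontinuous at `2 tau_rise`, exactly as defined.
#'
#' @param t_since time since the triggering spike (ms); vectorized, negative
#'   values give 0.
#' @param tau decay time constant (ms).
#' @param tau_SK SK decay time constant (ms).
#' @param tau_rise SK sigmoidal half-rise time (ms).
#' @return Kernel value(s), 1/ms.
#' @examples
#' alpha_kernel(0, 2)            # 1/tau = 0.5
#' sk_kernel(25, 250, 25)        # half-rise: 1/(2 * 250)
#' @export
alpha_kernel <- function(t_since, tau) {
  stopifnot(tau > 0)
  ifelse(t_since < 0, 0, exp(-t_since / tau) / tau)
}

#' @rdname alpha_kernel
#' @export
sk_kernel <- function(t_since, tau_SK = 250, tau_rise = 25) {
  stopifnot(tau_SK > 0, tau_rise > 0)
  ifelse(t_since < 0, 0,
         ifelse(t_since <= 2 * tau_rise,
                plogis(5 * (t_since - tau_rise) / tau_rise) / tau_SK,
                exp(-(t_since - 2 * tau_rise) / tau_SK) / tau_SK))
}

#' Simulate the antennal lobe network
#'
#' Advances the coupled membrane/conductance dynamics with forward Euler at
#' step `dt` (0.1 ms by default), drawing per-bin Poisson external input
#' from the protocol's rate profiles. Spikes fired in one step reach their
#' postsynaptic targets at the next step; after each spike the membrane is
#' held at the reset potential for the refractory period.
#'
#' Deterministic given `(network, stim_seed)`: the same arguments always
#' produce a byte-identical raster.
#'
#' @param network an [al_network()].
#' @param protocol a [stim_protocol()] (its duration sets the simulated
#'   time; a duration that is not a multiple of `dt` is rounded down with a
#'   warning).
#' @param dt integration step (ms).
#' @param stim_seed integer seed for the external input realization.
#' @param record integer vector of neuron ids whose state to trace
#'   (membrane potential and all conductance states, every step).
#' @param v_init initial membrane potential(s), recycled across neurons.
#' @param ext_counts optional integer matrix (neurons x steps) of external
#'   input event counts, overriding Poisson sampling (canned input trains
#'   for controlled experiments).
#' @param stim_clamp optional non-negative value at which to clamp the
#'   stimulus conductance of every neuron (no external events delivered);
#'   `NULL` for normal operation.
#' @param return_inputs if `TRUE`, also return the realized external input
#'   counts (neurons x steps).
#' @return An object of class `al_sim`: list with `raster` (data.frame
#'   `neuron`, `time`, plus class/glomerulus), `traces` (named list of
#'   step-aligned matrices, one column per recorded neuron), `dt`,
#'   `duration`, `network_seed`, `stim_seed`, and optionally `ext_counts`.
#' @examples
#' net <- al_network(seed = 1)
#' pr <- stim_protocol("background", duration = 200)
#' sim <- al_simulate(net, pr, stim_seed = 7)
#' nrow(sim$raster)
#' @export
al_simulate <- function(network, protocol, dt = 0.1, stim_seed = 1L,
                        record = NULL, v_init = NULL, ext_counts = NULL,
                        stim_clamp = NULL, return_inputs = FALSE) {
  stopifnot(inherits(network, "al_network"),
            inherits(protocol, "stim_protocol"))
  p <- network$params
  if (abs(protocol$duration / dt - round(protocol$duration / dt)) > 1e-9) {
    warning("duration is not a multiple of dt; rounding down")
  }
  nn <- network$neurons
  n <- nrow(nn)
  cls <- ifelse(nn$class == "PN", 0L, 1L)

  rp <- rate_profiles(network, protocol, dt)
  csr <- adjacency_csr(network)
  if (is.null(v_init)) v_init <- p$V_L
  if (is.null(ext_counts)) {
    ext_counts <- matrix(0L, nrow = 0, ncol = 0)
  } else {
    stopifnot(nrow(ext_counts) == n, ncol(ext_counts) == rp$n_steps)
    storage.mode(ext_counts) <- "integer"
  }
  record_idx <- if (is.null(record)) integer(0) else as.integer(record) - 1L
  stopifnot(all(record_idx >= 0 & record_idx < n))

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(stim_seed))
  res <- sim_core(cls, nn$sk_strength, csr$ptr, csr$tgt,
                  p, rp$rates, rp$group - 1L, rp$n_steps, dt,
                  as.numeric(v_init), record_idx, ext_counts,
                  if (is.null(stim_clamp)) -1 else stim_clamp,
                  return_inputs)

  raster <- data.frame(
    neuron = res$spike_id,
    time = res$spike_t,
    class = nn$class[res$spike_id],
    glomerulus = nn$glomerulus[res$spike_id],
    stringsAsFactors = FALSE
  )
  traces <- NULL
  if (length(record_idx)) {
    traces <- res$traces
    for (nm in names(traces)) colnames(traces[[nm]]) <- record_idx + 1L
  }
  out <- list(raster = raster, traces = traces, dt = dt,
              duration = rp$n_steps * dt, network_seed = network$seed,
              stim_seed = as.integer(stim_seed), scenario = protocol$scenario)
  if (return_inputs) out$ext_counts <- res$ext_counts
  structure(out, class = "al_sim")
}

adjacency_csr <- function(network) {
  n <- nrow(network$neurons)
  e <- network$edges
  o <- order(e$pre)
  pre <- e$pre[o]
  counts <- tabulate(pre, nbins = n)
  list(ptr = c(0L, cumsum(counts)), tgt = as.integer(e$post[o]) - 1L)
}

#' @export
print.al_sim <- function(x, ...) {
  cat(sprintf("Antennal lobe simulation: %g ms at dt = %g ms (%s)\n",
              x$duration, x$dt, x$scenario))
  cat(sprintf("  %d spikes (%d PN, %d LN); seeds: network %d, stimulus %d\n",
              nrow(x$raster), sum(x$raster$class == "PN"),
              sum(x$raster$class == "LN"), x$network_seed, x$stim_seed))
  if (!is.null(x$traces)) {
    cat("  traces recorded for neuron(s):",
        paste(colnames(x$traces$V), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Spike times of one neuron
#'
#' @param sim an `al_sim` object.
#' @param neuron neuron id.
#' @return Sorted numeric vector of spike times (ms).
#' @export
spike_times <- function(sim, neuron) {
  stopifnot(inherits(sim, "al_sim"))
  sort(sim$raster$time[sim$raster$neuron == neuron])
}

#' Raster plot of a simulation
#'
#' Neurons on the y axis (grouped by glomerulus, PNs below LNs within each),
#' time on the x axis; stimulus pulses, if supplied, drawn as bars along the
#' bottom.
#'
#' @param x an `al_sim` object.
#' @param schedule optional [pulse_schedule()] to mark.
#' @param ... passed to [graphics::plot()].
#' @export
plot.al_sim <- function(x, schedule = NULL, ...) {
  r <- x$raster
  graphics::plot(r$time, r$neuron, pch = ".", cex = 2,
                 col = ifelse(r$class == "PN", "black", "firebrick"),
                 xlab = "time (ms)", ylab = "neuron id",
                 xlim = c(0, x$duration), ...)
  if (!is.null(schedule)) {
    rect(schedule$t_on, -1, schedule$t_off, 0.5, col = "grey30",
         border = NA)
  }
  invisible(x)
}

#' Trial-averaged sliding-window firing rate
#'
#' Smoothed firing rate of a set of spike trains (e.g., one probe neuron
#' over many trials): spike counts in a sliding window divided by window
#' length and train count.
#'
#' @param trains list of numeric spike-time vectors (ms).
#' @param duration recording length (ms).
#' @param window sliding window length (ms).
#' @param step window step (ms).
#' @return data.frame with window centre `time` (ms) and `rate` (spikes/s).
#' @export
sliding_rate <- function(trains, duration, window = 200, step = 10) {
  all_spikes <- sort(unlist(trains, use.names = FALSE))
  centres <- seq(window / 2, duration - window / 2, by = step)
  counts <- vapply(centres, function(ct) {
    sum(all_spikes >= ct - window / 2 & all_spikes < ct + window / 2)
  }, numeric(1))
  data.frame(time = centres,
             rate = counts / (window / 1000) / length(trains))
}
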