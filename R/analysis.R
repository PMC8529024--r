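#' Length of a spiking response
#'
#' Time between the first spike after stimulus onset and the end of the
#' response. The response ends at the spike preceding the first interspike
#' interval that exceeds three times the mean of the first three intervals;
#' if no interval exceeds that threshold the response runs to the last
#' spike. Trains with fewer than four spikes after onset fall back to
#' last-minus-first spike time (0 for at most one spike), which keeps the
#' metric continuous as spiking fades in sweeps.
#'
#' @param spikes numeric vector of spike times (ms), sorted.
#' @param stim_onset stimulus onset (ms); only spikes at or after it count.
#' @return Response length (ms), >= 0.
#' @examples
#' response_length(c(100, 150, 200, 250, 600), 0)  # 150
#' @export
response_length <- function(spikes, stim_onset) {
  s <- spikes[spikes >= stim_onset]
  n <- length(s)
  if (n <= 1L) return(0)
  if (n < 4L) return(s[n] - s[1])
  isi <- diff(s)
  threshold <- 3 * mean(isi[1:3])
  over <- which(isi > threshold)
  end <- if (length(over)) s[over[1]] else s[n]
  end - s[1]
}

#' Response slope
#'
#' Ordinary least-squares slope of response length against stimulus pulse
#' length. A slope near one means the spiking response faithfully encodes
#' pulse duration; near zero, that it carries no duration information.
#'
#' @param pulse_lengths pulse length grid (ms), at least 3 distinct values.
#' @param response_lengths response lengths (ms), same length.
#' @return Dimensionless slope.
#' @examples
#' response_slope(c(50, 100, 150), c(100, 180, 260))  # 1.6
#' @export
response_slope <- function(pulse_lengths, response_lengths) {
  stopifnot(length(pulse_lengths) == length(response_lengths))
  if (length(pulse_lengths) < 3L) stop("need at least 3 grid points")
  if (var(pulse_lengths) == 0) stop("pulse lengths are all equal")
  unname(coef(lm(response_lengths ~ pulse_lengths))[2])
}

#' Pulse-following index
#'
#' Autocorrelation-based measure of how well a spike raster tracks a
#' periodic pulse train. Spikes from the first pulse onset through the end
#' of the train (`n_pulses` periods) are binned at `bin` ms; the
#' mean-subtracted, coefficient-normalized autocorrelation (unit value at
#' zero lag) is computed; the index is the ACF at the pulse
#' inception-to-inception lag (the period -- the peak of a pulse-locked
#' raster) minus the ACF at the lag of the first pulse's end (the pulse
#' duration -- the trough of a raster whose responses truncate with the
#' pulse), floored at zero. Each of the two values is averaged over the
#' bins within one bin width of its nominal lag, which absorbs binning
#' misalignment and keeps the statistic unbiased on structureless rasters,
#' so the 0.05 cutoff separates genuine pulse locking from sampling noise.
#'
#' The trough lag makes the index sensitive to response brevity: a raster
#' that bursts briefly at each pulse and is silent by pulse end scores
#' high, while responses that outlast the pulse -- and at high pulse
#' frequencies fuse into tonic firing -- raise the pulse-end
#' autocorrelation and drive the index toward zero. Tonic or Poisson
#' firing at any rate scores near zero; an empty raster scores exactly
#' zero.
#'
#' @param spikes numeric vector of spike times, or a list of them (pooled
#'   before binning, e.g. all PNs of a glomerulus).
#' @param schedule a periodic [pulse_schedule()] with at least 2 pulses.
#' @param bin ACF bin width (ms).
#' @return Dimensionless index >= 0.
#' @export
pulse_following_index <- function(spikes, schedule, bin = 5) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  if (nrow(schedule) < 2L) stop("schedule must contain at least 2 pulses")
  period <- attr(schedule, "period")
  pulse_ms <- attr(schedule, "pulse_ms")
  if (is.na(period)) stop("schedule must be periodic")
  if (period <= 2 * bin) stop("period <= 2 * bin: unresolvable at this binning")
  if (is.list(spikes)) spikes <- unlist(spikes, use.names = FALSE)

  if (is.na(pulse_ms)) stop("schedule must have a common pulse duration")

  t0 <- schedule$t_on[1]
  t1 <- t0 + nrow(schedule) * period
  s <- spikes[spikes >= t0 & spikes < t1]
  n_bins <- max(1L, floor((t1 - t0) / bin))
  if (length(s) == 0L) return(0)
  counts <- tabulate(pmin(floor((s - t0) / bin) + 1L, n_bins), nbins = n_bins)
  if (var(counts) == 0) return(0)

  lag_max <- min(ceiling((period + bin) / bin), n_bins - 1L)
  r <- as.numeric(acf(counts, lag.max = lag_max, plot = FALSE,
                      demean = TRUE)$acf)
  lag_ms <- (seq_along(r) - 1) * bin

  peak_in <- abs(lag_ms - period) <= bin
  trough_in <- abs(lag_ms - pulse_ms) <= bin & lag_ms > 0
  if (!any(peak_in) || !any(trough_in)) return(0)
  max(mean(r[peak_in]) - mean(r[trough_in]), 0)
}

#' Pulse-following rate
#'
#' The highest tested pulse frequency whose (trial-mean) pulse-following
#' index is at or above the cutoff; 0 if none is. Indices exactly at the
#' cutoff count as following. This is the model's analogue of a low-pass
#' cutoff frequency for pulse tracking.
#'
#' @param freqs tested pulse frequencies (Hz), ascending.
#' @param index mean pulse-following index at each frequency, or a
#'   [metric_series] whose `x` is the frequency grid.
#' @param cutoff index cutoff (default 0.05).
#' @return Rate in Hz.
#' @examples
#' pulse_following_rate(c(2, 4, 6, 8), c(0.3, 0.2, 0.1, 0.04))  # 6
#' @export
pulse_following_rate <- function(freqs, index = NULL, cutoff = 0.05) {
  if (inherits(freqs, "metric_series")) {
    index <- freqs$mean
    freqs <- freqs$x
  }
  if (length(freqs) == 0L) stop("empty frequency series")
  stopifnot(length(freqs) == length(index), !is.unsorted(freqs))
  ok <- which(index >= cutoff)
  if (length(ok) == 0L) 0 else freqs[max(ok)]
}

#' Metric series: per-grid-point trial values with summaries
#'
#' Container used by all sweep experiments: an independent-variable grid
#' (pulse length, pulse frequency, conductance multiplier, ...), the
#' per-trial metric values at each grid point, and their mean and standard
#' deviation.
#'
#' @param x independent variable grid.
#' @param trials numeric matrix, one row per trial, one column per grid
#'   point.
#' @param xlab label describing `x`.
#' @param metric label describing the metric.
#' @return An object of class `metric_series`: list with `x`, `trials`,
#'   `mean`, `sd`, `n_trials`, labels.
#' @export
metric_series <- function(x, trials, xlab = "x", metric = "value") {
  trials <- as.matrix(trials)
  stopifnot(ncol(trials) == length(x))
  structure(
    list(x = x, trials = trials,
         mean = colMeans(trials),
         sd = apply(trials, 2, sd),
         n_trials = nrow(trials), xlab = xlab, metric = metric),
    class = "metric_series"
  )
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("Metric series: %s vs %s (%d trials)\n",
              x$metric, x$xlab, x$n_trials))
  print(data.frame(x = x$x, mean = signif(x$mean, 4),
                   sd = signif(x$sd, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.metric_series <- function(x, ...,
                                        what = c("summary", "trials")) {
  what <- match.arg(what)
  if (what == "summary") {
    data.frame(x = x$x, mean = x$mean, sd = x$sd, n = x$n_trials)
  } else {
    data.frame(x = rep(x$x, each = nrow(x$trials)),
               trial = rep(seq_len(nrow(x$trials)), length(x$x)),
               value = as.vector(x$trials))
  }
}

#' @export
plot.metric_series <- function(x, ...) {
  graphics::plot(x$x, x$mean, type = "b", pch = 16,
                 xlab = x$xlab, ylab = x$metric,
                 ylim = range(c(x$mean - x$sd, x$mean + x$sd)), ...)
  segments(x$x, x$mean - x$sd, x$x, x$mean + x$sd)
  invisible(x)
}
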