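#' Model parameters for the antennal lobe network
#'
#' Collects every scalar constant of the model in one validated record:
#' membrane and kernel time constants, reversal potentials, synaptic and
#' stimulus coupling strengths, the SK-current strength distribution,
#' network geometry, connection probabilities, input rates, stimulus
#' envelope time constants, and the dimensionless multipliers used for
#' conductance-strength sweeps.
#'
#' Voltages are nondimensional (leak/reset at 0, spike threshold at 1,
#' excitatory reversal 14/3, inhibitory/SK reversal -2/3); times are in ms;
#' input rates in spikes/ms; conductances in 1/ms.
#'
#' @param tau_V membrane leak time constant (ms).
#' @param V_L leak/reset potential.
#' @param V_thres spike threshold.
#' @param tau_ref absolute refractory period (ms); the potential is held at
#'   `V_L` for this long after each spike.
#' @param V_exc,V_stim excitatory and stimulus reversal potentials.
#' @param V_inh,V_SK inhibitory and SK reversal potentials.
#' @param S_PN_to_PN,S_PN_to_LN excitatory (cholinergic) coupling strength of
#'   a PN onto a postsynaptic PN or LN.
#' @param S_inh_PN,S_inh_LN fast (GABA-A-like) inhibitory strength onto a PN
#'   or LN.
#' @param S_slow_PN,S_slow_LN slow (GABA-B-like) inhibitory strength onto a
#'   PN or LN.
#' @param S_stim_PN,S_stim_LN stimulus (external input) strength onto a PN or
#'   LN.
#' @param tau_exc,tau_inh,tau_stim fast kernel time constants (ms).
#' @param tau_slow slow inhibition time constant (ms).
#' @param tau_SK SK current decay time constant (ms).
#' @param tau_SK_rise SK sigmoidal half-rise time (ms); the sigmoidal branch
#'   lasts `2 * tau_SK_rise`.
#' @param SK_mu,SK_sigma mean and standard deviation of the per-PN Gaussian
#'   SK strength distribution (negative draws are clamped to 0).
#' @param n_glomeruli,n_PN_per_glom,n_LN_per_glom network geometry.
#' @param p_PN_PN,p_PN_LN,p_LN_PN_intra,p_LN_LN intra-glomerular connection
#'   probabilities per ordered cell pair.
#' @param p_LN_PN_cross cross-glomerular LN to PN connection probability (the
#'   only synapse class that crosses glomeruli).
#' @param lambda_back background input rate (spikes/ms), delivered to every
#'   cell at all times.
#' @param lambda_odor_max,lambda_mech_max peak odor and mechanosensory input
#'   rates (spikes/ms).
#' @param tau_odor_rise_PN odor envelope sigmoidal half-rise time for PNs
#'   (ms); odor rise is instantaneous for LNs.
#' @param tau_mech_rise_LN mechanosensory envelope sigmoidal half-rise time
#'   for LNs (ms); mechanosensory rise is instantaneous for PNs.
#' @param tau_env_decay stimulus envelope decay time constant (ms), common to
#'   odor and mechanosensory input and both cell classes.
#' @param scale_SK,scale_inh,scale_slow,scale_exc,scale_stim dimensionless
#'   multipliers on the corresponding strengths (1 = standard model), used by
#'   the conductance-strength sweeps. `scale_SK` is applied when the network
#'   is built; the others are applied at simulation time.
#'
#' @return An object of class `al_params` (a named list).
#' @examples
#' p <- al_params()
#' p$tau_slow
#' al_params(scale_SK = 2)$scale_SK
#' @export
al_params <- function(tau_V = 20, V_L = 0, V_thres = 1, tau_ref = 2,
                      V_exc = 14 / 3, V_stim = 14 / 3,
                      V_inh = -2 / 3, V_SK = -2 / 3,
                      S_PN_to_PN = 0.01, S_PN_to_LN = 0.006,
                      S_inh_PN = 0.0169, S_inh_LN = 0.015,
                      S_slow_PN = 0.0338, S_slow_LN = 0.04,
                      S_stim_PN = 0.004, S_stim_LN = 0.0031,
                      tau_exc = 2, tau_inh = 2, tau_stim = 2, tau_slow = 750,
                      tau_SK = 250, tau_SK_rise = 25,
                      SK_mu = 0.5, SK_sigma = 0.2,
                      n_glomeruli = 6, n_PN_per_glom = 10, n_LN_per_glom = 6,
                      p_PN_PN = 0.75, p_PN_LN = 0.75, p_LN_PN_intra = 0.38,
                      p_LN_LN = 0.25, p_LN_PN_cross = 0.38,
                      lambda_back = 3.6, lambda_odor_max = 3.6,
                      lambda_mech_max = 1.8,
                      tau_odor_rise_PN = 35, tau_mech_rise_LN = 300,
                      tau_env_decay = 384,
                      scale_SK = 1, scale_inh = 1, scale_slow = 1,
                      scale_exc = 1, scale_stim = 1) {
  p <- as.list(environment())
  structure(validate_al_params(p), class = "al_params")
}

validate_al_params <- function(p) {
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", field, "' must be a single finite number",
           call. = FALSE)
    }
    v
  }
  for (f in names(p)) num1(f)
  for (f in c("tau_V", "tau_ref", "tau_exc", "tau_inh", "tau_stim",
              "tau_slow", "tau_SK", "tau_SK_rise", "tau_odor_rise_PN",
              "tau_mech_rise_LN", "tau_env_decay")) {
    if (p[[f]] <= 0) stop("time constant '", f, "' must be > 0", call. = FALSE)
  }
  for (f in c("p_PN_PN", "p_PN_LN", "p_LN_PN_intra", "p_LN_LN",
              "p_LN_PN_cross")) {
    if (p[[f]] < 0 || p[[f]] > 1) {
      stop("connection probability '", f, "' must lie in [0, 1]",
           call. = FALSE)
    }
  }
  for (f in c("lambda_back", "lambda_odor_max", "lambda_mech_max",
              "SK_sigma", "scale_SK", "scale_inh", "scale_slow",
              "scale_exc", "scale_stim")) {
    if (p[[f]] < 0) stop("parameter '", f, "' must be >= 0", call. = FALSE)
  }
  for (f in c("n_glomeruli", "n_PN_per_glom", "n_LN_per_glom")) {
    if (p[[f]] < 1 || p[[f]] != round(p[[f]])) {
      stop("count '", f, "' must be a positive integer", call. = FALSE)
    }
    p[[f]] <- as.integer(p[[f]])
  }
  if (!(p$V_L < p$V_thres && p$V_thres < p$V_exc)) {
    stop("reversal ordering violated: need V_L < V_thres < V_exc ",
         "(fields 'V_L', 'V_thres', 'V_exc')", call. = FALSE)
  }
  if (p$V_inh >= p$V_L) {
    stop("parameter 'V_inh' must be below the leak potential 'V_L'",
         call. = FALSE)
  }
  p
}

#' @export
print.al_params <- function(x, ...) {
  cat("Antennal lobe model parameters\n")
  cat(sprintf("  %d glomeruli x (%d PN + %d LN) = %d neurons\n",
              x$n_glomeruli, x$n_PN_per_glom, x$n_LN_per_glom,
              x$n_glomeruli * (x$n_PN_per_glom + x$n_LN_per_glom)))
  cat(sprintf("  membrane: tau_V = %g ms, threshold %g, refractory %g ms\n",
              x$tau_V, x$V_thres, x$tau_ref))
  cat(sprintf("  rates: back %g, odor max %g, mech max %g spikes/ms\n",
              x$lambda_back, x$lambda_odor_max, x$lambda_mech_max))
  scales <- c(SK = x$scale_SK, inh = x$scale_inh, slow = x$scale_slow,
              exc = x$scale_exc, stim = x$scale_stim)
  if (any(scales != 1)) {
    cat("  non-standard strength multipliers:",
        paste(sprintf("%s=%g", names(scales)[scales != 1],
                      scales[scales != 1]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read model parameters from a YAML or JSON configuration file
#'
#' The file holds a flat mapping whose keys mirror the [al_params()]
#' argument names; unknown keys are rejected so that typos do not silently
#' fall back to defaults.
#'
#' @param path path to a YAML (or JSON, which YAML subsumes) file.
#' @return An `al_params` object.
#' @export
al_params_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping of parameter names")
  unknown <- setdiff(names(cfg), names(formals(al_params)))
  if (length(unknown)) {
    stop("unknown parameter field(s) in config: ",
         paste(unknown, collapse = ", "))
  }
  do.call(al_params, cfg)
}
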