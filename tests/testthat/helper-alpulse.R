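# A one-glomerulus, one-PN/one-LN circuit with deterministic wiring
# (every allowed synapse present) used for exact kernel-sum checks.
tiny_params <- function(...) {
  defaults <- list(n_glomeruli = 1, n_PN_per_glom = 1, n_LN_per_glom = 1,
                   p_PN_PN = 1, p_PN_LN = 1, p_LN_PN_intra = 1,
                   p_LN_LN = 1, p_LN_PN_cross = 1)
  do.call(al_params, utils::modifyList(defaults, list(...)))
}

# A silent variant: no external input, no synapses, no SK, used for
# closed-form membrane checks on isolated neurons.
silent_params <- function(...) {
  tiny_params(lambda_back = 0, SK_mu = 0, SK_sigma = 0,
              p_PN_PN = 0, p_PN_LN = 0, p_LN_PN_intra = 0, p_LN_LN = 0,
              p_LN_PN_cross = 0, ...)
}

standard_sched_4hz <- function(n_pulses = 12) {
  pulse_train(4, n_pulses, pulse_ms = 50, t_start = 500)
}
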