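test_that("synaptic and SK kernels match their closed forms", {
  expect_equal(alpha_kernel(0, 2), 0.5)
  expect_equal(alpha_kernel(2, 2), 0.5 * exp(-1))
  expect_equal(alpha_kernel(-1, 2), 0)
  # unit integral (trapezoid on a fine grid)
  tg <- seq(0, 60, by = 0.001)
  expect_equal(sum(alpha_kernel(tg, 2)) * 0.001, 1, tolerance = 1e-3)

  expect_equal(sk_kernel(25, 250, 25), 0.5 / 250)
  # sigmoid branch holds up to exactly 2*tau_rise, exponential just after
  expect_equal(sk_kernel(50, 250, 25), plogis(5) / 250)
  expect_equal(sk_kernel(50 + 1e-9, 250, 25), 1 / 250, tolerance = 1e-6)
  expect_equal(sk_kernel(50 + 250, 250, 25), exp(-1) / 250)
  expect_equal(sk_kernel(-5, 250, 25), 0)
})

test_that("an input-free neuron decays with the leak time constant", {
  net <- al_network(silent_params(), seed = 1)
  pr <- stim_protocol("background", duration = 100, n_glomeruli = 1)
  sim <- al_simulate(net, pr, stim_seed = 1, record = 1:2, v_init = 0.5)
  expect_equal(nrow(sim$raster), 0)
  v20 <- sim$traces$V[200, ]  # t = 20 ms = tau_V
  expect_equal(unname(v20), rep(0.5 * exp(-1), 2), tolerance = 3e-3)
})

test_that("clamped-drive firing matches a fine-grid oracle and refractoriness", {
  g <- 0.03
  p <- silent_params()
  net <- al_network(p, seed = 1)
  pr <- stim_protocol("background", duration = 400, n_glomeruli = 1)
  sim <- al_simulate(net, pr, stim_seed = 1, stim_clamp = g, record = 1)

  # closed form: dV/dt = -(1/tau_V + g) V + g V_exc from V = 0
  v_inf <- g * p$V_exc / (1 / p$tau_V + g)
  t_cross <- -1 / (1 / p$tau_V + g) * log(1 - p$V_thres / v_inf)
  # independent fine-grid Euler oracle (dt = 0.001 ms)
  euler_cross <- function(dt) {
    v <- 0; t <- 0
    while (v < p$V_thres) {
      v <- v + dt * (-(v - p$V_L) / p$tau_V - g * (v - p$V_exc))
      t <- t + dt
    }
    t
  }
  expect_equal(euler_cross(0.001), t_cross, tolerance = 1e-3)

  isi <- diff(spike_times(sim, 1))
  expect_true(all(abs(isi - (p$tau_ref + t_cross)) < 0.3))
  # refractory period: ISIs can never be below tau_ref, and the membrane
  # is pinned at the reset potential for tau_ref after each spike
  expect_true(all(isi >= p$tau_ref))
  k1 <- round(spike_times(sim, 1)[1] / 0.1)
  expect_true(all(sim$traces$V[(k1 + 1):(k1 + 20), 1] == 0))
})

test_that("conductance accumulators equal the explicit kernel sums", {
  p <- tiny_params(SK_sigma = 0)  # SK strength exactly 0.5 on the PN
  net <- al_network(p, seed = 2)
  dt <- 0.1
  n_steps <- 3000L
  # canned external input: strong enough to make both cells spike
  ext <- matrix(0L, 2, n_steps)
  set.seed(99)
  ext[1, ] <- rpois(n_steps, 0.6)
  ext[2, ] <- rpois(n_steps, 0.5)
  pr <- stim_protocol("background", duration = n_steps * dt,
                      n_glomeruli = 1)
  sim <- al_simulate(net, pr, stim_seed = 1, record = 1:2,
                     ext_counts = ext)
  expect_gt(nrow(sim$raster), 5)
  expect_true(all(sim$raster$neuron %in% 1:2))

  kgrid <- seq_len(n_steps)
  decay_sum <- function(event_steps, jumps, tau) {
    out <- numeric(n_steps)
    for (i in seq_along(event_steps)) {
      s <- event_steps[i]
      out[s:n_steps] <- out[s:n_steps] +
        jumps[i] * exp(-((s:n_steps) - s) * dt / tau)
    }
    out
  }
  pn_spk <- round(spike_times(sim, 1) / dt)  # PN is neuron 1
  ln_spk <- round(spike_times(sim, 2) / dt)
  for (j in 1:2) {
    is_pn <- j == 1
    # external events in bin k act at step k
    ev <- rep(kgrid, ext[j, ])
    S_stim <- if (is_pn) p$S_stim_PN else p$S_stim_LN
    g_stim_ref <- decay_sum(ev, rep(S_stim / p$tau_stim, length(ev)),
                            p$tau_stim)
    expect_equal(sim$traces$g_stim[, j], g_stim_ref, tolerance = 1e-10)
    # presynaptic spikes at step s act from step s + 1
    if (j == 2) {
      pre_exc <- pn_spk[pn_spk < n_steps]
      g_exc_ref <- decay_sum(pre_exc + 1,
                             rep(p$S_PN_to_LN / p$tau_exc,
                                 length(pre_exc)), p$tau_exc)
      expect_equal(sim$traces$g_exc[, j], g_exc_ref, tolerance = 1e-10)
    }
    if (j == 1) {
      pre_inh <- ln_spk[ln_spk < n_steps]
      g_inh_ref <- decay_sum(pre_inh + 1,
                             rep(p$S_inh_PN / p$tau_inh, length(pre_inh)),
                             p$tau_inh)
      g_slow_ref <- decay_sum(pre_inh + 1,
                              rep(p$S_slow_PN / p$tau_slow,
                                  length(pre_inh)), p$tau_slow)
      expect_equal(sim$traces$g_inh[, j], g_inh_ref, tolerance = 1e-10)
      expect_equal(sim$traces$g_slow[, j], g_slow_ref, tolerance = 1e-10)
      # SK: literal sum of the sigmoidal-rise kernel over own spikes,
      # entering one step after each spike
      g_sk_ref <- numeric(n_steps)
      for (s in pn_spk[pn_spk < n_steps]) {
        k <- (s + 1):n_steps
        g_sk_ref[k] <- g_sk_ref[k] + 0.5 * sk_kernel((k - s) * dt,
                                                     p$tau_SK,
                                                     p$tau_SK_rise)
      }
      expect_equal(sim$traces$g_SK[, j], g_sk_ref, tolerance = 1e-10)
    }
  }
})

test_that("identical seeds give byte-identical simulations", {
  net <- al_network(seed = 4)
  sched <- standard_sched_4hz(4)
  pr <- stim_protocol("additive", sched, duration = 2000)
  a <- al_simulate(net, pr, stim_seed = 11)
  b <- al_simulate(net, pr, stim_seed = 11)
  expect_identical(a$raster, b$raster)
  expect_false(identical(a$raster,
                         al_simulate(net, pr, stim_seed = 12)$raster))
})

test_that("membrane potentials stay within the reversal bounds", {
  net <- al_network(seed = 4)
  sched <- standard_sched_4hz(4)
  pr <- stim_protocol("additive", sched, duration = 1500)
  sim <- al_simulate(net, pr, stim_seed = 3, record = c(1, 31, 61, 96))
  v <- sim$traces$V
  expect_true(all(v >= -2 / 3 - 1e-6))
  expect_true(all(v <= 14 / 3 + 1e-6))
  # refractoriness holds for every neuron of the full network
  isi_ok <- tapply(sim$raster$time, sim$raster$neuron,
                   function(tt) all(diff(sort(tt)) >= 2))
  expect_true(all(isi_ok))
})

test_that("strengthening slow inhibition never adds PN spikes on fixed input", {
  sched <- standard_sched_4hz(6)
  pr <- stim_protocol("odor_only", sched, duration = 2500)
  net1 <- al_network(seed = 6)
  base <- al_simulate(net1, pr, stim_seed = 21, return_inputs = TRUE)
  net2 <- al_network(al_params(scale_slow = 2), seed = 6)
  expect_identical(net1$edges, net2$edges)  # same wiring, scaled strengths
  strong <- al_simulate(net2, pr, stim_seed = 21,
                        ext_counts = base$ext_counts)
  n_pn <- function(s) sum(s$raster$class == "PN")
  expect_lte(n_pn(strong), n_pn(base))
})

test_that("durations that are not multiples of dt are rounded down with a warning", {
  net <- al_network(silent_params(), seed = 1)
  pr <- stim_protocol("background", duration = 100.05, n_glomeruli = 1)
  expect_warning(sim <- al_simulate(net, pr, stim_seed = 1), "rounding")
  expect_equal(sim$duration, 100)
})
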