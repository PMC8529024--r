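# small problem sizes throughout: these tests exercise structure, seed
# policy and bookkeeping, not the scientific claims (see test-acceptance.R)

test_that("probe selection picks a representative PN of the right glomerulus", {
  net <- al_network(seed = 1)
  po <- probe_neuron(net, "odor")
  pq <- probe_neuron(net, "non_odor")
  nn <- net$neurons
  expect_equal(nn$class[po], "PN")
  expect_equal(nn$glomerulus[po], 1)
  expect_equal(nn$class[pq], "PN")
  expect_equal(nn$glomerulus[pq], 4)
  # representative: SK strength within the glomerulus's interquartile-ish
  # band, never an extreme cell
  sk1 <- nn$sk_strength[nn$class == "PN" & nn$glomerulus == 1]
  expect_gt(nn$sk_strength[po], min(sk1))
  expect_lt(nn$sk_strength[po], max(sk1))
  # deterministic
  expect_identical(probe_neuron(net, "odor"), po)
  net2 <- al_network(al_params(n_glomeruli = 2), seed = 1)
  expect_error(probe_neuron(net2, "non_odor"), "glomerulus 4")
})

test_that("frequency experiments return consistent, reproducible series", {
  net <- al_network(seed = 2)
  r1 <- run_frequency_experiment(net, "additive", freqs = c(3, 5),
                                 n_trials = 3, train_ms = 1500,
                                 pre_ms = 300, post_ms = 300,
                                 stim_seed0 = 77L)
  expect_named(r1$index, c("odor", "non_odor"))
  expect_equal(r1$index$odor$n_trials, 3)
  expect_equal(dim(r1$index$odor$trials), c(3, 2))
  expect_equal(r1$index$odor$mean, colMeans(r1$index$odor$trials))
  expect_true(all(unlist(lapply(r1$index, function(m) m$trials)) >= 0))
  # full reproducibility from the seed block
  r2 <- run_frequency_experiment(net, "additive", freqs = c(3, 5),
                                 n_trials = 3, train_ms = 1500,
                                 pre_ms = 300, post_ms = 300,
                                 stim_seed0 = 77L)
  expect_identical(r1$index$odor$trials, r2$index$odor$trials)
  # too few pulses is a configuration error
  expect_error(run_frequency_experiment(net, "additive", freqs = 1,
                                        n_trials = 1, train_ms = 1000),
               "fewer than 2 pulses")
})

test_that("length sweeps measure responses against the pulse grid", {
  net <- al_network(seed = 2)
  sw <- run_length_sweep(net, "odor_only", pulse_lengths = c(100, 200, 300),
                         n_trials = 3, post_ms = 600, stim_seed0 = 5L)
  expect_equal(sw$length$x, c(100, 200, 300))
  expect_equal(dim(sw$length$trials), c(3, 3))
  expect_true(all(sw$length$trials >= 0))
  expect_equal(length(sw$slope$trials), 3)
  # per-trial slopes are the OLS fits of that trial's lengths
  expect_equal(sw$slope$trials[1, 1],
               response_slope(sw$pulse_lengths, sw$length$trials[1, ]))
})

test_that("conductance sweeps rebuild scaled networks on one structural seed", {
  sw <- run_conductance_sweep("SK", "slope", multipliers = c(0.5, 1, 2),
                              scenario = "odor_only", net_seed = 9,
                              n_trials = 2, pulse_lengths = c(100, 250, 400),
                              post_ms = 600)
  expect_equal(sw$multipliers, c(0.5, 1, 2))
  expect_equal(dim(sw$slope$trials), c(2, 3))
  expect_error(run_conductance_sweep("SK", "slope", multipliers = c(-1, 1)),
               "non-negative")
  # the same structural seed gives identical wiring at every grid point
  n1 <- al_network(al_params(scale_SK = 0.5), seed = 9)
  n2 <- al_network(al_params(scale_SK = 2), seed = 9)
  expect_identical(n1$edges, n2$edges)
  expect_equal(n1$neurons$sk_strength / 0.5, n2$neurons$sk_strength / 2)
})

test_that("an all-zero odor gain reduces the graded paradigm to background", {
  net <- al_network(seed = 3)
  g <- run_graded_odor(net, "odor_only", freqs = c(3, 6), n_trials = 8,
                       odor_gain = rep(0, 6), train_ms = 1500,
                       pre_ms = 300, post_ms = 300, stim_seed0 = 11L)
  expect_length(g$rate, 6)
  expect_true(all(g$rate == 0))
})

test_that("synthetic rasters have the advertised structure", {
  sched <- standard_sched_4hz(8)
  r <- make_synthetic_raster("pulse_locked", sched, 3000, n_trains = 3,
                             seed = 7)
  expect_length(r, 3)
  expect_true(all(vapply(r, function(s) !is.unsorted(s), logical(1))))
  expect_identical(r, make_synthetic_raster("pulse_locked", sched, 3000,
                                            n_trains = 3, seed = 7))
  # in-pulse rate dominates for the locked kind
  in_pulse <- function(s) any(s >= sched$t_on[1] & s < sched$t_off[1])
  expect_true(in_pulse(r[[1]]))
  expect_length(make_synthetic_raster("empty", sched, 3000)[[1]], 0)
  ton <- make_synthetic_raster("tonic", sched, 3000)[[1]]
  expect_equal(length(unique(round(diff(ton), 9))), 1)  # regular ISIs
})
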