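test_that("pulse schedules validate and derive period and duration", {
  s <- pulse_train(4, 8, 50, 500)
  expect_equal(nrow(s), 8)
  expect_equal(attr(s, "period"), 250)
  expect_equal(attr(s, "pulse_ms"), 50)
  expect_error(pulse_schedule(100, 100), "t_on < t_off")
  expect_error(pulse_schedule(c(0, 40), c(50, 90)), "overlap")
  expect_error(pulse_train(25, 3, pulse_ms = 50), "shorter than the period")
})

test_that("envelope branch values match the closed forms", {
  on <- 500
  # odor to PN: sigmoid toe at onset, plateau after 2*35 ms
  expect_equal(odor_envelope(on, on, on + 200, "PN"),
               exp(-5) / (1 + exp(-5)), tolerance = 1e-12)
  expect_equal(odor_envelope(on + 35, on, on + 200, "PN"), 0.5)
  expect_equal(odor_envelope(on + 100, on, on + 200, "PN"), 1)
  # common exponential decay: one time constant after offset
  for (cls in c("PN", "LN")) {
    expect_equal(odor_envelope(on + 200 + 384, on, on + 200, cls),
                 exp(-1), tolerance = 1e-12)
    expect_equal(mech_envelope(on + 700 + 384, on, on + 700, cls),
                 exp(-1), tolerance = 1e-12)
  }
  # odor to LN and mech to PN rise instantaneously
  expect_equal(odor_envelope(on, on, on + 200, "LN"), 1)
  expect_equal(mech_envelope(on, on, on + 50, "PN"), 1)
  # mech to LN: sigmoid half-rise at 300 ms
  expect_equal(mech_envelope(on + 300, on, on + 700, "LN"), 0.5)
  # 50 ms pulse never reaches the LN plateau; sigmoid value at offset
  expect_equal(mech_envelope(on + 50, on, on + 50, "LN"),
               plogis(5 * (50 - 300) / 300), tolerance = 1e-12)
  expect_equal(mech_envelope(on + 50, on, on + 50, "LN"), 0.0153,
               tolerance = 1e-2)
  # zero before onset
  expect_equal(odor_envelope(on - 1, on, on + 200, "PN"), 0)
})

test_that("envelopes stay in [0,1] and decay monotonically once past the rise window", {
  on <- 200
  t <- seq(0, 4000, by = 0.5)
  for (off in c(on + 50, on + 400)) {
    for (cls in c("PN", "LN")) {
      for (env in list(odor_envelope, mech_envelope)) {
        v <- env(t, on, off, cls)
        expect_true(all(v >= 0 & v <= 1))
        # after both the offset and the full rise, decay is monotone
        tail_v <- v[t > max(off, on + 2 * 300)]
        expect_true(all(diff(tail_v) <= 0))
      }
    }
  }
})

test_that("total rates combine background, odor and mech terms per class", {
  pr_bg <- stim_protocol("background", duration = 1000)
  expect_equal(total_rate("PN", 1, c(1, 500, 999), pr_bg), rep(3.6, 3))

  sched <- pulse_schedule(500, 700)
  pr_add <- stim_protocol("additive", sched, duration = 2000)
  # on the plateau an odor-receiving PN sees back + odor + mech
  expect_equal(total_rate("PN", 1, 600, pr_add), 3.6 + 3.6 + 1.8)
  # a non-odor PN sees back + mech only
  expect_equal(total_rate("PN", 4, 600, pr_add), 3.6 + 1.8)
  # odor_only protocol zeroes the mech term, mech_only zeroes odor
  pr_odor <- stim_protocol("odor_only", sched, duration = 2000)
  expect_equal(total_rate("PN", 1, 600, pr_odor), 7.2)
  pr_mech <- stim_protocol("mech_only", sched, duration = 2000)
  expect_equal(total_rate("PN", 1, 600, pr_mech), 5.4)
})

test_that("the additive scenario is the literal sum of the pulse drives", {
  sched <- pulse_train(4, 6, 50, 300)
  mk <- function(sc) stim_protocol(sc, sched, duration = 3000)
  t <- seq(0, 3000, by = 7)
  for (cls in c("PN", "LN")) {
    for (g in c(1, 5)) {
      lhs <- total_rate(cls, g, t, mk("additive"))
      rhs <- total_rate(cls, g, t, mk("odor_only")) +
        total_rate(cls, g, t, mk("mech_only")) - 3.6
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("scenario gating forces odor gains to zero where required", {
  sched <- pulse_schedule(100, 150)
  pr <- stim_protocol("mech_only", sched, duration = 500,
                      odor_gain = rep(1, 6))
  expect_true(all(pr$odor_gain == 0))
  expect_error(stim_protocol("odor_only", sched, duration = 500,
                             odor_gain = rep(2, 6)), "odor_gain")
  expect_error(stim_protocol("odor_only", duration = 500), "schedule")
})

test_that("sampled input trains realize the programmed Poisson rate", {
  totals <- vapply(1:20, function(s)
    length(sample_input_train(3.6, 1000, dt = 0.1, seed = s)), numeric(1))
  # per-train sd is sqrt(3600) = 60; the mean of 20 has se ~13.4
  expect_lt(abs(mean(totals) - 3600), 3 * 60 / sqrt(20))

  expect_identical(sample_input_train(2, 500, seed = 9),
                   sample_input_train(2, 500, seed = 9))
  expect_length(sample_input_train(0, 1000, seed = 1), 0)
  expect_error(sample_input_train(-1, 100, seed = 1), "negative")

  # time-varying rate is recovered bin by bin (z-scores of binned counts)
  rate_fn <- function(t) 3.6 + 3.6 * odor_envelope(t, 200, 400, "PN")
  binw <- 100
  exp_counts <- vapply(seq(0, 1900, binw), function(b)
    sum(rate_fn(seq(b, b + binw - 0.1, 0.1)) * 0.1), numeric(1))
  obs <- matrix(0, 30, length(exp_counts))
  for (s in 1:30) {
    tr <- sample_input_train(rate_fn, 2000, seed = 100 + s)
    obs[s, ] <- tabulate(floor(tr / binw) + 1, nbins = length(exp_counts))
  }
  z <- (colMeans(obs) - exp_counts) / sqrt(exp_counts / 30)
  expect_lt(mean(z^2), 2)   # consistent with unit-variance z-scores
  expect_true(all(abs(z) < 5))
})
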