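test_that("noiseless input recovers the generating parameters", {
  truth <- decay_params(1e8, 0.7, 1.4, 2.9, offset = 50)
  h <- noiseless_histogram(truth, irf256)
  fit <- fit_decay(h, irf256)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$tau1_ns - 1.4) / 1.4, 1e-4)
  expect_lt(abs(fit$params$tau2_ns - 2.9) / 2.9, 1e-4)
  expect_lt(abs(fit$params$fraction - 0.7), 1e-4)
})

test_that("single-component simulated nuclei recover the true lifetime within 1%", {
  truth <- decay_params(5e5, 1, 2.79, 2.79, offset = 2)
  for (s in 1:3) {
    h <- simulate_histogram(truth, irf256, 1, seed = 100 + s)
    fit <- fit_decay(h, irf256)
    expect_lt(abs(fit$mean_lifetime_amp_ns - 2.79) / 2.79, 0.01)
  }
})

test_that("pure-background input is flagged degenerate, not an error", {
  set.seed(5)
  h <- decay_histogram(stats::rpois(256, 40), bin256)
  fit <- suppressWarnings(fit_decay(h, irf256))
  expect_true(fit$degenerate)
})

test_that("two-component recovery is accurate and unbiased over 50 nuclei", {
  truth <- decay_params(5e5, 0.7, 1.4, 2.9, offset = 0.02 * 5e5 / 256)
  tau_true <- mean_lifetime(truth)
  err <- vapply(1:50, function(s) {
    h <- simulate_histogram(truth, irf256, 1, seed = 7000 + s)
    fit_decay(h, irf256)$mean_lifetime_amp_ns / tau_true - 1
  }, 0)
  expect_lt(stats::median(abs(err)), 0.015)
  # sign tests reject a median bias beyond +/-0.5%
  expect_gt(stats::binom.test(sum(err > 0.005), 50, alternative = "greater")$p.value, 0.05)
  expect_gt(stats::binom.test(sum(err < -0.005), 50, alternative = "greater")$p.value, 0.05)
})

test_that("the optimum is never worse than the generating parameters", {
  cfg <- fit_config()
  for (s in 1:5) {
    truth <- decay_params(2e5, 0.6, 1.1 + 0.1 * s, 3.0, offset = 1)
    h <- simulate_histogram(truth, irf256, 1, seed = 300 + s)
    fit <- fit_decay(h, irf256, cfg)
    at_truth <- flimreach:::fit_objective_fun(h$counts, irf256, cfg$objective)(
      c(truth$amplitude, truth$fraction, truth$tau1_ns, truth$tau2_ns, truth$offset))
    expect_lte(fit$objective_value, at_truth + 1e-6)
  }
})

test_that("Poisson MLE and weighted least squares agree at high counts", {
  truth <- decay_params(1e6, 1, 2.79, 2.79, offset = 5)
  h <- simulate_histogram(truth, irf256, 1, seed = 77)
  mle <- fit_decay(h, irf256, fit_config(objective = "poisson_mle"))
  wls <- fit_decay(h, irf256, fit_config(objective = "weighted_least_squares"))
  expect_lt(abs(mle$mean_lifetime_amp_ns - wls$mean_lifetime_amp_ns) /
              mle$mean_lifetime_amp_ns, 0.02)
})

test_that("IRF shifting is exact on whole bins and bounded on fractional bins", {
  w <- irf128$weights
  one_bin_ps <- 1000 * bin128$bin_width_ns

  expect_equal(shift_irf(irf128, 0)$weights, w)
  shifted <- shift_irf(irf128, one_bin_ps)
  expect_equal(shifted$weights, c(w[128], w[1:127]), tolerance = 1e-12)

  # integer-bin round trip is exact
  rt <- shift_irf(shift_irf(irf128, 3 * one_bin_ps), -3 * one_bin_ps)
  expect_lt(sum(abs(rt$weights - w)), 1e-9)

  # sub-bin round trip smooths: each interpolation pass mixes 2 f (1 - f)
  # of mass into neighbors, so the L1 discrepancy is bounded by twice that
  f <- 17 / one_bin_ps
  rt2 <- shift_irf(shift_irf(irf128, 17), -17)
  expect_lte(sum(abs(rt2$weights - w)), 2 * 2 * f * (1 - f))
  expect_equal(sum(rt2$weights), 1)
  expect_error(shift_irf(irf128, 1e9), "period")
})

test_that("drift search is disabled by max_shift_ps = 0 and finds no drift on clean data", {
  truth <- decay_params(1e8, 1, 2.79, 2.79, offset = 10)
  h <- noiseless_histogram(truth, irf256)
  plain <- fit_decay(h, irf256, fit_config(max_shift_ps = 0))
  off <- correct_irf_drift(h, irf256, fit_config(max_shift_ps = 0))
  expect_identical(off$irf_shift_ps, 0)
  expect_equal(off$fit$objective_value, plain$objective_value)

  # noiseless, undrifted data: the selected shift is 0 within one grid step
  dc <- correct_irf_drift(h, irf256, fit_config(step_ps = 0.5))
  expect_lte(abs(dc$irf_shift_ps), 0.5)
})

test_that("an injected IRF displacement is recovered by the drift search", {
  binning <- time_binning(1024)
  irf <- make_gaussian_irf(300, 2, binning)
  irf_displaced <- shift_irf(irf, 1.5)
  # drift is an instrument property shared by the whole field of view, so
  # it is estimated from pooled counts (~1e7 photons)
  truth <- decay_params(1e7, 1, 2.79, 2.79, offset = 20)
  h <- simulate_histogram(truth, irf_displaced, 1, seed = 21)
  dc <- correct_irf_drift(h, irf, fit_config())
  expect_lt(abs(dc$irf_shift_ps - 1.5), 0.3 + 1e-9)
  expect_equal(dc$fit$irf_shift_ps, dc$irf_shift_ps)
  expect_lt(abs(dc$fit$mean_lifetime_amp_ns - 2.79) / 2.79, 0.01)
})

test_that("mean lifetime reductions are correct and ordered", {
  p <- decay_params(1, 1, 2.2, 5)
  expect_equal(mean_lifetime(p, "amplitude_weighted"), 2.2)
  expect_equal(mean_lifetime(p, "intensity_weighted"), 2.2)

  q <- decay_params(1, 0.5, 1, 3)
  expect_equal(mean_lifetime(q, "amplitude_weighted"), 2.0)
  expect_equal(mean_lifetime(q, "intensity_weighted"), 2.5)

  set.seed(12)
  for (i in 1:20) {
    r <- decay_params(1, stats::runif(1), stats::runif(1, 0.2, 4),
                      stats::runif(1, 0.2, 4))
    expect_gte(mean_lifetime(r, "intensity_weighted"),
               mean_lifetime(r, "amplitude_weighted") - 1e-12)
  }

  # label-swap never changes reported means
  a <- decay_params(1, 0.3, 2.9, 1.4)
  b <- decay_params(1, 0.7, 1.4, 2.9)
  expect_equal(mean_lifetime(a), mean_lifetime(b))
  expect_equal(mean_lifetime(a, "intensity_weighted"),
               mean_lifetime(b, "intensity_weighted"))
})

test_that("group FRET uses group mean lifetimes and tolerates negative estimates", {
  expect_equal(round(100 * estimate_group_fret(2.79, 2.69)$efficiency, 1), 3.6)
  expect_equal(round(100 * estimate_group_fret(2.78, 2.16)$efficiency), 22)
  expect_equal(estimate_group_fret(c(2.7, 2.8), c(2.7, 2.8))$efficiency, 0)

  neg <- estimate_group_fret(c(2.70, 2.72), c(2.80, 2.82))
  expect_equal(neg$efficiency, 0)
  expect_identical(neg$note, "negative_estimate")
  expect_error(estimate_group_fret(numeric(0), 2.7), "non-empty")
})
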