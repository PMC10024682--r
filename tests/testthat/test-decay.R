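test_that("circular convolution matches the direct O(N^2) sum and conserves mass", {
  set.seed(31)
  for (rep in 1:5) {
    s <- stats::runif(64)
    k <- stats::runif(64)
    fast <- convolve_periodic(s, k)
    slow <- convolve_direct(s, k)
    expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-9)
    expect_equal(sum(fast), sum(s) * sum(k))
  }
  # identity kernel
  delta <- c(1, numeric(63))
  s <- stats::runif(64)
  expect_equal(convolve_periodic(s, delta), s)
  expect_error(convolve_periodic(1:4, 1:5), "length mismatch")
})

test_that("forward model reduces to the periodic exponential under a delta IRF", {
  delta_irf <- instrument_response(c(1, numeric(63)), bin64)
  p <- decay_params(1000, 1, 2.5, 2.5, offset = 0)
  mu <- forward_model(p, delta_irf)
  # wrap-sum closed form: per-bin integral of exp(-t/tau)/(1 - exp(-T/tau))
  t0 <- (0:63) * bin64$bin_width_ns
  t1 <- t0 + bin64$bin_width_ns
  expected <- 1000 * (exp(-t0 / 2.5) - exp(-t1 / 2.5)) / (1 - exp(-50 / 2.5))
  expect_equal(mu, expected, tolerance = 1e-12)
})

test_that("forward model totals C, matches a direct-sum oracle, and is label-swap invariant", {
  p <- decay_params(5000, 0.5, 1, 3, offset = 0)
  expect_equal(sum(forward_model(p, irf256)), 5000, tolerance = 1e-9)

  # oracle: direct circular sum of the same bin-integrated decay
  d <- 0.5 * flimreach:::periodic_decay_bins(1, bin256) +
    0.5 * flimreach:::periodic_decay_bins(3, bin256)
  direct <- 5000 * convolve_direct(d, irf256$weights)
  expect_lt(max(abs(forward_model(p, irf256) - direct)) / max(direct), 1e-9)

  swapped <- decay_params(5000, 0.5, 3, 1, offset = 0)
  expect_equal(forward_model(swapped, irf256), forward_model(p, irf256))
  # construction canonicalizes tau1 <= tau2
  q <- decay_params(1, 0.3, 2.9, 1.4)
  expect_equal(c(q$tau1_ns, q$tau2_ns, q$fraction), c(1.4, 2.9, 0.7))
})

test_that("forward model validates its inputs", {
  p <- decay_params(10, 0.5, 1, 3)
  irf_other <- make_gaussian_irf(300, 2, bin64)
  h <- simulate_histogram(p, irf_other, 10, seed = 1)
  expect_error(fit_decay(h, irf256), "binning mismatch")
  expect_error(decay_params(-1, 0.5, 1, 3), "amplitude")
  expect_error(decay_params(1, 1.5, 1, 3), "fraction")
  expect_error(decay_params(1, 0.5, 0, 3), "lifetimes")
})

test_that("Poisson simulation is seeded and unbiased", {
  p <- decay_params(50, 0.4, 1.2, 2.8, offset = 0.05)
  h1 <- simulate_histogram(p, irf256, 1000, seed = 7)
  h2 <- simulate_histogram(p, irf256, 1000, seed = 7)
  expect_identical(h1$counts, h2$counts)

  expected_total <- 1000 * (50 + 256 * 0.05)
  for (s in 1:5) {
    h <- simulate_histogram(p, irf256, 1000, seed = s)
    expect_lt(abs(sum(h$counts) - expected_total), 4 * sqrt(expected_total))
  }

  # law of large numbers: relative deviation from the forward model shrinks
  mu <- forward_model(p, irf256)
  big <- simulate_histogram(p, irf256, 1e5, seed = 3)
  keep <- mu > 1e-3
  expect_lt(max(abs(big$counts[keep] / 1e5 - mu[keep]) / mu[keep]), 0.05)
})

test_that("simulated histograms are calibrated against their own forward model", {
  # chi-square goodness of fit at the 1% level should pass in >= 95% of seeds
  p <- decay_params(20, 0.5, 1, 3, offset = 0.5)
  mu <- 2000 * forward_model(p, irf256)
  pass <- 0L
  for (s in 1:100) {
    h <- simulate_histogram(p, irf256, 2000, seed = s)
    x2 <- sum((h$counts - mu)^2 / mu)
    if (stats::pchisq(x2, df = 256, lower.tail = FALSE) > 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 95L)
})

test_that("FRET quenching algebra matches the two-channel survival model", {
  expect_equal(quenched_lifetime(2.79, Inf), 2.79)
  expect_equal(quenched_lifetime(2.79, 2.79), 1.395)
  # tau' inverted from the lifetime pair (2.79, 2.69): tau0*tau/(tau0 - tau)
  tau_fret <- 2.79 * 2.69 / (2.79 - 2.69)
  expect_equal(tau_fret, 75.051, tolerance = 1e-4)
  expect_equal(quenched_lifetime(2.79, tau_fret), 2.69)
  expect_error(quenched_lifetime(-1, 2), "tau0_ns")
})

test_that("FRET efficiency reproduces the reported donor-quenching values", {
  e1 <- fret_efficiency(2.79, 2.69)
  expect_equal(round(100 * e1$efficiency, 1), 3.6)
  e2 <- fret_efficiency(2.78, 2.16)
  expect_equal(round(100 * e2$efficiency), 22)
  expect_equal(fret_efficiency(2.79, 2.79)$efficiency, 0)
  expect_identical(fret_efficiency(2.79, 2.79)$tau_fret_ns, Inf)
  expect_error(fret_efficiency(2.5, 2.6), "exceeds")
})

test_that("quenching and efficiency round-trip across four decades of tau'", {
  tau0 <- 2.79
  for (tau_fret in 10^seq(-1, 4, length.out = 25)) {
    tau <- quenched_lifetime(tau0, tau_fret)
    out <- fret_efficiency(tau0, tau)
    expect_lt(abs(out$tau_fret_ns - tau_fret) / tau_fret, 1e-9)
    expect_gte(out$efficiency, 0)
    expect_lt(out$efficiency, 1)
  }
  # efficiency strictly decreasing in tau at fixed tau0
  effs <- vapply(seq(0.5, 2.79, length.out = 20),
                 function(t) fret_efficiency(tau0, t)$efficiency, 0)
  expect_true(all(diff(effs) < 0))
})
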