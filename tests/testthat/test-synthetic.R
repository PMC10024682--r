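test_that("Gaussian IRF is normalized with the requested width and center", {
  irf <- make_gaussian_irf(300, 2, bin256)
  expect_equal(sum(irf$weights), 1)

  # FWHM measured on the generated vector, to within one bin
  w <- irf$weights
  half <- max(w) / 2
  above <- which(w >= half)
  fwhm_bins <- max(above) - min(above) + 1
  bin_ps <- 1000 * bin256$bin_width_ns
  expect_lt(abs(fwhm_bins * bin_ps - 300), bin_ps)

  peak_ns <- (which.max(w) - 0.5) * bin256$bin_width_ns
  expect_lt(abs(peak_ns - 2), bin256$bin_width_ns)

  # width far below the bin collapses to a single-bin delta
  d <- make_gaussian_irf(0.01, 2, bin64)
  expect_equal(sort(d$weights, decreasing = TRUE)[1], 1)
  expect_error(make_gaussian_irf(-5, 2, bin64), "fwhm_ps")
  expect_error(make_gaussian_irf(300, 60, bin64), "period")
})

test_that("per-cell decay parameters encode partial donor-acceptor pairing", {
  donor <- group_spec("d", 5, 2.79, paired_fraction = 0)
  p0 <- cell_decay_params(donor, 2.79)
  expect_equal(mean_lifetime(p0), 2.79)

  full <- group_spec("f", 5, 2.79, paired_fraction = 1, tau_fret_ns = 2.79)
  p1 <- cell_decay_params(full, 2.79)
  expect_equal(mean_lifetime(p1), 2.79 / 2)

  expect_error(group_spec("bad", 5, 2.79, paired_fraction = 0.5), "tau_fret_ns")
})

test_that("solve_tau_fret hits a target ensemble efficiency, round trip", {
  tau0 <- 2.79
  f <- 0.35
  tau_fret <- solve_tau_fret(tau0, f, target_efficiency = 0.036)
  spec <- group_spec("g", 1, tau0, paired_fraction = f, tau_fret_ns = tau_fret)
  p <- cell_decay_params(spec, tau0)
  ens_eff <- (tau0 - mean_lifetime(p)) / tau0
  expect_equal(ens_eff, 0.036, tolerance = 1e-9)
  # closed-form check: E = f tau0 / (tau0 + tau')
  expect_equal(f * tau0 / (tau0 + tau_fret), 0.036, tolerance = 1e-9)
  expect_error(solve_tau_fret(tau0, 0.02, 0.036), "target_efficiency")
})

test_that("population simulation is reproducible and counter-seeded per cell", {
  spec <- group_spec("g", 4, 2.79, tau0_sd_ns = 0.05, photons_mean = 2e4, seed = 5)
  a <- simulate_population(spec, irf256)
  b <- simulate_population(spec, irf256)
  expect_identical(a$histograms[[2]]$counts, b$histograms[[2]]$counts)
  expect_identical(a$truth, b$truth)

  # growing the population never reshuffles earlier cells
  bigger <- group_spec("g", 7, 2.79, tau0_sd_ns = 0.05, photons_mean = 2e4, seed = 5)
  c3 <- simulate_population(bigger, irf256)
  expect_identical(a$truth$tau0_ns, c3$truth$tau0_ns[1:4])
  expect_identical(a$histograms[[3]]$counts, c3$histograms[[3]]$counts)

  # sd = 0, f = 0: all cells share the same generating truth
  flat <- group_spec("g", 3, 2.79, tau0_sd_ns = 0, photons_mean = 2e4, seed = 1)
  tf <- simulate_population(flat, irf256)$truth
  expect_true(all(tf$tau0_ns == 2.79))
  expect_true(all(tf$efficiency == 0))
})

test_that("donor-only population recovers its generating lifetime end to end", {
  spec <- group_spec("donor_only", 40, 2.79, tau0_sd_ns = 0.05,
                     photons_mean = 1e5, seed = 11)
  pop <- simulate_population(spec, irf256)
  cfg <- fit_config(max_shift_ps = 0)
  taus <- vapply(pop$histograms,
                 function(h) fit_decay(h, irf256, cfg)$mean_lifetime_amp_ns, 0)
  g <- group_ci95(taus)
  expect_lt(abs(g$mean - 2.79), g$ci95_half_width)
})

test_that("simulate_experiment writes a complete, self-contained dataset", {
  dir <- withr::local_tempdir()
  groups <- list(
    group_spec("a", 3, 2.79, photons_mean = 1e4, seed = 1),
    group_spec("b", 2, 2.79, paired_fraction = 0.5, tau_fret_ns = 2.79,
               photons_mean = 1e4, seed = 2))
  out <- simulate_experiment(groups, irf256, dir)
  expect_equal(nrow(out$truth), 5)
  expect_true(file.exists(file.path(dir, "irf.txt")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  expect_true(file.exists(file.path(dir, "dataset.json")))
  expect_length(out$files, 5)
  expect_true(all(file.exists(out$files)))

  # histograms round-trip with their annotations
  h <- read_histogram(out$files[1])
  expect_identical(h$meta$group, "a")
  expect_equal(h$binning$n_bins, 256)

  expect_error(simulate_experiment(list(), irf256, dir), "non-empty")
})
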