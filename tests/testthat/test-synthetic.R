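# Synthetic TCSPC generator: determinism, Poisson statistics, IRF shape,
# and study-scenario fixtures.

test_that("simulation is bit-identical under a fixed seed and differs across seeds", {
  a <- small_pair(seed = 7)
  b <- {
    truth <- attr(a, "truth")$parameters
    p <- fret_parameters(f_D = truth$f_D, donor = truth$donor, R0 = truth$R0,
                         rho1 = truth$rho1, shift_irf = truth$shift_irf,
                         A0 = 1, bkgr_dec = truth$bkgr_dec)
    cfg <- simulation_config(p, n_bins = 1024L, total_counts = 1e6, seed = 7)
    simulate_decay(cfg)
  }
  expect_identical(a$sample$counts, b$sample$counts)
  expect_identical(a$irf$counts, b$irf$counts)

  c2 <- small_pair(seed = 8)
  expect_false(identical(a$sample$counts, c2$sample$counts))
  # residual streams across seeds are uncorrelated
  mu <- attr(a, "truth")$expected$values
  r1 <- (a$sample$counts - mu) / sqrt(pmax(mu, 1))
  mu2 <- attr(c2, "truth")$expected$values
  r2 <- (c2$sample$counts - mu2) / sqrt(pmax(mu2, 1))
  expect_lt(abs(cor(r1, r2)), 0.1)
})

test_that("per-bin counts are Poisson: variance tracks the mean", {
  donor <- ref_donor()
  truth <- fret_parameters(f_D = 1, donor = donor, R0 = 43.5,
                           rho1 = distance_distribution(1, 43.5, 2),
                           A0 = 1, bkgr_dec = 2)
  sims <- lapply(1:200, function(s) {
    cfg <- simulation_config(truth, n_bins = 128L, time_window = 25,
                             total_counts = 2e5, seed = 1000L + s)
    simulate_decay(cfg)$sample$counts
  })
  m <- Reduce(`+`, sims) / length(sims)
  v <- Reduce(`+`, lapply(sims, function(x) (x - m)^2)) / (length(sims) - 1)
  keep <- m >= 100
  expect_gt(sum(keep), 20)
  # aggregate variance/mean ratio within 10% of 1
  expect_equal(sum(v[keep]) / sum(m[keep]), 1, tolerance = 0.1)
  # mean of simulations tracks the expected curve within 3 MC standard errors
  mu <- attr(simulate_decay(simulation_config(truth, n_bins = 128L,
                                              time_window = 25,
                                              total_counts = 2e5, seed = 1L)),
             "truth")$expected$values
  se <- sqrt(mu / length(sims))
  expect_lt(mean(abs(m - mu) > 3 * pmax(se, 1e-6)), 0.02)
})

test_that("simulated IRF has the configured width and is deterministic", {
  donor <- ref_donor()
  truth <- fret_parameters(f_D = 1, donor = donor, R0 = 43.5,
                           rho1 = distance_distribution(1, 43.5, 2), A0 = 1)
  cfg <- simulation_config(truth, n_bins = 2048L, total_counts = 1e6,
                           irf_fwhm = 0.5, seed = 3)
  irf <- simulate_irf(cfg)
  expect_identical(irf$counts, simulate_irf(cfg)$counts)
  # moment estimate of the FWHM on the sampled histogram
  w <- irf$counts / sum(irf$counts)
  mu <- sum(w * irf$time)
  sdev <- sqrt(sum(w * (irf$time - mu)^2))
  expect_equal(sdev * 2 * sqrt(2 * log(2)), 0.5, tolerance = 0.05)

  expect_warning(
    simulation_config(truth, n_bins = 64L, time_window = 50,
                      total_counts = 1e5, irf_fwhm = 0.5, seed = 1),
    class = "tmfret_irf_resolution_warning")
})

test_that("background-only truth gives a flat Poisson trace", {
  donor <- ref_donor()
  truth <- fret_parameters(f_D = 1, donor = donor, R0 = 43.5,
                           rho1 = distance_distribution(1, 43.5, 2),
                           A0 = 0, bkgr_dec = 5)
  cfg <- simulation_config(truth, n_bins = 1024L, total_counts = 0, seed = 9)
  pair <- simulate_decay(cfg)
  m <- mean(pair$sample$counts)
  expect_lt(abs(m - 5), 5 * sqrt(5 / 1024))
  expect_equal(var(pair$sample$counts), 5, tolerance = 0.15)
})

test_that("study fixtures have the declared structure", {
  fx <- cached("hetero_small", {
    make_study_fixture("cterm_hetero_titration", seed = 3,
                       total_counts = 2e5, n_bins = 256L)
  })
  expect_length(fx, 5)
  expect_named(fx, paste0("cAMP_", c(0, 0.5, 1, 2, 320), "uM"))
  # per-condition fractions follow the published binding curve
  f <- attr(fx, "f_A2")
  expect_equal(f[1], 0.08)
  expect_equal(f[5], dose_response(320, 0.22, 1.2, 0.96, 0.08))
  expect_true(all(diff(f) > 0))
  # all five share one measured IRF
  expect_identical(fx[[1]]$irf$counts, fx[[5]]$irf$counts)

  homo <- make_study_fixture("cterm_homo", seed = 3, total_counts = 2e5,
                             n_bins = 256L)
  expect_true(attr(homo, "two_acceptor"))
  expect_false(is.null(attr(homo[[1]], "truth")$parameters$rho2))

  full <- make_study_fixture("full_length", seed = 3, total_counts = 2e5,
                             n_bins = 256L)
  expect_length(full, 6)              # apo + 0.25, 0.5, 1, 2, 320 uM
  expect_true(attr(full, "two_acceptor"))
  f_full <- attr(full, "f_A2")
  expect_equal(f_full[1], 0.41)
  expect_true(all(diff(f_full) > 0))

  expect_error(make_study_fixture("nope"))
})

test_that("fixtures are fittable with reduced chi2 near 1", {
  # end-to-end: the generating family fits its own data (reduced scale)
  pair <- small_pair(seed = 7)
  bf <- small_buffer_fit(pair)
  fit <- cached("fret_small_fit", {
    fit_fret_single(pair, ref_donor(), bf$model, ref_R0(), f_A2 = 0,
                    n_starts = 2, seed = 3)
  })
  expect_gt(fit$reduced_chi2, 0.9)
  expect_lt(fit$reduced_chi2, 1.1)
})
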