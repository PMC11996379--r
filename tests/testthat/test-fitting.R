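# Chi-square computation and the reconvolution fitting protocol.
# Recovery tests run at reduced scale (1024 bins, 1e6 counts); the
# full-scale recoveries live in test-acceptance.R.

test_that("chi2 computes Poisson-weighted residuals", {
  t <- seq(0.5, 16, by = 0.5)
  obs <- decay_histogram(t, rep(100L, length(t)))
  m <- model_curve(t, rep(100, length(t)))
  expect_equal(chi2(obs, m)$chi2, 0)

  # one bin off by 10 with obs = 100: ((10)/sqrt(100))^2 = 1
  v <- rep(100, length(t)); v[5] <- 90
  expect_equal(chi2(obs, model_curve(t, v))$chi2, 1)
  # as-printed rule divides by the counts, not their square root
  expect_equal(chi2(obs, model_curve(t, v), "as-printed")$chi2, 0.01)

  expect_error(chi2(decay_histogram(t, rep(0L, length(t))), m),
               class = "tmfret_degenerate_data_error")
})

test_that("buffer fit recovers a two-component buffer and rejects 5 components", {
  # dedicated bright buffer trace so component lifetimes are identifiable
  n <- 1024L
  truth_p <- fret_parameters(f_D = 1, donor = donor_model(1, 10), R0 = 40,
                             rho1 = distance_distribution(1, 40, 2),
                             A0 = 0, f_B = 1, bkgr_dec = 2)
  cfg <- simulation_config(truth_p, n_bins = n, total_counts = 0, seed = 31)
  irf <- simulate_irf(cfg)
  t <- irf$time
  buf_truth <- buffer_model(c(0.008, 0.004), c(6, 1.5))
  mu <- reconvolve(fret_parameters(f_D = 1, donor = donor_model(1, 10),
                                   R0 = 40,
                                   rho1 = distance_distribution(1, 40, 2),
                                   A0 = 0, f_B = 1, bkgr_dec = 2),
                   numeric(n), buf_truth,
                   model_curve(t, irf$counts))$values
  set.seed(77)
  buf_hist <- decay_histogram(t, rpois(n, mu), role = "buffer",
                              acquisition_time = 60)
  expect_gt(sum(buf_hist$counts), 1e6)

  bf <- fit_buffer(buf_hist, irf, n_components = 2, seed = 3)
  expect_true(bf$convergence$converged)
  # lifetimes recovered within 5% (components sorted by decreasing tau)
  expect_equal(bf$model$tau, c(6, 1.5), tolerance = 0.05)
  expect_lt(abs(bf$reduced_chi2 - 1), 0.15)

  expect_error(fit_buffer(buf_hist, irf, n_components = 5),
               class = "tmfret_spec_error")
  low <- decay_histogram(t, c(rep(0L, n - 16L), rep(1L, 16L)), role = "buffer")
  expect_error(fit_buffer(low, irf), class = "tmfret_precondition_error")
})

test_that("flat buffer trace yields near-zero amplitude and bkgr at the mean", {
  # run at counts high enough that the chi-square weighting is unbiased
  # (Neyman chi-square pulls a Poisson mean toward the harmonic mean at low
  # counts, a property of the stated weighting rule, not a fit failure)
  pair <- small_pair()
  t <- pair$irf$time
  set.seed(5)
  flat <- decay_histogram(t, rpois(length(t), 200), role = "buffer")
  bf <- fit_buffer(flat, pair$irf, n_components = 1, window = "full")
  contribution <- bf$estimates[["alpha_B1"]] * sum(pair$irf$counts)
  expect_lt(contribution, 0.05 * 200)            # amplitude ~ 0
  expect_equal(bf$estimates[["bkgr_dec"]], 200, tolerance = 0.01)
})

test_that("donor-only fit recovers the biexponential lifetimes", {
  fx <- cached("donor_small", {
    make_study_fixture("donor_only", seed = 21, total_counts = 1e6,
                       n_bins = 1024L)
  })
  pair <- fx[[1]]
  res <- cached("donor_small_fit", fit_donor_only(pair, seed = 2))
  expect_equal(res$donor$tau[1], 17.6, tolerance = 0.05)
  expect_equal(res$donor$alpha[1], 0.87, tolerance = 0.05)
  expect_lt(abs(res$fit$reduced_chi2 - 1), 3 * sqrt(2 / res$fit$n_bins) + 0.1)

  expect_error(fit_donor_only(pair$sample), class = "tmfret_precondition_error")
})

test_that("single-decay FRET fit recovers the distance and gives reduced chi2 near 1", {
  pair <- small_pair(seed = 7)        # truth: rbar 41.7, sigma 2.3, f_D 0.15
  bf <- small_buffer_fit(pair)
  fit <- cached("fret_small_fit", {
    fit_fret_single(pair, ref_donor(), bf$model, ref_R0(), f_A2 = 0,
                    n_starts = 2, seed = 3)
  })
  expect_true(fit$convergence$converged)
  expect_equal(fit$estimates$rbar_1, 41.7, tolerance = 0.02)
  expect_equal(fit$estimates$f_D, 0.15, tolerance = 0.35)
  expect_lt(abs(fit$reduced_chi2 - 1), 3 * sqrt(2 / fit$n_bins) + 0.05)
})

test_that("a fully fixed spec evaluates chi-square without optimizing", {
  pair <- small_pair(seed = 7)
  truth <- attr(pair, "truth")
  p <- truth$parameters
  params <- rbind(
    param_spec("f_D", "fixed", p$f_D),
    param_spec("tau_D1", "fixed", p$donor$tau[1]),
    param_spec("alpha_D1", "fixed", p$donor$alpha[1]),
    param_spec("tau_D2", "fixed", p$donor$tau[2]),
    param_spec("R0", "fixed", p$R0),
    param_spec("rbar_1", "fixed", p$rho1$mean[1]),
    param_spec("sigma_1", "fixed", p$rho1$sd[1]),
    param_spec("f_A2", "fixed", 0),
    param_spec("shift_irf", "fixed", p$shift_irf),
    param_spec("A0", "fixed", p$A0),
    param_spec("bkgr_dec", "fixed", p$bkgr_dec),
    param_spec("bkgr_irf", "fixed", 0))
  spec <- fit_spec(pair, params, buffers = truth$buffer)
  fit <- fit_decays(spec)
  expect_identical(fit$n_free, 0L)
  expect_identical(fit$convergence$n_iter, 0L)
  # evaluation at the exact truth: reduced chi2 near 1
  expect_lt(abs(fit$reduced_chi2 - 1), 0.1)
})

test_that("global fit of two identical decays with everything shared matches the single fit", {
  pair <- small_pair(seed = 7)
  bf <- small_buffer_fit(pair)
  single <- cached("fret_small_fit", {
    fit_fret_single(pair, ref_donor(), bf$model, ref_R0(), f_A2 = 0,
                    n_starts = 2, seed = 3)
  })
  glob <- fit_fret_global(
    list(pair, pair), ref_donor(), bf$model, ref_R0(),
    share = c("rbar_1", "sigma_1", "f_D", "shift_irf", "A0", "bkgr_dec"),
    f_A2 = c(0, 0), seed = 3)
  expect_equal(glob$estimates$rbar_1[1], single$estimates$rbar_1,
               tolerance = 1e-4)
  # identical decays: chi2 doubles
  expect_equal(glob$chi2, 2 * single$chi2, tolerance = 1e-3)
})

test_that("global fit with shared distances recovers per-decay fractions", {
  pairs <- cached("global_pairs", {
    lapply(c(101, 102, 103), function(s) {
      fa <- c(0.1, 0.5, 0.9)[s - 100]
      small_pair(seed = s, f_A2 = fa, counts = 1e6, n_bins = 1024L)
    })
  })
  bf <- small_buffer_fit(pairs[[1]])
  fit <- cached("global_fit", {
    fit_fret_global(pairs, ref_donor(), bf$model, ref_R0(),
                    f_A2 = "free", seed = 4,
                    start = list(rbar_1 = 43, rbar_2 = 31))
  })
  expect_true(fit$convergence$converged)
  expect_equal(fit$estimates$rbar_1[1], 41.7, tolerance = 0.03)
  expect_equal(fit$estimates$rbar_2[1], 28.8, tolerance = 0.03)
  expect_equal(fit$estimates$f_A2, c(0.1, 0.5, 0.9), tolerance = 0.3)
  expect_true(all(abs(fit$estimates$f_A2 - c(0.1, 0.5, 0.9)) < 0.05))
  # component labels obey the convention: resting (1) is the longer distance
  expect_gt(fit$estimates$rbar_1[1], fit$estimates$rbar_2[1])
  expect_lt(abs(fit$reduced_chi2 - 1), 0.05)
})

test_that("two-acceptor fit with an inert intersubunit acceptor matches the single-acceptor fit", {
  pair <- small_pair(seed = 7)
  bf <- small_buffer_fit(pair)
  single <- cached("fret_small_fit", {
    fit_fret_single(pair, ref_donor(), bf$model, ref_R0(), f_A2 = 0,
                    n_starts = 2, seed = 3)
  })
  inert <- distance_distribution(1, 140, 0.5)
  two <- fit_fret_two_acceptor(pair, inert, ref_donor(), bf$model, ref_R0(),
                               f_A2 = 0, n_starts = 1, seed = 3,
                               start = list(rbar_1 = single$estimates$rbar_1))
  expect_equal(two$estimates$rbar_1, single$estimates$rbar_1, tolerance = 5e-3)
})

test_that("spec errors: broken f_A2 linkage, absent decays, bad sharing", {
  expect_error(param_spec("rho2_f_A2", "free"), class = "tmfret_spec_error")
  pair <- small_pair(seed = 7)
  params <- rbind(param_spec("R0", "fixed", 43.5),
                  param_spec("rbar_1", "free", 45, decay = 3))
  expect_error(fit_spec(pair, params), class = "tmfret_spec_error")
  params2 <- rbind(param_spec("R0", "fixed", 43.5),
                   param_spec("rbar_1", "shared", 45, decay = 1))
  expect_error(fit_spec(list(pair, pair), params2), class = "tmfret_spec_error")
})
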