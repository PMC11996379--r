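# Decay-model evaluation: Gaussian distance distributions, FRET quenching,
# the two-acceptor factorization, and IRF reconvolution.

test_that("gaussian_density matches the closed form and mixture identities", {
  d <- distance_distribution(1, 41.7, 2.3)
  expect_equal(gaussian_density(d, 41.7), 1 / (2.3 * sqrt(2 * pi)),
               tolerance = 1e-12)
  # far tails vanish
  expect_lt(gaussian_density(d, 41.7 + 10 * 2.3),
            1e-20 * gaussian_density(d, 41.7))
  # two equal components at a shared center collapse to one Gaussian
  d2 <- distance_distribution(c(0.5, 0.5), c(41.7, 41.7), c(2.3, 2.3))
  r <- seq(30, 55, by = 0.5)
  expect_equal(gaussian_density(d2, r), gaussian_density(d, r),
               tolerance = 1e-12)
  # discretized mass on the default grid is 1 within 1e-3 before renormalizing
  rg <- default_r_grid()
  dr <- diff(rg[1:2])
  expect_equal(sum(gaussian_density(d, rg)) * dr, 1, tolerance = 1e-3)
})

test_that("fret_efficiency follows the 1/(1+(r/R0)^6) law", {
  expect_identical(fret_efficiency(43.5, 43.5), 0.5)
  expect_equal(fret_efficiency(10 * 43.5, 43.5), 1e-6, tolerance = 1e-3)
  expect_equal(fret_efficiency(43.5 / 2, 43.5), 64 / 65, tolerance = 1e-12)
  expect_error(fret_efficiency(0, 43.5), class = "tmfret_domain_error")
  expect_error(fret_efficiency(-1, 43.5), class = "tmfret_domain_error")
})

test_that("donor_intensity is normalized and evaluates the biexponential", {
  donor <- ref_donor()
  expect_equal(donor_intensity(donor, 0), 1)
  expect_equal(donor_intensity(donor, 17.6),
               0.87 * exp(-1) + 0.13 * exp(-17.6 / 4.73), tolerance = 1e-12)
  mono <- donor_model(1, 5)
  expect_equal(donor_intensity(mono, 5), exp(-1))
})

test_that("single-acceptor intensity has the right limits", {
  donor <- ref_donor()
  t <- seq(0, 40, by = 0.25)
  R0 <- 43.5

  # sigma -> 0 collapses to the single-distance closed form (rbar on-grid)
  rbar <- 41.7
  p <- fret_parameters(f_D = 0, donor = donor, R0 = R0,
                       rho1 = distance_distribution(1, rbar, 1e-3))
  closed <- 0.87 * exp(-(t / 17.6) * (1 + (R0 / rbar)^6)) +
            0.13 * exp(-(t / 4.73) * (1 + (R0 / rbar)^6))
  expect_equal(fret_intensity_single(p, t), closed, tolerance = 1e-6)

  # f_D = 1: donor-only
  p1 <- fret_parameters(f_D = 1, donor = donor, R0 = R0,
                        rho1 = distance_distribution(1, 41.7, 2.3))
  expect_equal(fret_intensity_single(p1, t), donor_intensity(donor, t),
               tolerance = 1e-12)

  # acceptor at 10 R0: no quenching
  p2 <- fret_parameters(f_D = 0, donor = donor, R0 = 10,
                        rho1 = distance_distribution(1, 100, 1))
  expect_equal(fret_intensity_single(p2, t), donor_intensity(donor, t),
               tolerance = 1e-5)
})

test_that("intensity properties hold over random parameter draws", {
  donor <- ref_donor()
  t <- seq(0, 40, by = 0.5)
  set.seed(123)
  for (i in 1:10) {
    rbar <- runif(1, 25, 60)
    sigma <- runif(1, 0.5, 5)
    f_D <- runif(1)
    p <- fret_parameters(f_D = f_D, donor = donor, R0 = 43.5,
                         rho1 = distance_distribution(1, rbar, sigma))
    I <- fret_intensity_single(p, t)
    expect_equal(I[1], 1, tolerance = 1e-9)      # I(0) = 1 before A0
    expect_true(all(diff(I) <= 1e-12))           # non-increasing
    # monotone in rbar: a larger mean distance quenches less
    p_far <- fret_parameters(f_D = f_D, donor = donor, R0 = 43.5,
                             rho1 = distance_distribution(1, rbar + 5, sigma))
    expect_true(all(fret_intensity_single(p_far, t)[-1] >= I[-1] - 1e-12))
  }
})

test_that("two-acceptor model matches the brute-force double integral", {
  donor <- ref_donor()
  t <- c(0.5, 1, 2, 5, 10, 20, 35)
  set.seed(99)
  for (i in 1:5) {
    fa2 <- runif(1, 0.1, 0.9)
    p <- fret_parameters(
      f_D = runif(1, 0, 0.4), donor = donor, R0 = 43.5,
      rho1 = distance_distribution(c(1 - fa2, fa2),
                                   c(runif(1, 38, 50), runif(1, 26, 34)),
                                   c(runif(1, 1.5, 4), runif(1, 1.5, 4))),
      rho2 = distance_distribution(c(1 - fa2, fa2),
                                   c(runif(1, 50, 60), runif(1, 55, 65)),
                                   c(runif(1, 2, 5), runif(1, 2, 5))))
    got <- fret_intensity_two_acceptor(p, t)
    oracle <- two_acceptor_brute_force(p, t)
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("two-acceptor limits: inert second acceptor and rate additivity", {
  donor <- ref_donor()
  t <- seq(0, 40, by = 0.5)
  rho1 <- distance_distribution(1, 41.7, 2.3)

  # second acceptor at 10 R0 contributes no quenching (extended r grid)
  p <- fret_parameters(f_D = 0.2, donor = donor, R0 = 43.5, rho1 = rho1,
                       rho2 = distance_distribution(1, 10 * 43.5, 1))
  p_single <- fret_parameters(f_D = 0.2, donor = donor, R0 = 43.5, rho1 = rho1)
  rg <- seq(2, 450, by = 0.1)
  expect_equal(fret_intensity_two_acceptor(p, t, r_grid = rg),
               fret_intensity_single(p_single, t, r_grid = rg),
               tolerance = 1e-5)

  # adding any finite-distance acceptor never increases intensity
  p_near <- fret_parameters(f_D = 0.2, donor = donor, R0 = 43.5, rho1 = rho1,
                            rho2 = distance_distribution(1, 54.1, 3))
  expect_true(all(fret_intensity_two_acceptor(p_near, t) <=
                    fret_intensity_single(p_single, t) + 1e-12))

  # sigma -> 0 with both acceptors at one distance, single-exponential donor
  mono <- donor_model(1, 17.6)
  rbar <- 40
  p0 <- fret_parameters(f_D = 0, donor = mono, R0 = 43.5,
                        rho1 = distance_distribution(1, rbar, 1e-3),
                        rho2 = distance_distribution(1, rbar, 1e-3))
  expect_equal(fret_intensity_two_acceptor(p0, t),
               exp(-(t / 17.6) * (1 + 2 * (43.5 / rbar)^6)), tolerance = 1e-6)

  # misuse: no rho2
  expect_error(fret_intensity_two_acceptor(p_single, t),
               class = "tmfret_misuse_error")
})

test_that("distance-grid truncation beyond 0.1% of mass is rejected", {
  donor <- ref_donor()
  p <- fret_parameters(f_D = 0, donor = donor, R0 = 43.5,
                       rho1 = distance_distribution(1, 4, 2))  # mass below 2 A
  expect_error(fret_intensity_single(p, seq(0, 10, 0.5)),
               class = "tmfret_config_error")
})

test_that("reconvolve obeys the delta-IRF, shift and background contracts", {
  n <- 256L
  dt <- 50 / n
  t <- (seq_len(n) - 0.5) * dt
  donor <- ref_donor()
  rho <- distance_distribution(1, 41.7, 2.3)

  # delta-function IRF: convolution is identity (times the IRF sum)
  imp <- integer(n); imp[1] <- 1000L
  irf <- decay_histogram(t, imp, role = "irf")
  p <- fret_parameters(f_D = 0.3, donor = donor, R0 = 43.5, rho1 = rho,
                       A0 = 0.02, f_B = 2, bkgr_dec = 3)
  buf <- buffer_model(0.5, 2)
  I <- fret_intensity_single(p, t - t[1])
  out <- reconvolve(p, I, buf, irf)
  manual <- 1000 * (0.02 * I + 2 * buffer_intensity(buf, t - t[1])) + 3
  expect_equal(out$values, manual, tolerance = 1e-10)

  # one-exact-bin shift delays the curve by one bin
  set.seed(1)
  irf_g <- decay_histogram(t, rpois(n, 1e4 * exp(-(t - 5)^2 / 0.5)),
                           role = "irf")
  p0 <- fret_parameters(f_D = 0.3, donor = donor, R0 = 43.5, rho1 = rho,
                        A0 = 0.02, f_B = 0, bkgr_dec = 0)
  p1 <- p0; p1$shift_irf <- dt
  out0 <- reconvolve(p0, I, NULL, irf_g)$values
  out1 <- reconvolve(p1, I, NULL, irf_g)$values
  expect_equal(out1[2:n], out0[1:(n - 1)], tolerance = 1e-10)

  # background-only
  pb <- fret_parameters(f_D = 1, donor = donor, R0 = 43.5, rho1 = rho,
                        A0 = 0, f_B = 0, bkgr_dec = 7)
  expect_equal(reconvolve(pb, numeric(n), NULL, irf_g)$values, rep(7, n))

  # degenerate IRF
  z <- decay_histogram(t, rep(0L, n), role = "irf")
  expect_error(reconvolve(p0, I, NULL, z),
               class = "tmfret_degenerate_irf_error")
})

test_that("linked-fraction invariant is enforced on construction", {
  donor <- ref_donor()
  rho1 <- distance_distribution(c(0.7, 0.3), c(41.7, 28.8), c(2.3, 2.1))
  rho2_bad <- distance_distribution(c(0.5, 0.5), c(54.1, 58), c(3, 5))
  expect_error(fret_parameters(f_D = 0.1, donor = donor, R0 = 43.5,
                               rho1 = rho1, rho2 = rho2_bad),
               class = "tmfret_spec_error")
  rho2_ok <- distance_distribution(c(0.7, 0.3), c(54.1, 58), c(3, 5))
  expect_silent(fret_parameters(f_D = 0.1, donor = donor, R0 = 43.5,
                                rho1 = rho1, rho2 = rho2_ok))
})
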