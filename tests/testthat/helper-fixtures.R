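# Shared reduced-scale fixtures, memoized so each is simulated once per run.
# Unit tests run at 1024 bins / 1e6 counts; the acceptance tests use the
# full study scale (4096 bins / 1e7 counts).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

ref_donor <- function() {
  r <- sthk_reference()$donor
  donor_model(r$alpha, r$tau)
}

ref_R0 <- function() sthk_reference()$R0

# single-acceptor pair at reduced scale
small_pair <- function(seed = 7, rbar = 41.7, sigma = 2.3, f_A2 = NULL,
                       rbar2 = 28.8, sigma2 = 2.1, counts = 1e6,
                       n_bins = 1024L, rho2 = NULL, f_D = 0.15) {
  key <- paste("pair", seed, rbar, sigma, f_A2 %||% "NA", counts, n_bins,
               is.null(rho2), f_D)
  cached(key, {
    rho1 <- if (is.null(f_A2)) {
      distance_distribution(1, rbar, sigma)
    } else {
      distance_distribution(c(1 - f_A2, f_A2), c(rbar, rbar2), c(sigma, sigma2))
    }
    truth <- fret_parameters(f_D = f_D, donor = ref_donor(), R0 = ref_R0(),
                             rho1 = rho1, rho2 = rho2, shift_irf = 0.01,
                             A0 = 1, bkgr_dec = 5)
    cfg <- simulation_config(truth, n_bins = n_bins, total_counts = counts,
                             seed = seed)
    simulate_decay(cfg)
  })
}

small_buffer_fit <- function(pair) {
  key <- paste("buffer", sum(pair$buffer$counts), length(pair$buffer$time))
  cached(key, fit_buffer(pair, n_components = 1, seed = 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force two-acceptor oracle: the double distance integral evaluated as
# an explicit double sum on an independent trapezoid grid.  Kept deliberately
# naive (no factorization) so it checks the product-of-integrals evaluation.
two_acceptor_brute_force <- function(p, t, n_grid = 600L, r_lim = c(5, 95)) {
  r1 <- seq(r_lim[1], r_lim[2], length.out = n_grid)
  r2 <- r1
  w <- rep(diff(r1)[1], n_grid); w[c(1, n_grid)] <- w[1] / 2
  q1 <- w * gaussian_density(p$rho1, r1); q1 <- q1 / sum(q1)
  q2 <- w * gaussian_density(p$rho2, r2); q2 <- q2 / sum(q2)
  donor <- p$donor
  out <- p$f_D * donor_intensity(donor, t)
  fret <- numeric(length(t))
  for (i in seq_along(donor$alpha)) {
    tau <- donor$tau[i]
    for (a in seq_along(r1)) {
      rate <- (1 + (p$R0 / r1[a])^6) / tau
      ex2 <- exp(-outer(t, (p$R0 / r2)^6 / tau))   # t x r2
      fret <- fret + donor$alpha[i] * q1[a] * exp(-t * rate) * drop(ex2 %*% q2)
    }
  }
  out + (1 - p$f_D) * fret
}
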