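#' Donor fluorescence model
#'
#' Intrinsic (no-FRET) donor decay as a sum of one or two exponentials with
#' amplitude fractions summing to 1.  The Acd donor used in the SthK study is
#' close to single-exponential but is best described by two components
#' (0.87 of a 17.6 ns lifetime plus 0.13 of a 4.73 ns lifetime).
#'
#' @param alpha amplitude fractions (length 1-2, sum to 1).
#' @param tau lifetimes in ns (positive, same length as `alpha`).
#' @return an object of class `donor_model`.
#' @export
donor_model <- function(alpha, tau) {
  alpha <- as.numeric(alpha); tau <- as.numeric(tau)
  if (length(alpha) != length(tau) || !length(alpha) %in% 1:2) {
    tmfret_error("donor model needs 1-2 (alpha, tau) pairs", "tmfret_format_error")
  }
  if (abs(sum(alpha) - 1) > 1e-12) {
    tmfret_error("donor amplitude fractions must sum to 1", "tmfret_format_error")
  }
  if (any(tau <= 0)) tmfret_error("donor lifetimes must be > 0", "tmfret_format_error")
  structure(list(alpha = alpha, tau = tau), class = "donor_model")
}

#' Buffer fluorescence model
#'
#' Background fluorescence of the buffer-only sample as a sum of up to four
#' exponentials.  Amplitudes are in counts (not fractions); the model is added
#' to the sample decay, scaled by `f_B`, before convolution with the IRF.
#'
#' @param alpha component amplitudes in counts (length 1-4, non-negative).
#' @param tau lifetimes in ns (positive).
#' @return an object of class `buffer_model`.
#' @export
buffer_model <- function(alpha, tau) {
  alpha <- as.numeric(alpha); tau <- as.numeric(tau)
  if (length(alpha) != length(tau) || !length(alpha) %in% 1:4) {
    tmfret_error("buffer model needs 1-4 (alpha, tau) pairs", "tmfret_format_error")
  }
  if (any(alpha < 0)) tmfret_error("buffer amplitudes must be >= 0", "tmfret_format_error")
  if (any(tau <= 0)) tmfret_error("buffer lifetimes must be > 0", "tmfret_format_error")
  structure(list(alpha = alpha, tau = tau), class = "buffer_model")
}

#' Gaussian donor-acceptor distance distribution
#'
#' Sum of up to two Gaussians over distance, the two components representing
#' the resting and active conformational states.  By study convention,
#' component 1 is the resting state (the longer distance) and `fraction[2]`
#' is the active-state fraction f_A2.
#'
#' @param fraction component fractions (length 1-2, sum to 1).
#' @param mean mean distances r-bar in Angstrom (positive).
#' @param sd standard deviations sigma in Angstrom (positive).
#' @return an object of class `distance_distribution`.
#' @export
distance_distribution <- function(fraction, mean, sd) {
  fraction <- as.numeric(fraction); mean <- as.numeric(mean); sd <- as.numeric(sd)
  n <- length(fraction)
  if (!n %in% 1:2 || length(mean) != n || length(sd) != n) {
    tmfret_error("distance distribution needs 1-2 (fraction, mean, sd) triples",
                 "tmfret_format_error")
  }
  if (abs(sum(fraction) - 1) > 1e-12) {
    tmfret_error("distance-distribution fractions must sum to 1",
                 "tmfret_format_error")
  }
  if (any(fraction < 0)) tmfret_error("fractions must be >= 0", "tmfret_format_error")
  if (any(mean <= 0) || any(sd <= 0)) {
    tmfret_error("distances and widths must be > 0", "tmfret_format_error")
  }
  structure(list(fraction = fraction, mean = mean, sd = sd),
            class = "distance_distribution")
}

#' Full decay-model parameter set
#'
#' The complete parameter vector of the reconvolution FRET model: fraction of
#' donor-only molecules `f_D`, donor model, Forster radius `R0`, the
#' intrasubunit distance distribution `rho1`, an optional intersubunit
#' distribution `rho2` (two-acceptor model for homotetramers), the IRF time
#' shift, buffer scaling `f_B`, overall amplitude `A0`, and the two
#' time-independent backgrounds.  When `rho2` is present its active-state
#' fraction must equal that of `rho1` (the fractions are linked because both
#' distributions report the same conformational equilibrium).
#'
#' @param f_D fraction of donor-only (acceptor-free) molecules, in `[0, 1]`.
#' @param donor a [donor_model()].
#' @param R0 Forster radius in Angstrom (43.5 for Acd / Ru(bpy)2phenM).
#' @param rho1 intrasubunit [distance_distribution()].
#' @param rho2 optional intersubunit [distance_distribution()].
#' @param shift_irf IRF time shift in ns (may be negative).
#' @param f_B buffer scaling (acquisition-time ratio).
#' @param A0 amplitude of the donor model estimate, in counts.
#' @param bkgr_dec time-independent decay background, counts per bin.
#' @param bkgr_irf time-independent IRF background, counts per bin (fixed to
#'   0 in practice since IRF background counts are far below 1).
#' @return an object of class `fret_parameters`.
#' @export
fret_parameters <- function(f_D, donor, R0, rho1, rho2 = NULL, shift_irf = 0,
                            f_B = 1, A0 = 1, bkgr_dec = 0, bkgr_irf = 0) {
  if (f_D < 0 || f_D > 1) tmfret_error("f_D must be in [0, 1]", "tmfret_format_error")
  if (!inherits(donor, "donor_model")) {
    tmfret_error("`donor` must be a donor_model", "tmfret_format_error")
  }
  if (R0 <= 0) tmfret_error("R0 must be > 0", "tmfret_format_error")
  if (!inherits(rho1, "distance_distribution")) {
    tmfret_error("`rho1` must be a distance_distribution", "tmfret_format_error")
  }
  if (!is.null(rho2)) {
    if (!inherits(rho2, "distance_distribution")) {
      tmfret_error("`rho2` must be a distance_distribution", "tmfret_format_error")
    }
    fa2_1 <- if (length(rho1$fraction) == 2L) rho1$fraction[2L] else 1
    fa2_2 <- if (length(rho2$fraction) == 2L) rho2$fraction[2L] else 1
    if (abs(fa2_1 - fa2_2) > 1e-9) {
      tmfret_error("rho1 and rho2 must share the same active-state fraction f_A2",
                   "tmfret_spec_error")
    }
  }
  if (A0 < 0) tmfret_error("A0 must be >= 0", "tmfret_format_error")
  if (bkgr_dec < 0 || bkgr_irf < 0) {
    tmfret_error("backgrounds must be >= 0", "tmfret_format_error")
  }
  structure(list(f_D = f_D, donor = donor, R0 = R0, rho1 = rho1, rho2 = rho2,
                 shift_irf = shift_irf, f_B = f_B, A0 = A0,
                 bkgr_dec = bkgr_dec, bkgr_irf = bkgr_irf),
            class = "fret_parameters")
}

# distance quadrature ---------------------------------------------------------

#' Default distance quadrature grid
#'
#' Fixed grid from 2 to 150 Angstrom in 0.1 Angstrom steps, used for the
#' distance integral in the FRET model.  Study-relevant distances (28-58 A
#' with sigma <= 5 A) are fully covered; the Gaussian density is renormalized
#' on the grid so truncation error is second order.
#'
#' @return numeric vector of distances (Angstrom).
#' @export
default_r_grid <- function() seq(2, 150, by = 0.1)

#' Gaussian mixture density over distance
#'
#' @param dist a [distance_distribution()].
#' @param r distances in Angstrom (non-negative).
#' @return probability density in 1/Angstrom.
#' @export
gaussian_density <- function(dist, r) {
  if (!inherits(dist, "distance_distribution")) {
    tmfret_error("`dist` must be a distance_distribution", "tmfret_format_error")
  }
  if (any(r < 0)) tmfret_error("r must be >= 0", "tmfret_format_error")
  out <- numeric(length(r))
  for (i in seq_along(dist$fraction)) {
    out <- out + dist$fraction[i] * dnorm(r, dist$mean[i], dist$sd[i])
  }
  out
}

# trapezoid quadrature weights times renormalized density; sums to 1 exactly
rho_quadrature <- function(dist, r_grid = default_r_grid(), check = TRUE) {
  if (check) {
    lo <- r_grid[1L]; hi <- r_grid[length(r_grid)]
    mass <- sum(dist$fraction *
                  (pnorm(hi, dist$mean, dist$sd) - pnorm(lo, dist$mean, dist$sd)))
    if (mass < 0.999) {
      tmfret_error(sprintf(
        "distance grid truncates %.2g%% of the distribution mass (> 0.1%%)",
        100 * (1 - mass)), "tmfret_config_error")
    }
  }
  dr <- r_grid[2L] - r_grid[1L]
  w <- rep(dr, length(r_grid)); w[c(1L, length(r_grid))] <- dr / 2
  q <- w * gaussian_density(dist, r_grid)
  q / sum(q)
}

# model primitives ------------------------------------------------------------

#' FRET efficiency at a given distance
#'
#' `E = 1 / (1 + (r/R0)^6)`: efficiency is 0.5 at `r = R0` and falls off with
#' the sixth power of distance.
#'
#' @param r donor-acceptor distance in Angstrom (> 0); vectorized.
#' @param R0 Forster radius in Angstrom (> 0).
#' @return FRET efficiency in `[0, 1]`.
#' @export
fret_efficiency <- function(r, R0) {
  if (any(r <= 0)) tmfret_error("r must be > 0", "tmfret_domain_error")
  if (any(R0 <= 0)) tmfret_error("R0 must be > 0", "tmfret_domain_error")
  1 / (1 + (r / R0)^6)
}

#' Normalized donor-only intensity
#'
#' `sum_i alpha_i exp(-t / tau_i)`; equals 1 at `t = 0`.
#'
#' @param donor a [donor_model()].
#' @param t times in ns (non-negative); vectorized.
#' @return normalized intensity.
#' @export
donor_intensity <- function(donor, t) {
  if (any(t < 0)) tmfret_error("t must be >= 0", "tmfret_domain_error")
  out <- numeric(length(t))
  for (i in seq_along(donor$alpha)) {
    out <- out + donor$alpha[i] * exp(-t / donor$tau[i])
  }
  out
}

#' Buffer intensity in counts
#'
#' @param b a [buffer_model()].
#' @param t_grid times in ns (non-negative).
#' @return intensity vector on the counts scale.
#' @export
buffer_intensity <- function(b, t_grid) {
  if (any(t_grid < 0)) tmfret_error("t must be >= 0", "tmfret_domain_error")
  out <- numeric(length(t_grid))
  for (i in seq_along(b$alpha)) {
    out <- out + b$alpha[i] * exp(-t_grid / b$tau[i])
  }
  out
}

# exp(-outer(t, (1 + (R0/r)^6)/tau_i)) for each donor component: the expensive
# factor of the distance integral.  Constant whenever tau and R0 are fixed, so
# fits precompute it once.  `transfer_only` drops the intrinsic decay term
# (rate (R0/r)^6 / tau only), as needed for the second acceptor.
fret_kernels <- function(t_grid, donor, R0, r_grid, transfer_only = FALSE) {
  base <- (R0 / r_grid)^6
  lapply(donor$tau, function(tau) {
    rate <- if (transfer_only) base / tau else (1 + base) / tau
    exp(-outer(t_grid, rate))
  })
}

#' Normalized donor intensity with one FRET acceptor
#'
#' Computes `f_D * I_donor(t) + (1 - f_D) * integral rho(r) sum_i alpha_i
#' exp(-t/tau_i - (t/tau_i)(R0/r)^6) dr` by fixed-grid trapezoid quadrature
#' over distance.  Equals 1 at `t = 0` and is non-increasing in `t`.
#'
#' @param p a [fret_parameters()] without `rho2`.
#' @param t_grid times in ns (non-negative).
#' @param r_grid distance quadrature grid; default [default_r_grid()].
#' @return normalized intensity vector.
#' @export
fret_intensity_single <- function(p, t_grid, r_grid = default_r_grid()) {
  if (any(t_grid < 0)) tmfret_error("t must be >= 0", "tmfret_domain_error")
  out <- p$f_D * donor_intensity(p$donor, t_grid)
  if (p$f_D < 1) {
    q <- rho_quadrature(p$rho1, r_grid)
    ker <- fret_kernels(t_grid, p$donor, p$R0, r_grid)
    fret <- numeric(length(t_grid))
    for (i in seq_along(p$donor$alpha)) {
      fret <- fret + p$donor$alpha[i] * drop(ker[[i]] %*% q)
    }
    out <- out + (1 - p$f_D) * fret
  }
  out
}

#' Normalized donor intensity with two independent FRET acceptors
#'
#' For a donor quenched by an intrasubunit acceptor (distribution `rho1`) and
#' an intersubunit acceptor (distribution `rho2`, same `R0`), the transfer
#' rates add, and because the two distances are independent the double
#' distance integral factorizes into a product of one-dimensional integrals:
#' for each donor component, `[integral rho1 e^{-t/tau - (t/tau)(R0/r1)^6}
#' dr1] * [integral rho2 e^{-(t/tau)(R0/r2)^6} dr2]`.
#'
#' @inheritParams fret_intensity_single
#' @param p a [fret_parameters()] with `rho2` present.
#' @return normalized intensity vector.
#' @export
fret_intensity_two_acceptor <- function(p, t_grid, r_grid = default_r_grid()) {
  if (is.null(p$rho2)) {
    tmfret_error("rho2 is missing: use fret_intensity_single() for one acceptor",
                 "tmfret_misuse_error")
  }
  if (any(t_grid < 0)) tmfret_error("t must be >= 0", "tmfret_domain_error")
  out <- p$f_D * donor_intensity(p$donor, t_grid)
  if (p$f_D < 1) {
    q1 <- rho_quadrature(p$rho1, r_grid)
    q2 <- rho_quadrature(p$rho2, r_grid)
    ker1 <- fret_kernels(t_grid, p$donor, p$R0, r_grid)
    ker2 <- fret_kernels(t_grid, p$donor, p$R0, r_grid, transfer_only = TRUE)
    fret <- numeric(length(t_grid))
    for (i in seq_along(p$donor$alpha)) {
      fret <- fret +
        p$donor$alpha[i] * drop(ker1[[i]] %*% q1) * drop(ker2[[i]] %*% q2)
    }
    out <- out + (1 - p$f_D) * fret
  }
  out
}

# convolution -----------------------------------------------------------------

# linear convolution via zero-padded power-of-2 FFT, truncated to length(x)
conv_linear <- function(x, y) {
  n <- length(x)
  N <- 2^ceiling(log2(2L * n))
  xf <- fft(c(x, rep(0, N - n)))
  yf <- fft(c(y, rep(0, N - n)))
  Re(fft(xf * yf, inverse = TRUE))[seq_len(n)] / N
}

# background-subtract, clip and sub-bin-shift the IRF trace
prepare_irf <- function(irf_values, time, shift_irf, bkgr_irf) {
  v <- pmax(irf_values - bkgr_irf, 0)
  if (sum(v) <= 0) {
    tmfret_error("IRF has no counts after background subtraction",
                 "tmfret_degenerate_irf_error")
  }
  if (shift_irf != 0) {
    v <- approx(time, v, xout = time - shift_irf, yleft = 0, yright = 0)$y
  }
  v
}

#' Reconvolve the decay model with a measured IRF
#'
#' Builds the model estimate of the measured decay: the (shifted,
#' background-subtracted) IRF is convolved with `A0 * I_DA(t) + f_B * I_B(t)`
#' -- the buffer model is added to the sample model before convolution -- and
#' the time-independent background `bkgr_dec` is added.  Discrete linear
#' convolution at bin resolution, truncated to the data window; sub-bin IRF
#' shifts are applied by linear interpolation.
#'
#' @param p a [fret_parameters()] (supplies `A0`, `f_B`, `shift_irf`,
#'   `bkgr_dec`, `bkgr_irf`).
#' @param donor_part normalized donor intensity on the IRF time grid (from
#'   [fret_intensity_single()] or [fret_intensity_two_acceptor()]); `A0` is
#'   applied here.
#' @param buffer a [buffer_model()], or `NULL` for no buffer term.
#' @param irf a [decay_histogram()] (role `"irf"`) or [model_curve()] on the
#'   same grid as `donor_part`.
#' @return a [model_curve()] of expected counts.
#' @export
reconvolve <- function(p, donor_part, buffer = NULL, irf) {
  time <- irf$time
  irf_vals <- if (inherits(irf, "model_curve")) irf$values else irf$counts
  if (length(donor_part) != length(time)) {
    tmfret_error("donor_part and IRF must share the time grid", "tmfret_grid_error")
  }
  v <- prepare_irf(irf_vals, time, p$shift_irf, p$bkgr_irf)
  signal <- p$A0 * donor_part
  if (!is.null(buffer) && p$f_B != 0) {
    signal <- signal + p$f_B * buffer_intensity(buffer, time - time[1L])
  }
  model_curve(time, conv_linear(v, signal) + p$bkgr_dec)
}

#' Export a distance distribution on the quadrature grid
#'
#' @param dist a [distance_distribution()].
#' @param path CSV output path (columns `r_angstrom`, `density`).
#' @param r_grid distance grid.
#' @return `path`, invisibly.
#' @export
write_distance_distribution <- function(dist, path, r_grid = default_r_grid()) {
  df <- data.frame(r_angstrom = r_grid, density = gaussian_density(dist, r_grid))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a model curve as CSV
#'
#' @param curve a [model_curve()].
#' @param path CSV output path (columns `time_ns`, `expected_counts`).
#' @return `path`, invisibly.
#' @export
write_model_curve <- function(curve, path) {
  df <- data.frame(time_ns = curve$time, expected_counts = curve$values)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
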