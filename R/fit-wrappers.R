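# Protocol wrappers around fit_decays() --------------------------------------
#
# The study protocol fits in a fixed order: (1) the buffer-only decay, whose
# multi-exponential model is then held fixed; (2) the donor-only decay with
# f_D = 1, whose lifetimes are then held fixed; (3) the donor+acceptor decays
# with the distance-distribution parameters free.

donor_fixed_rows <- function(donor) {
  a1 <- donor$alpha[1L]
  t1 <- donor$tau[1L]
  t2 <- if (length(donor$tau) == 2L) donor$tau[2L] else donor$tau[1L]
  rbind(param_spec("tau_D1", "fixed", t1),
        param_spec("alpha_D1", "fixed", if (length(donor$alpha) == 2L) a1 else 1),
        param_spec("tau_D2", "fixed", t2))
}

apply_user_overrides <- function(params, free_names, fixed, start) {
  for (nm in names(fixed)) {
    free_names <- setdiff(free_names, nm)
    params <- params[params$name != nm, , drop = FALSE]
    params <- rbind(params, param_spec(nm, "fixed", fixed[[nm]]))
  }
  rows <- lapply(free_names, function(nm) {
    init <- if (!is.null(start[[nm]])) start[[nm]] else NA_real_
    param_spec(nm, "free", init)
  })
  rbind(params, do.call(rbind, rows))
}

default_fret_starts <- function(R0) {
  list(f_D = 0.2, rbar_1 = R0 * 1.05, sigma_1 = 3, f_A2 = 0.5,
       rbar_2 = R0 * 0.7, sigma_2 = 3, shift_irf = 0)
}

merge_starts <- function(defaults, start) modifyList(defaults, start)

#' Fit the buffer-only decay
#'
#' Multi-exponential reconvolution fit of the buffer trace: the measured IRF
#' is convolved with a sum of up to four exponentials plus a flat background.
#' The returned buffer model is held fixed in all subsequent sample fits.
#'
#' @param buffer a buffer [decay_histogram()], or an [acquisition_pair()]
#'   (its buffer and IRF are used).
#' @param irf the IRF [decay_histogram()]; ignored when `buffer` is a pair.
#' @param n_components number of exponential components, 1-4.
#' @param weighting chi-square weighting rule, see [chi2()].
#' @param n_starts,seed multistart attempts and seed.
#' @param window fit window rule, `"auto"` or `"full"`.
#' @return list of class `buffer_fit` with elements `model` (a
#'   [buffer_model()], components sorted by decreasing lifetime), `estimates`,
#'   `chi2`, `reduced_chi2`, `n_free`, `residuals`, `fitted`, `convergence`.
#' @export
fit_buffer <- function(buffer, irf = NULL, n_components = 1L,
                       weighting = c("poisson", "as-printed"),
                       n_starts = 3L, seed = 1L, window = "auto") {
  weighting <- match.arg(weighting)
  if (inherits(buffer, "acquisition_pair")) {
    irf <- buffer$irf
    buffer <- buffer$buffer
  }
  if (!inherits(buffer, "decay_histogram") || !inherits(irf, "decay_histogram")) {
    tmfret_error("fit_buffer() needs buffer and IRF histograms",
                 "tmfret_precondition_error")
  }
  if (!n_components %in% 1:4) {
    tmfret_error("the buffer model allows 1-4 exponential components",
                 "tmfret_spec_error")
  }
  if (sum(buffer$counts) < 100) {
    tmfret_error("buffer trace has fewer than 100 total counts",
                 "tmfret_precondition_error")
  }
  k <- as.integer(n_components)
  t <- buffer$time
  t_rel <- t - t[1L]
  pseudo <- list(sample = buffer, irf = irf)
  win <- fit_window(pseudo, window)
  obs <- buffer$counts
  sig <- sigma_weights(obs, weighting)[win]

  model_fn <- function(p) {
    # p = (alpha_1..k, tau_1..k, shift, bkgr)
    alpha <- p[seq_len(k)]; tau <- p[k + seq_len(k)]
    shift <- p[2L * k + 1L]; bkgr <- p[2L * k + 2L]
    decay <- numeric(length(t_rel))
    for (i in seq_len(k)) decay <- decay + alpha[i] * exp(-t_rel / tau[i])
    v <- prepare_irf(irf$counts, t, shift, 0)
    conv_linear(v, decay) + bkgr
  }
  resid_fn <- function(p) (obs[win] - model_fn(p)[win]) / sig

  bk0 <- {
    kpre <- win[1L] - 1L
    if (kpre >= 8L) max(median(obs[seq_len(kpre)]), 1e-3) else max(min(obs), 1e-3)
  }
  amp0 <- max((max(obs) - bk0) / max(sum(irf$counts), 1), 1e-9) / k
  tau0 <- exp(seq(log(0.5), log(8), length.out = k))
  p0 <- c(rep(amp0, k), tau0, 0, bk0)
  lower <- c(rep(0, k), rep(0.01, k), -3, 0)
  upper <- c(rep(1e9, k), rep(100, k), 3, 1e9)

  best <- NULL
  for (s in seq_len(n_starts)) {
    ps <- if (s == 1L) p0 else with_seed(seed + s, {
      c(p0[seq_len(k)] * exp(runif(k, -1, 1)),
        p0[k + seq_len(k)] * exp(runif(k, -1, 1)),
        runif(1, -0.2, 0.2), p0[2L * k + 2L] * exp(runif(1, -0.5, 0.5)))
    })
    att <- lm_least_squares(resid_fn, ps, lower, upper)
    if (is.null(best) || att$cost < best$cost) best <- att
  }
  if (!best$converged) {
    stop(structure(
      class = c("tmfret_convergence_error", "tmfret_error", "error", "condition"),
      list(message = paste0("buffer fit did not converge: ", best$message),
           call = sys.call(), best = best)))
  }
  p <- best$par
  ord <- order(p[k + seq_len(k)], decreasing = TRUE)
  alpha <- p[seq_len(k)][ord]; tau <- p[k + seq_len(k)][ord]
  n_free <- length(p)
  structure(list(
    model = buffer_model(pmax(alpha, 0), tau),
    estimates = c(setNames(alpha, paste0("alpha_B", seq_len(k))),
                  setNames(tau, paste0("tau_B", seq_len(k))),
                  shift_irf = p[2L * k + 1L], bkgr_dec = p[2L * k + 2L]),
    chi2 = best$cost,
    reduced_chi2 = best$cost / (length(win) - n_free),
    n_free = n_free, n_bins = length(win),
    residuals = best$residuals,
    fitted = model_curve(t, model_fn(p)),
    convergence = list(converged = best$converged, message = best$message,
                       n_eval = best$n_eval)
  ), class = "buffer_fit")
}

#' @export
print.buffer_fit <- function(x, ...) {
  cat(sprintf("<buffer_fit> %d component(s), reduced chi2 = %.4f\n",
              length(x$model$tau), x$reduced_chi2))
  print(round(x$estimates, 6))
  invisible(x)
}

#' Fit the donor-only decay
#'
#' Reconvolution fit of a donor-only sample with `f_D` fixed at 1: only the
#' donor lifetimes and amplitude fraction, the IRF shift, `A0` and the flat
#' background vary.  The fitted donor model is subsequently held fixed when
#' analyzing FRET samples.
#'
#' @param pair an [acquisition_pair()] for the donor-only sample.
#' @param buffer a fixed [buffer_model()]; when `NULL`, fitted from the
#'   pair's buffer trace with [fit_buffer()].
#' @param n_components donor components, 1 or 2 (biexponential default).
#' @param start named list of starting values (`tau_D1`, `alpha_D1`, ...).
#' @param weighting,n_starts,seed,window,control see [fit_decays()].
#' @return list with elements `donor` (a [donor_model()], components sorted
#'   by decreasing lifetime), `buffer`, and `fit` (the [fit_decays()] result).
#' @export
fit_donor_only <- function(pair, buffer = NULL, n_components = 2L,
                           start = list(),
                           weighting = c("poisson", "as-printed"),
                           n_starts = 3L, seed = 1L, window = "auto",
                           control = list()) {
  weighting <- match.arg(weighting)
  if (!inherits(pair, "acquisition_pair") || !inherits(pair$irf, "decay_histogram")) {
    tmfret_error("fit_donor_only() needs an acquisition_pair with an IRF",
                 "tmfret_precondition_error")
  }
  if (!n_components %in% 1:2) {
    tmfret_error("the donor model allows 1-2 exponential components",
                 "tmfret_spec_error")
  }
  if (is.null(buffer)) buffer <- fit_buffer(pair, weighting = weighting,
                                            seed = seed)$model
  start <- merge_starts(list(tau_D1 = 15, alpha_D1 = 0.8, tau_D2 = 4,
                             shift_irf = 0), start)
  params <- rbind(param_spec("f_D", "fixed", 1),
                  param_spec("bkgr_irf", "fixed", 0),
                  param_spec("R0", "fixed", 50))   # inert with f_D = 1
  free_names <- c("tau_D1", "shift_irf", "A0", "bkgr_dec")
  if (n_components == 2L) {
    free_names <- c(free_names, "alpha_D1", "tau_D2")
  } else {
    params <- rbind(params, param_spec("alpha_D1", "fixed", 1),
                    param_spec("tau_D2", "fixed", start$tau_D2))
  }
  params <- apply_user_overrides(params, free_names, list(), start)
  spec <- fit_spec(pair, params, buffers = buffer, weighting = weighting,
                   window = window)
  fit <- fit_decays(spec, n_starts = n_starts, seed = seed, control = control)
  est <- fit$estimates[1L, ]
  if (n_components == 2L) {
    alpha <- c(est$alpha_D1, 1 - est$alpha_D1)
    tau <- c(est$tau_D1, est$tau_D2)
    ord <- order(tau, decreasing = TRUE)
    donor <- donor_model(alpha[ord] / sum(alpha), tau[ord])
  } else {
    donor <- donor_model(1, est$tau_D1)
  }
  list(donor = donor, buffer = buffer, fit = fit)
}

#' Fit a single decay with the one-acceptor FRET model
#'
#' Estimates the Gaussian distance-distribution parameters of one
#' donor+acceptor decay.  Donor lifetimes, the buffer model, `R0` and `f_B`
#' are held fixed per the study protocol; `f_D`, the distribution
#' parameters, the IRF shift, `A0` and the background vary.
#'
#' @param pair an [acquisition_pair()].
#' @param donor fixed [donor_model()] from [fit_donor_only()].
#' @param buffer fixed [buffer_model()] from [fit_buffer()].
#' @param R0 Forster radius in Angstrom.
#' @param f_A2 `"free"` to fit a two-Gaussian distribution with a free
#'   active-state fraction, or a number to fix it (0 or 1 select a
#'   single-Gaussian resting- or active-state fit).
#' @param fixed named list of additional parameters to fix (e.g.
#'   `list(rbar_1 = 41.7, sigma_1 = 2.3)` to fit only the state fraction).
#' @param start named list of starting values for free parameters.
#' @param weighting,n_starts,seed,window,r_grid,control see [fit_decays()].
#' @return a `fret_fit` object (see [fit_decays()]).
#' @export
fit_fret_single <- function(pair, donor, buffer, R0, f_A2 = 0,
                            fixed = list(), start = list(),
                            weighting = c("poisson", "as-printed"),
                            n_starts = 5L, seed = 1L, window = "auto",
                            r_grid = default_r_grid(), control = list()) {
  weighting <- match.arg(weighting)
  start <- merge_starts(default_fret_starts(R0), start)
  params <- rbind(donor_fixed_rows(donor),
                  param_spec("R0", "fixed", R0),
                  param_spec("bkgr_irf", "fixed", 0))
  free_names <- c("f_D", "shift_irf", "A0", "bkgr_dec")
  if (identical(f_A2, "free")) {
    free_names <- c(free_names, "rbar_1", "sigma_1", "f_A2", "rbar_2", "sigma_2")
  } else {
    f_A2 <- as.numeric(f_A2)
    params <- rbind(params, param_spec("f_A2", "fixed", f_A2))
    if (f_A2 <= 0) {
      free_names <- c(free_names, "rbar_1", "sigma_1")
    } else if (f_A2 >= 1) {
      free_names <- c(free_names, "rbar_2", "sigma_2")
    } else {
      free_names <- c(free_names, "rbar_1", "sigma_1", "rbar_2", "sigma_2")
    }
  }
  params <- apply_user_overrides(params, free_names, fixed, start)
  spec <- fit_spec(pair, params, buffers = buffer, weighting = weighting,
                   window = window, r_grid = r_grid)
  fit_decays(spec, n_starts = n_starts, seed = seed, control = control)
}

#' Globally fit multiple decays with shared parameters
#'
#' Joint chi-square minimization over several decays measured under
#' different conditions.  The study's typical configuration shares the
#' resting- and active-state distances and widths across conditions while
#' the active-state fraction `f_A2` (and the per-decay nuisance parameters
#' `f_D`, `shift_irf`, `A0`, `bkgr_dec`) vary per decay.
#'
#' @param pairs list of [acquisition_pair()] objects (or a ready-made
#'   [fit_spec()], in which case the remaining arguments are ignored).
#' @param donor,buffer,R0 fixed models as in [fit_fret_single()]; `buffer`
#'   may be a list with one model per decay.
#' @param share parameter names tied across all decays.
#' @param f_A2 `"free"` (one free fraction per decay) or a numeric vector of
#'   fixed per-decay fractions.
#' @param fixed,start,weighting,n_starts,seed,window,r_grid,control as in
#'   [fit_fret_single()].
#' @param two_acceptor logical; fit the two-acceptor (homotetramer) model.
#' @param rho2 fixed intersubunit [distance_distribution()] when
#'   `two_acceptor` is `TRUE`.
#' @return a `fret_fit` object.
#' @export
fit_fret_global <- function(pairs, donor, buffer, R0,
                            share = c("rbar_1", "sigma_1", "rbar_2", "sigma_2"),
                            f_A2 = "free", fixed = list(), start = list(),
                            two_acceptor = FALSE, rho2 = NULL,
                            weighting = c("poisson", "as-printed"),
                            n_starts = 1L, seed = 1L, window = "auto",
                            r_grid = default_r_grid(), control = list()) {
  if (inherits(pairs, "fit_spec")) {
    return(fit_decays(pairs, n_starts = n_starts, seed = seed,
                      control = control))
  }
  weighting <- match.arg(weighting)
  if (inherits(pairs, "acquisition_pair")) pairs <- list(pairs)
  n <- length(pairs)
  start <- merge_starts(default_fret_starts(R0), start)
  params <- rbind(donor_fixed_rows(donor),
                  param_spec("R0", "fixed", R0),
                  param_spec("bkgr_irf", "fixed", 0))
  for (nm in share) {
    params <- rbind(params, param_spec(nm, "shared",
                                       start[[nm]] %||% NA_real_, group = nm))
  }
  free_names <- c("f_D", "shift_irf", "A0", "bkgr_dec")
  if (identical(f_A2, "free")) {
    free_names <- c(free_names, "f_A2")
  } else {
    f_A2 <- as.numeric(f_A2)
    if (length(f_A2) == 1L) f_A2 <- rep(f_A2, n)
    if (length(f_A2) != n) {
      tmfret_error("f_A2 must be \"free\" or one value per decay",
                   "tmfret_spec_error")
    }
    for (d in seq_len(n)) {
      params <- rbind(params, param_spec("f_A2", "fixed", f_A2[d], decay = d))
    }
  }
  rho2_components <- 2L
  if (two_acceptor) {
    if (is.null(rho2)) {
      tmfret_error("two-acceptor fits need a fixed intersubunit rho2",
                   "tmfret_spec_error")
    }
    params <- rbind(params, rho2_fixed_rows(rho2))
    rho2_components <- length(rho2$mean)
  }
  params <- apply_user_overrides(params, free_names, fixed, start)
  spec <- fit_spec(pairs, params, buffers = buffer,
                   two_acceptor = two_acceptor,
                   rho2_components = rho2_components,
                   weighting = weighting, window = window, r_grid = r_grid)
  fit_decays(spec, n_starts = n_starts, seed = seed, control = control)
}

rho2_fixed_rows <- function(rho2) {
  if (!inherits(rho2, "distance_distribution")) {
    tmfret_error("rho2 must be a distance_distribution", "tmfret_spec_error")
  }
  rows <- rbind(param_spec("rho2_rbar_1", "fixed", rho2$mean[1L]),
                param_spec("rho2_sigma_1", "fixed", rho2$sd[1L]))
  if (length(rho2$mean) == 2L) {
    rows <- rbind(rows,
                  param_spec("rho2_rbar_2", "fixed", rho2$mean[2L]),
                  param_spec("rho2_sigma_2", "fixed", rho2$sd[2L]))
  }
  rows
}

#' Fit one decay with the two-acceptor (homotetramer) model
#'
#' Implements the homotetramer protocol: the intersubunit distribution
#' `rho2`, previously determined from a donor/acceptor-on-different-subunits
#' experiment, is held fixed (distances and widths), its state fraction
#' linked to the intrasubunit `f_A2`, and the intrasubunit distribution
#' `rho1` is estimated under the product-of-integrals two-acceptor model.
#'
#' @param pair an [acquisition_pair()].
#' @param inter fixed intersubunit [distance_distribution()] (1 or 2
#'   Gaussians; component fractions are ignored, the fraction is linked).
#' @param donor,buffer,R0,f_A2,fixed,start,weighting,n_starts,seed,window,r_grid,control
#'   as in [fit_fret_single()].
#' @return a `fret_fit` object.
#' @export
fit_fret_two_acceptor <- function(pair, inter, donor, buffer, R0,
                                  f_A2 = "free", fixed = list(), start = list(),
                                  weighting = c("poisson", "as-printed"),
                                  n_starts = 5L, seed = 1L, window = "auto",
                                  r_grid = default_r_grid(), control = list()) {
  weighting <- match.arg(weighting)
  start <- merge_starts(default_fret_starts(R0), start)
  params <- rbind(donor_fixed_rows(donor),
                  param_spec("R0", "fixed", R0),
                  param_spec("bkgr_irf", "fixed", 0),
                  rho2_fixed_rows(inter))
  free_names <- c("f_D", "shift_irf", "A0", "bkgr_dec")
  if (identical(f_A2, "free")) {
    free_names <- c(free_names, "rbar_1", "sigma_1", "f_A2", "rbar_2", "sigma_2")
  } else {
    f_A2 <- as.numeric(f_A2)
    params <- rbind(params, param_spec("f_A2", "fixed", f_A2))
    if (f_A2 <= 0) {
      free_names <- c(free_names, "rbar_1", "sigma_1")
    } else if (f_A2 >= 1) {
      free_names <- c(free_names, "rbar_2", "sigma_2")
    } else {
      free_names <- c(free_names, "rbar_1", "sigma_1", "rbar_2", "sigma_2")
    }
  }
  params <- apply_user_overrides(params, free_names, fixed, start)
  spec <- fit_spec(pair, params, buffers = buffer, two_acceptor = TRUE,
                   rho2_components = length(inter$mean),
                   weighting = weighting, window = window, r_grid = r_grid)
  fit_decays(spec, n_starts = n_starts, seed = seed, control = control)
}
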