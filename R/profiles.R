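# Chi-square profiles and surfaces -------------------------------------------
#
# True profiling: for each grid value the target parameter is fixed and all
# remaining free parameters are re-optimized (warm-started from the previous
# grid point).  Reduced chi-square is reported on the original fit's degrees
# of freedom so the profile minimum is directly comparable to the joint-fit
# reduced chi-square.

# rebuild a fit_spec from a fitted result with selected parameters fixed and
# all remaining free/shared parameters warm-started at their estimates
respec_with_fixes <- function(fit, fixes) {
  resolved <- fit$resolved
  tab <- resolved$table
  est <- fit$estimates
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    d <- tab$decay[i]; nm <- tab$name[i]
    fx <- fixes[fixes$name == nm &
                  (is.na(fixes$decay) | fixes$decay == d), , drop = FALSE]
    if (nrow(fx)) {
      rows[[i]] <- param_spec(nm, "fixed", fx$value[1L], decay = d)
    } else if (tab$status[i] == "free") {
      rows[[i]] <- param_spec(nm, "free", est[d, nm],
                              lower = tab$lower[i], upper = tab$upper[i],
                              decay = d)
    } else if (tab$status[i] == "shared") {
      rows[[i]] <- param_spec(nm, "shared", est[d, nm],
                              lower = tab$lower[i], upper = tab$upper[i],
                              group = tab$group[i], decay = d)
    } else {
      rows[[i]] <- param_spec(nm, "fixed", tab$value[i], decay = d)
    }
  }
  spec <- fit$spec
  fit_spec(spec$pairs, do.call(rbind, rows), buffers = spec$buffers,
           two_acceptor = spec$two_acceptor,
           rho2_components = spec$rho2_components,
           weighting = spec$weighting, window = spec$window,
           r_grid = spec$r_grid)
}

check_profile_inputs <- function(fit, param) {
  if (!inherits(fit, "fret_fit")) {
    tmfret_error("`fit` must be a fret_fit", "tmfret_spec_error")
  }
  if (!isTRUE(fit$convergence$converged)) {
    tmfret_error("profiles require a converged fit", "tmfret_precondition_error")
  }
  if (!param %in% FIT_PARAM_NAMES) {
    tmfret_error(paste0("unknown parameter: ", param), "tmfret_spec_error")
  }
}

profile_point <- function(fit, fixes, warm = NULL) {
  spec <- respec_with_fixes(fit, fixes)
  if (!is.null(warm)) {
    # warm-start free/shared rows from the previous grid point's estimates
    for (i in seq_len(nrow(spec$params))) {
      nm <- spec$params$name[i]; d <- spec$params$decay[i]
      if (spec$params$status[i] %in% c("free", "shared")) {
        spec$params$value[i] <- warm[d, nm]
      }
    }
  }
  fit_decays(spec, n_starts = 1L)
}

#' Chi-square profile of one parameter
#'
#' @param fit a converged `fret_fit`.
#' @param param parameter name.
#' @param grid values at which to fix the parameter.
#' @param decay decay index for a per-decay parameter; `NA` (default)
#'   profiles the parameter in all decays at once (correct for shared
#'   parameters and for single-decay fits).
#' @return `data.frame` with columns `value` and `reduced_chi2` (on the
#'   original fit's degrees of freedom), with the fitted estimate and
#'   reduced chi-square as attributes.
#' @export
chi2_profile <- function(fit, param, grid, decay = NA_integer_) {
  check_profile_inputs(fit, param)
  d_ref <- if (is.na(decay)) 1L else as.integer(decay)
  est <- fit$estimates[d_ref, param]
  if (est < min(grid) || est > max(grid)) {
    tmfret_warn(sprintf(
      "profile grid [%.4g, %.4g] does not bracket the fitted value %.4g",
      min(grid), max(grid), est), "tmfret_profile_grid_warning")
  }
  red <- numeric(length(grid))
  warm <- NULL
  for (i in seq_along(grid)) {
    sub <- profile_point(fit, data.frame(name = param, decay = decay,
                                         value = grid[i]), warm)
    red[i] <- sub$chi2 / fit$dof
    warm <- as.matrix(sub$estimates)
  }
  structure(data.frame(value = grid, reduced_chi2 = red),
            param = param, decay = decay,
            fit_value = est, fit_reduced_chi2 = fit$chi2 / fit$dof)
}

#' Chi-square surface over two parameters
#'
#' Two-dimensional profiled surface: in each cell both parameters are fixed
#' and the remaining free parameters re-optimized.  Used to expose parameter
#' correlations (e.g. between sigma1 and the donor-only fraction).
#'
#' @param fit a converged `fret_fit`.
#' @param param_x,param_y parameter names.
#' @param grid_x,grid_y grid values.
#' @param decay_x,decay_y decay indices (`NA` = all decays / shared).
#' @return list with `grid_x`, `grid_y` and matrix `reduced_chi2`
#'   (`length(grid_x)` rows by `length(grid_y)` columns).
#' @export
chi2_surface <- function(fit, param_x, param_y, grid_x, grid_y,
                         decay_x = NA_integer_, decay_y = NA_integer_) {
  check_profile_inputs(fit, param_x)
  check_profile_inputs(fit, param_y)
  z <- matrix(NA_real_, nrow = length(grid_x), ncol = length(grid_y))
  warm_row <- NULL
  for (i in seq_along(grid_x)) {
    warm <- warm_row
    for (j in seq_along(grid_y)) {
      sub <- profile_point(fit, data.frame(
        name = c(param_x, param_y), decay = c(decay_x, decay_y),
        value = c(grid_x[i], grid_y[j])), warm)
      z[i, j] <- sub$chi2 / fit$dof
      warm <- as.matrix(sub$estimates)
      if (j == 1L) warm_row <- warm
    }
  }
  list(grid_x = grid_x, grid_y = grid_y, reduced_chi2 = z,
       param_x = param_x, param_y = param_y,
       fit_reduced_chi2 = fit$chi2 / fit$dof)
}
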