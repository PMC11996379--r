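# Parameter and fit specifications ------------------------------------------
#
# The decay model has a 15-element parameter vector
#   f_D, tau_D1, alpha_D1, tau_D2, R0, rbar_1, sigma_1, f_A2, rbar_2,
#   sigma_2, shift_irf, f_B, A0, bkgr_dec, bkgr_irf
# plus, for the two-acceptor (homotetramer) model, the intersubunit
# distribution parameters rho2_rbar_1, rho2_sigma_1, rho2_rbar_2,
# rho2_sigma_2 whose active-state fraction is linked to f_A2 by construction.

FIT_PARAM_NAMES <- c(
  "f_D", "tau_D1", "alpha_D1", "tau_D2", "R0", "rbar_1", "sigma_1", "f_A2",
  "rbar_2", "sigma_2", "shift_irf", "f_B", "A0", "bkgr_dec", "bkgr_irf",
  "rho2_rbar_1", "rho2_sigma_1", "rho2_rbar_2", "rho2_sigma_2"
)

FRACTION_PARAMS <- c("f_D", "alpha_D1", "f_A2")

default_param_bounds <- function(name) {
  switch(name,
    f_D = , alpha_D1 = , f_A2 = c(0, 1),
    tau_D1 = , tau_D2 = c(0.05, 100),
    R0 = c(5, 100),
    rbar_1 = , rbar_2 = , rho2_rbar_1 = , rho2_rbar_2 = c(3, 148),
    # sigma floor = 2x the distance-grid step: below that the discretized
    # Gaussian is jagged and its derivatives unusable
    sigma_1 = , sigma_2 = , rho2_sigma_1 = , rho2_sigma_2 = c(0.2, 30),
    shift_irf = c(-3, 3),
    f_B = c(0, 1e6),
    A0 = c(0, 1e9),
    bkgr_dec = , bkgr_irf = c(0, 1e9),
    tmfret_error(paste0("unknown parameter name: ", name), "tmfret_spec_error")
  )
}

default_param_values <- function() {
  c(f_D = 1, tau_D1 = 15, alpha_D1 = 0.8, tau_D2 = 4, R0 = NA_real_,
    rbar_1 = 45, sigma_1 = 3, f_A2 = 0, rbar_2 = 30, sigma_2 = 3,
    shift_irf = 0, f_B = 1, A0 = NA_real_, bkgr_dec = NA_real_, bkgr_irf = 0,
    rho2_rbar_1 = 54, rho2_sigma_1 = 3, rho2_rbar_2 = 58, rho2_sigma_2 = 5)
}

#' One row of a fit parameter table
#'
#' Declares how one model parameter is treated in a fit: held `fixed` at
#' `value`, optimized (`free`) within `[lower, upper]` starting from `value`,
#' or `shared` across decays within a named `group`.
#'
#' @param name one of the model parameter names (see [fit_spec()]).
#' @param status `"fixed"`, `"free"` or `"shared"`.
#' @param value fixed value or starting value; `NA` for an automatic start.
#' @param lower,upper bounds for free/shared parameters; `NA` uses per-name
#'   defaults (fractions are bounded to `[0, 1]`).
#' @param group sharing-group id for `status = "shared"`.
#' @param decay decay index this row applies to; `NA` applies to all decays.
#' @return one-row `data.frame`.
#' @export
param_spec <- function(name, status = c("fixed", "free", "shared"),
                       value = NA_real_, lower = NA_real_, upper = NA_real_,
                       group = NA_character_, decay = NA_integer_) {
  status <- match.arg(status)
  if (identical(name, "rho2_f_A2")) {
    tmfret_error(paste0(
      "rho2 has no independent fraction: its f_A2 is linked to rho1's f_A2 ",
      "(the two distributions report the same conformational equilibrium)"),
      "tmfret_spec_error")
  }
  if (!name %in% FIT_PARAM_NAMES) {
    tmfret_error(paste0("unknown parameter name: ", name), "tmfret_spec_error")
  }
  if (status == "fixed" && is.na(value)) {
    tmfret_error(paste0("fixed parameter ", name, " needs a value"),
                 "tmfret_spec_error")
  }
  if (status == "shared" && is.na(group)) group <- name
  b <- default_param_bounds(name)
  if (is.na(lower)) lower <- b[1L]
  if (is.na(upper)) upper <- b[2L]
  if (name %in% FRACTION_PARAMS) {
    lower <- max(lower, 0); upper <- min(upper, 1)
  }
  if (!is.finite(lower) || !is.finite(upper) || lower > upper) {
    tmfret_error(paste0("free parameter ", name, " needs finite bounds"),
                 "tmfret_spec_error")
  }
  data.frame(name = name, status = status, value = as.numeric(value),
             lower = lower, upper = upper, group = as.character(group),
             decay = as.integer(decay), stringsAsFactors = FALSE)
}

#' Fit specification: decays plus a parameter table
#'
#' Binds one or more [acquisition_pair()] objects to a parameter table built
#' from [param_spec()] rows.  Rows with `decay = NA` apply to every decay;
#' `shared` rows with a common `group` tie one value across decays.  Buffer
#' models are held fixed per decay (from [fit_buffer()]).
#'
#' @param pairs an [acquisition_pair()] or list of them.
#' @param params `data.frame` of [param_spec()] rows.
#' @param buffers a [buffer_model()], list of them (one per decay), or `NULL`
#'   for no buffer term.
#' @param two_acceptor logical; use the two-acceptor (intersubunit) model.
#' @param rho2_components 1 or 2: number of Gaussians in the intersubunit
#'   distribution (two-acceptor model only).  With 2, the component weights
#'   are `(1 - f_A2, f_A2)`, linked to `rho1`.
#' @param weighting `"poisson"` (sigma = sqrt(max(counts, 1)), the default)
#'   or `"as-printed"` (sigma = max(counts, 1)).
#' @param window `"auto"` (from the rising edge to the end of the record) or
#'   `"full"`.
#' @param r_grid distance quadrature grid.
#' @return an object of class `fit_spec`.
#' @export
fit_spec <- function(pairs, params, buffers = NULL, two_acceptor = FALSE,
                     rho2_components = 2L,
                     weighting = c("poisson", "as-printed"),
                     window = c("auto", "full"), r_grid = default_r_grid()) {
  weighting <- match.arg(weighting)
  window <- match.arg(window)
  if (inherits(pairs, "acquisition_pair")) pairs <- list(pairs)
  if (!length(pairs) || !all(vapply(pairs, inherits, TRUE, "acquisition_pair"))) {
    tmfret_error("`pairs` must be acquisition_pair objects", "tmfret_spec_error")
  }
  n_decay <- length(pairs)
  if (inherits(buffers, "buffer_model")) buffers <- rep(list(buffers), n_decay)
  if (!is.null(buffers) && length(buffers) != n_decay) {
    tmfret_error("`buffers` must have one buffer model per decay",
                 "tmfret_spec_error")
  }
  if (!is.data.frame(params) || !all(c("name", "status", "value") %in% names(params))) {
    tmfret_error("`params` must be a data.frame of param_spec() rows",
                 "tmfret_spec_error")
  }
  bad_decay <- params$decay[!is.na(params$decay)]
  if (any(bad_decay < 1L | bad_decay > n_decay)) {
    tmfret_error("parameter table references a decay that does not exist",
                 "tmfret_spec_error")
  }
  # a shared group must resolve to >= 2 decays when there are >= 2 decays
  sh <- params[params$status == "shared", , drop = FALSE]
  if (n_decay >= 2L && nrow(sh)) {
    for (g in unique(sh$group)) {
      rows <- sh[sh$group == g, , drop = FALSE]
      covered <- if (anyNA(rows$decay)) n_decay else length(unique(rows$decay))
      if (covered < 2L) {
        tmfret_error(paste0("shared group '", g,
                            "' must span at least two decays"),
                     "tmfret_spec_error")
      }
    }
  }
  if (!rho2_components %in% 1:2) {
    tmfret_error("rho2_components must be 1 or 2", "tmfret_spec_error")
  }
  structure(list(pairs = pairs, params = params, buffers = buffers,
                 two_acceptor = isTRUE(two_acceptor),
                 rho2_components = as.integer(rho2_components),
                 weighting = weighting, window = window, r_grid = r_grid),
            class = "fit_spec")
}

#' @export
print.fit_spec <- function(x, ...) {
  cat(sprintf("<fit_spec> %d decay(s), %s model, weighting=%s\n",
              length(x$pairs),
              if (x$two_acceptor) "two-acceptor" else "single-acceptor",
              x$weighting))
  print(x$params, row.names = FALSE)
  invisible(x)
}
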