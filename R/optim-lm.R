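# Internal box-constrained Levenberg-Marquardt least squares.
#
# Minimizes sum(fn(par)^2) where fn returns the weighted residual vector.
# Forward-difference Jacobian; bounds handled by projecting trial steps into
# the box.  Deterministic given (fn, par).  Written here because no LM
# implementation (minpack.lm) is available in the target environment and
# nls() formula plumbing fits this engine poorly.

lm_least_squares <- function(fn, par, lower = rep(-Inf, length(par)),
                             upper = rep(Inf, length(par)),
                             max_iter = 500L, ftol = 1e-12, xtol = 1e-12,
                             diag_step = 1e-6, jac_fn = NULL) {
  npar <- length(par)
  stopifnot(length(lower) == npar, length(upper) == npar)
  par <- pmin(pmax(par, lower), upper)
  r <- fn(par)
  cost <- sum(r * r)
  lambda <- 1e-3
  n_eval <- 1L
  converged <- FALSE
  message <- "max_iter reached"
  jac_last <- NULL
  n_stall <- 0L

  for (iter in seq_len(max_iter)) {
    # forward-difference Jacobian (backward at the upper bound); a caller
    # can supply a structured jac_fn that exploits block sparsity
    if (is.null(jac_fn)) {
      J <- matrix(0, nrow = length(r), ncol = npar)
      for (j in seq_len(npar)) {
        h <- diag_step * max(abs(par[j]), 1e-3)
        sign_h <- if (par[j] + h > upper[j]) -1 else 1
        pj <- par
        pj[j] <- par[j] + sign_h * h
        J[, j] <- (fn(pj) - r) / (sign_h * h)
        n_eval <- n_eval + 1L
      }
    } else {
      J <- jac_fn(par, r)
      n_eval <- n_eval + npar
    }
    jac_last <- J
    g <- drop(crossprod(J, r))     # gradient / 2 of the cost wrt par
    # active set: parameters pinned at a bound whose descent direction (-g)
    # points outside the box
    at_lo <- par <= lower + 1e-12 * (1 + abs(lower)) & g > 0
    at_hi <- par >= upper - 1e-12 * (1 + abs(upper)) & g < 0
    free_idx <- which(!(at_lo | at_hi))
    if (!length(free_idx) || max(abs(g[free_idx])) < 1e-14 * (1 + cost)) {
      converged <- TRUE; message <- "gradient ~ 0"; break
    }
    H <- crossprod(J)
    dH <- pmax(diag(H), 1e-12)
    improved <- FALSE
    for (try in 1:30) {
      A <- H[free_idx, free_idx, drop = FALSE]
      diag(A) <- diag(A) + lambda * dH[free_idx]
      delta_f <- tryCatch(drop(solve(A, -g[free_idx])), error = function(e) NULL)
      if (!is.null(delta_f)) {
        delta <- numeric(npar)
        delta[free_idx] <- delta_f
        trial <- pmin(pmax(par + delta, lower), upper)
        rt <- fn(trial)
        n_eval <- n_eval + 1L
        cost_t <- sum(rt * rt)
        if (is.finite(cost_t) && cost_t <= cost) {
          step <- max(abs(trial - par) / pmax(abs(par), 1))
          dcost <- cost - cost_t
          par <- trial; r <- rt; cost <- cost_t
          lambda <- max(lambda / 3, 1e-12)
          improved <- TRUE
          if (dcost <= ftol * (cost + 1e-300) || step <= xtol) {
            converged <- TRUE; message <- "converged"
          }
          # stall escape: several successive near-negligible improvements
          n_stall <- if (dcost <= 1e-7 * (cost + 1e-300)) n_stall + 1L else 0L
          if (n_stall >= 5L) {
            converged <- TRUE; message <- "converged (stalled improvements)"
          }
          break
        }
      }
      lambda <- lambda * 5
      if (lambda > 1e14) break
    }
    if (!improved) { converged <- TRUE; message <- "no further improvement"; break }
    if (converged) break
  }

  list(par = par, cost = cost, residuals = r, jacobian = jac_last,
       converged = converged, message = message,
       n_eval = n_eval, n_iter = if (exists("iter")) iter else 0L)
}

# identifiability flag from the final Gauss-Newton Hessian, scaled to its
# diagonal (a correlation matrix) so parameter units do not matter
hessian_singular <- function(jacobian, tol = 1e8) {
  if (is.null(jacobian)) return(FALSE)
  H <- crossprod(jacobian)
  d <- diag(H)
  if (any(d <= 0)) return(TRUE)
  C <- H / sqrt(outer(d, d))
  s <- svd(C, nu = 0, nv = 0)$d
  s[length(s)] <= 0 || (s[1L] / s[length(s)]) > tol
}
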