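# Reconvolution chi-square fitting -------------------------------------------

#' Chi-square of a model curve against an observed histogram
#'
#' `chi2 = sum ((obs - model) / sigma)^2` with per-bin sigma from the
#' weighting rule.  TCSPC counts are Poisson distributed, so the default is
#' `sigma = sqrt(max(counts, 1))`; the `"as-printed"` rule
#' `sigma = max(counts, 1)` (standard deviation equal to the decay itself) is
#' retained as a selectable alternative.
#'
#' @param observed a [decay_histogram()].
#' @param model a [model_curve()] on the same grid.
#' @param weighting `"poisson"` or `"as-printed"`.
#' @return list with elements `chi2` and `residuals` (signed weighted
#'   deviations, `(obs - model)/sigma`).
#' @export
chi2 <- function(observed, model, weighting = c("poisson", "as-printed")) {
  weighting <- match.arg(weighting)
  if (length(observed$time) != length(model$time) ||
      max(abs(observed$time - model$time)) > 1e-9) {
    tmfret_error("observed and model must share the time grid", "tmfret_grid_error")
  }
  if (sum(observed$counts) == 0) {
    tmfret_error("observed trace has no counts", "tmfret_degenerate_data_error")
  }
  s <- sigma_weights(observed$counts, weighting)
  r <- (observed$counts - model$values) / s
  list(chi2 = sum(r * r), residuals = r)
}

sigma_weights <- function(counts, weighting) {
  if (weighting == "poisson") sqrt(pmax(counts, 1)) else pmax(counts, 1)
}

# fit window: from the rising edge of the decay to the end of the record.
# The pre-pulse region (located from the IRF onset) estimates the flat
# background; the window starts where counts rise clearly above it.
fit_window <- function(pair, window = "auto") {
  n <- length(pair$sample$time)
  if (window == "full") return(seq_len(n))
  irf <- pair$irf$counts
  onset <- which(irf > 0.01 * max(irf))[1L]
  k <- if (is.na(onset)) 0L else onset - 2L
  if (k >= 8L) {
    bk <- median(pair$sample$counts[seq_len(k)])
    above <- which(pair$sample$counts > bk + 5 * sqrt(bk + 1))
    above <- above[above >= k]
    start <- if (length(above)) above[1L] else 1L
  } else {
    start <- 1L
  }
  seq.int(start, n)
}

# --- spec resolution ---------------------------------------------------------

# Expand a fit_spec parameter table into one row per (decay, name), applying
# defaults, then decay-NA rows, then decay-specific rows.
resolve_spec <- function(spec) {
  n_decay <- length(spec$pairs)
  defaults <- default_param_values()
  rows <- list()
  for (d in seq_len(n_decay)) {
    vals <- defaults
    vals["f_B"] <- spec$pairs[[d]]$f_B
    tab <- data.frame(decay = d, name = names(vals), status = "default",
                      value = unname(vals), lower = NA_real_, upper = NA_real_,
                      group = NA_character_, stringsAsFactors = FALSE)
    for (pass in 1:2) {
      sel <- if (pass == 1L) which(is.na(spec$params$decay)) else
        which(spec$params$decay == d)
      for (i in sel) {
        row <- spec$params[i, ]
        j <- match(row$name, tab$name)
        tab$status[j] <- row$status
        tab$value[j] <- row$value
        tab$lower[j] <- row$lower
        tab$upper[j] <- row$upper
        tab$group[j] <- row$group
      }
    }
    rows[[d]] <- tab
  }
  table <- do.call(rbind, rows)
  table$status[table$status == "default"] <- "fixed"

  # packed free vector: one slot per free (decay, name), one per shared group
  packed <- data.frame(name = character(), decay = integer(),
                       group = character(), init = numeric(),
                       lower = numeric(), upper = numeric(),
                       stringsAsFactors = FALSE)
  slot_of <- integer(nrow(table))      # table row -> packed slot (0 = fixed)
  group_slot <- list()
  for (i in seq_len(nrow(table))) {
    st <- table$status[i]
    if (st == "free") {
      packed <- rbind(packed, data.frame(
        name = table$name[i], decay = table$decay[i],
        group = NA_character_, init = table$value[i],
        lower = table$lower[i], upper = table$upper[i],
        stringsAsFactors = FALSE))
      slot_of[i] <- nrow(packed)
    } else if (st == "shared") {
      g <- table$group[i]
      if (is.null(group_slot[[g]])) {
        packed <- rbind(packed, data.frame(
          name = table$name[i], decay = NA_integer_, group = g,
          init = table$value[i], lower = table$lower[i],
          upper = table$upper[i], stringsAsFactors = FALSE))
        group_slot[[g]] <- nrow(packed)
      }
      slot_of[i] <- group_slot[[g]]
    }
  }
  list(table = table, packed = packed, slot_of = slot_of, n_decay = n_decay)
}

# values matrix (n_decay x n_param) for a packed parameter vector
packed_to_values <- function(resolved, par) {
  tab <- resolved$table
  vals <- tab$value
  touched <- resolved$slot_of > 0L
  vals[touched] <- par[resolved$slot_of[touched]]
  matrix(vals, nrow = resolved$n_decay, byrow = TRUE,
         dimnames = list(NULL, tab$name[tab$decay == 1L]))
}

# --- model evaluation engine -------------------------------------------------

# Build closures that evaluate per-decay residuals efficiently.  Kernel
# matrices (the expensive distance-integral factor) are memoized on
# (grid, donor lifetimes, R0), so fits with fixed donor parameters pay the
# cost once.
build_engine <- function(spec, resolved) {
  n_decay <- resolved$n_decay
  r_grid <- spec$r_grid
  dr <- r_grid[2L] - r_grid[1L]
  wq <- rep(dr, length(r_grid)); wq[c(1L, length(r_grid))] <- dr / 2
  kern_cache <- new.env(parent = emptyenv())

  decays <- lapply(seq_len(n_decay), function(d) {
    pair <- spec$pairs[[d]]
    t <- pair$sample$time
    t_rel <- t - t[1L]
    win <- fit_window(pair, spec$window)
    list(pair = pair, t = t, t_rel = t_rel, win = win,
         obs = pair$sample$counts,
         sigma = sigma_weights(pair$sample$counts, spec$weighting)[win],
         irf_counts = pair$irf$counts,
         buffer = if (is.null(spec$buffers)) NULL else spec$buffers[[d]],
         grid_sig = paste(length(t), signif(t[1L], 12), signif(t_rel[2L], 12)))
  })

  get_kernels <- function(dec, tau, R0, transfer_only) {
    key <- paste(dec$grid_sig, paste(signif(tau, 12), collapse = ","),
                 signif(R0, 12), transfer_only)
    k <- kern_cache[[key]]
    if (is.null(k)) {
      base <- (R0 / r_grid)^6
      k <- lapply(tau, function(tt) {
        rate <- if (transfer_only) base / tt else (1 + base) / tt
        exp(-outer(dec$t_rel, rate))
      })
      kern_cache[[key]] <- k
    }
    k
  }

  mix_quadrature <- function(fr, mean, sd) {
    q <- numeric(length(r_grid))
    for (i in seq_along(fr)) {
      if (fr[i] > 0) q <- q + fr[i] * dnorm(r_grid, mean[i], sd[i])
    }
    q <- wq * q
    q / sum(q)
  }

  model_decay <- function(d, v) {
    dec <- decays[[d]]
    alpha <- c(v[["alpha_D1"]], 1 - v[["alpha_D1"]])
    tau <- c(v[["tau_D1"]], v[["tau_D2"]])
    f_D <- v[["f_D"]]
    I <- f_D * (alpha[1L] * exp(-dec$t_rel / tau[1L]) +
                alpha[2L] * exp(-dec$t_rel / tau[2L]))
    if (f_D < 1) {
      fa2 <- v[["f_A2"]]
      q1 <- mix_quadrature(c(1 - fa2, fa2),
                           c(v[["rbar_1"]], v[["rbar_2"]]),
                           c(v[["sigma_1"]], v[["sigma_2"]]))
      k1 <- get_kernels(dec, tau, v[["R0"]], FALSE)
      if (spec$two_acceptor) {
        fr2 <- if (spec$rho2_components %||% 2L == 1L) 1 else c(1 - fa2, fa2)
        m2 <- c(v[["rho2_rbar_1"]], v[["rho2_rbar_2"]])[seq_along(fr2)]
        s2 <- c(v[["rho2_sigma_1"]], v[["rho2_sigma_2"]])[seq_along(fr2)]
        q2 <- mix_quadrature(fr2, m2, s2)
        k2 <- get_kernels(dec, tau, v[["R0"]], TRUE)
        fret <- alpha[1L] * drop(k1[[1L]] %*% q1) * drop(k2[[1L]] %*% q2) +
                alpha[2L] * drop(k1[[2L]] %*% q1) * drop(k2[[2L]] %*% q2)
      } else {
        fret <- alpha[1L] * drop(k1[[1L]] %*% q1) +
                alpha[2L] * drop(k1[[2L]] %*% q1)
      }
      I <- I + (1 - f_D) * fret
    }
    signal <- v[["A0"]] * I
    if (!is.null(dec$buffer) && v[["f_B"]] != 0) {
      signal <- signal + v[["f_B"]] * buffer_intensity(dec$buffer, dec$t_rel)
    }
    irf <- prepare_irf(dec$irf_counts, dec$t, v[["shift_irf"]], v[["bkgr_irf"]])
    conv_linear(irf, signal) + v[["bkgr_dec"]]
  }

  resid_decay <- function(d, v) {
    dec <- decays[[d]]
    m <- model_decay(d, v)
    (dec$obs[dec$win] - m[dec$win]) / dec$sigma
  }

  resid_fn <- function(par) {
    vals <- packed_to_values(resolved, par)
    unlist(lapply(seq_len(n_decay), function(d) resid_decay(d, vals[d, ])),
           use.names = FALSE)
  }

  # residual slice offsets per decay, for the structured Jacobian
  win_len <- vapply(decays, function(dec) length(dec$win), 1L)
  offsets <- cumsum(c(0L, win_len))

  # which decays each packed slot touches
  slot_decays <- lapply(seq_len(nrow(resolved$packed)), function(j) {
    rows <- which(resolved$slot_of == j)
    sort(unique(resolved$table$decay[rows]))
  })

  jac_fn <- function(par, r0) {
    vals0 <- packed_to_values(resolved, par)
    J <- matrix(0, nrow = length(r0), ncol = length(par))
    for (j in seq_along(par)) {
      h <- 1e-6 * max(abs(par[j]), 1e-3)
      sign_h <- if (par[j] + h > resolved$packed$upper[j]) -1 else 1
      pj <- par
      pj[j] <- par[j] + sign_h * h
      valsj <- packed_to_values(resolved, pj)
      for (d in slot_decays[[j]]) {
        idx <- (offsets[d] + 1L):offsets[d + 1L]
        J[idx, j] <- (resid_decay(d, valsj[d, ]) - r0[idx]) / (sign_h * h)
      }
    }
    J
  }

  list(resid_fn = resid_fn, jac_fn = jac_fn, model_decay = model_decay,
       decays = decays, n_bins = sum(win_len))
}

# fill NA starts: bkgr_dec from the pre-pulse / minimum counts, A0 by scaling
# the unscaled model to the observed counts
auto_starts <- function(spec, resolved, engine) {
  tab <- resolved$table
  packed <- resolved$packed
  for (d in seq_len(resolved$n_decay)) {
    dec <- engine$decays[[d]]
    rows_d <- which(tab$decay == d)
    vals <- setNames(tab$value[rows_d], tab$name[rows_d])
    # packed inits may already be set; merge current packed inits
    touched <- resolved$slot_of[rows_d] > 0L
    vals[touched] <- packed$init[resolved$slot_of[rows_d][touched]]
    need_bkgr <- is.na(vals[["bkgr_dec"]])
    need_A0 <- is.na(vals[["A0"]])
    if (need_bkgr) {
      k <- dec$win[1L] - 1L
      bk <- if (k >= 8L) median(dec$obs[seq_len(k)]) else
        max(min(dec$obs), 0.1)
      vals[["bkgr_dec"]] <- max(bk, 1e-3)
    }
    if (need_A0) {
      vals[["A0"]] <- 1
      v0 <- vals; v0[["bkgr_dec"]] <- 0
      m1 <- engine$model_decay(d, v0)
      buf_part <- if (!is.null(dec$buffer) && vals[["f_B"]] != 0) {
        vb <- vals; vb[["A0"]] <- 0; vb[["bkgr_dec"]] <- 0
        engine$model_decay(d, vb)
      } else {
        numeric(length(m1))
      }
      num <- sum(dec$obs[dec$win]) - vals[["bkgr_dec"]] * length(dec$win) -
        sum(buf_part[dec$win])
      den <- sum(m1[dec$win] - buf_part[dec$win])
      vals[["A0"]] <- max(num / max(den, 1e-12), 1e-9)
    }
    # write back into packed inits / fixed table values
    for (nm in c("bkgr_dec", "A0")) {
      i <- rows_d[match(nm, tab$name[rows_d])]
      if (resolved$slot_of[i] > 0L) {
        j <- resolved$slot_of[i]
        if (is.na(packed$init[j])) packed$init[j] <- vals[[nm]]
      } else if (is.na(tab$value[i])) {
        tab$value[i] <- vals[[nm]]
      }
    }
  }
  resolved$table <- tab
  resolved$packed <- packed
  resolved
}

multistart_inits <- function(packed, n_starts, seed) {
  inits <- list(packed$init)
  if (n_starts > 1L) {
    with_seed(seed, {
      for (s in 2:n_starts) {
        p <- packed$init
        for (j in seq_along(p)) {
          nm <- packed$name[j]
          p[j] <- switch(nm,
            rbar_1 = , rbar_2 = , rho2_rbar_1 = , rho2_rbar_2 =
              p[j] + runif(1, -8, 8),
            sigma_1 = , sigma_2 = , rho2_sigma_1 = , rho2_sigma_2 =
              p[j] * exp(runif(1, -0.7, 0.7)),
            f_D = , f_A2 = , alpha_D1 = runif(1, 0.05, 0.95),
            tau_D1 = , tau_D2 = p[j] * exp(runif(1, -0.5, 0.5)),
            shift_irf = p[j] + runif(1, -0.2, 0.2),
            A0 = p[j] * exp(runif(1, -0.3, 0.3)),
            bkgr_dec = p[j] * exp(runif(1, -1, 1)),
            p[j])
          p[j] <- min(max(p[j], packed$lower[j]), packed$upper[j])
        }
        inits[[s]] <- p
      }
    })
  }
  inits
}

#' Fit a decay model specification by chi-square minimization
#'
#' The workhorse behind [fit_donor_only()], [fit_fret_single()],
#' [fit_fret_global()] and [fit_fret_two_acceptor()]: box-constrained
#' Levenberg-Marquardt least squares on the weighted residual vector across
#' all decays of the fit specification, with optional seeded multistart.
#' With no free
#' parameters, evaluates chi-square without optimization.
#'
#' @param spec a [fit_spec()].
#' @param n_starts number of multistart attempts (start 1 uses the declared
#'   initial values; further starts perturb them deterministically under
#'   `seed`).
#' @param seed integer seed for the multistart perturbations.
#' @param control list of optimizer settings (`max_iter`, `ftol`, `xtol`).
#' @return an object of class `fret_fit`: estimates per decay, packed free
#'   estimates, `chi2`, `reduced_chi2`, `n_free`, `n_bins`, per-decay
#'   residuals and fitted curves, and convergence information.
#' @export
fit_decays <- function(spec, n_starts = 1L, seed = 1L, control = list()) {
  if (!inherits(spec, "fit_spec")) {
    tmfret_error("`spec` must be a fit_spec", "tmfret_spec_error")
  }
  for (pair in spec$pairs) {
    if (sum(pair$sample$counts) == 0) {
      tmfret_error("a sample trace has no counts", "tmfret_degenerate_data_error")
    }
  }
  resolved <- resolve_spec(spec)
  engine <- build_engine(spec, resolved)
  resolved <- auto_starts(spec, resolved, engine)
  packed <- resolved$packed
  n_free <- nrow(packed)
  if (engine$n_bins <= n_free) {
    tmfret_error("more free parameters than fitted bins", "tmfret_spec_error")
  }

  ctl <- modifyList(list(max_iter = 500L, ftol = 1e-12, xtol = 1e-12), control)

  if (n_free == 0L) {
    r <- engine$resid_fn(numeric(0))
    fit <- list(par = numeric(0), cost = sum(r * r), residuals = r,
                jacobian = NULL, converged = TRUE,
                message = "no free parameters: chi-square evaluation only",
                n_eval = 1L, n_iter = 0L)
  } else {
    inits <- multistart_inits(packed, n_starts, seed)
    fit <- NULL
    for (p0 in inits) {
      att <- lm_least_squares(engine$resid_fn, p0,
                              lower = packed$lower, upper = packed$upper,
                              max_iter = ctl$max_iter, ftol = ctl$ftol,
                              xtol = ctl$xtol, jac_fn = engine$jac_fn)
      if (is.null(fit) || att$cost < fit$cost) fit <- att
    }
    if (!fit$converged) {
      cond <- structure(
        class = c("tmfret_convergence_error", "tmfret_error", "error", "condition"),
        list(message = paste0("fit did not converge: ", fit$message),
             call = sys.call(-1), best = fit))
      stop(cond)
    }
  }

  build_fret_fit(spec, resolved, engine, fit)
}

build_fret_fit <- function(spec, resolved, engine, fit) {
  packed <- resolved$packed
  vals <- packed_to_values(resolved, fit$par)
  vals <- tie_break_states(spec, resolved, vals)
  n_free <- nrow(packed)
  dof <- engine$n_bins - n_free
  # per-decay residuals and fitted curves at the optimum
  fitted <- vector("list", resolved$n_decay)
  residuals <- vector("list", resolved$n_decay)
  for (d in seq_len(resolved$n_decay)) {
    dec <- engine$decays[[d]]
    m <- engine$model_decay(d, vals[d, ])
    fitted[[d]] <- model_curve(dec$t, m)
    residuals[[d]] <- (dec$obs[dec$win] - m[dec$win]) / dec$sigma
  }
  singular <- if (n_free > 0L && !is.null(fit$jacobian)) {
    hessian_singular(fit$jacobian)
  } else {
    FALSE
  }
  if (singular) {
    tmfret_warn("Hessian is near-singular at the optimum: one or more parameters are not identifiable from these data",
                "tmfret_identifiability_warning")
  }
  free_names <- ifelse(is.na(packed$decay),
                       ifelse(is.na(packed$group), packed$name,
                              paste0(packed$name, ":", packed$group)),
                       paste0(packed$name, "@", packed$decay))
  free_est <- packed_estimates(resolved, vals)
  structure(list(
    estimates = as.data.frame(vals),
    free = setNames(free_est, free_names),
    chi2 = fit$cost,
    reduced_chi2 = fit$cost / dof,
    n_free = n_free, n_bins = engine$n_bins, dof = dof,
    residuals = residuals, fitted = fitted,
    windows = lapply(engine$decays, function(dec) dec$win),
    convergence = list(converged = fit$converged, message = fit$message,
                       n_eval = fit$n_eval, n_iter = fit$n_iter,
                       hessian_singular = singular),
    weighting = spec$weighting,
    spec = spec, resolved = resolved
  ), class = "fret_fit")
}

# read packed estimates back from the (possibly label-swapped) values matrix
packed_estimates <- function(resolved, vals) {
  packed <- resolved$packed
  out <- numeric(nrow(packed))
  for (j in seq_len(nrow(packed))) {
    rows <- which(resolved$slot_of == j)
    i <- rows[1L]
    d <- resolved$table$decay[i]
    out[j] <- vals[d, resolved$table$name[i]]
  }
  out
}

# Component-label convention: component 1 (resting) has the larger mean
# distance.  The model is invariant under swapping the two Gaussians together
# with f_A2 -> 1 - f_A2 (and the rho2 labels in the two-acceptor model), so
# relabeling after the fit changes nothing numerically.
tie_break_states <- function(spec, resolved, vals) {
  est_status <- function(nm) {
    resolved$table$status[resolved$table$decay == 1L &
                            resolved$table$name == nm]
  }
  both_est <- all(c(est_status("rbar_1"), est_status("rbar_2")) != "fixed")
  fa2_est <- est_status("f_A2") != "fixed"
  if (!both_est || !fa2_est) return(vals)
  if (vals[1L, "rbar_1"] >= vals[1L, "rbar_2"]) return(vals)
  swap <- function(a, b) {
    tmp <- vals[, a]
    vals[, a] <<- vals[, b]
    vals[, b] <<- tmp
  }
  swap("rbar_1", "rbar_2")
  swap("sigma_1", "sigma_2")
  if (spec$two_acceptor && (spec$rho2_components %||% 2L) == 2L) {
    swap("rho2_rbar_1", "rho2_rbar_2")
    swap("rho2_sigma_1", "rho2_sigma_2")
  }
  vals[, "f_A2"] <- 1 - vals[, "f_A2"]
  vals
}

#' @export
print.fret_fit <- function(x, ...) {
  cat(sprintf("<fret_fit> %d decay(s), %d free parameters, %d bins\n",
              nrow(x$estimates), x$n_free, x$n_bins))
  cat(sprintf("  chi2 = %.6g, reduced chi2 = %.4f (%s weighting)\n",
              x$chi2, x$reduced_chi2, x$weighting))
  if (length(x$free)) {
    cat("  estimates:\n")
    print(round(x$free, 5))
  }
  invisible(x)
}
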