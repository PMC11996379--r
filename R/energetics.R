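# Two-state Boltzmann energetics and ligand dose-response --------------------

#' Gas constant in kcal/(mol K)
#' @keywords internal
R_KCAL <- 1.9872e-3

#' Free energy of a two-state transition from its active-state fraction
#'
#' `dG = -R T ln(f / (1 - f))` with R in kcal/(mol K): a fraction above 0.5
#' means the active state is favored (negative dG).  Boundary fractions of
#' exactly 0 or 1 (e.g. from single-state fits with f_A2 fixed) are rejected
#' because the energy diverges; report a bound instead of converting.
#'
#' @param f_A2 active-state fraction(s), strictly inside (0, 1).
#' @param temperature absolute temperature in K (default 298).
#' @return free energy in kcal/mol, with the temperature attached as the
#'   `"temperature"` attribute.
#' @export
delta_g <- function(f_A2, temperature = 298) {
  f_A2 <- as.numeric(f_A2)
  if (any(!is.finite(f_A2)) || any(f_A2 <= 0) || any(f_A2 >= 1)) {
    tmfret_error(paste0(
      "f_A2 must lie strictly inside (0, 1); a fraction fixed at 0 or 1 has ",
      "no finite free energy - report a bound instead"),
      "tmfret_domain_error")
  }
  if (temperature <= 0) {
    tmfret_error("temperature must be > 0 K", "tmfret_domain_error")
  }
  structure(-R_KCAL * temperature * log(f_A2 / (1 - f_A2)),
            temperature = temperature)
}

#' Ligand-induced change in transition free energy
#'
#' `ddG = dG_ligand - dG_apo`.  Because a constant domain-coupling offset
#' shifts both terms equally, ddG is invariant to coupling with neighboring
#' domains, which is what makes it the right cross-construct comparison.
#'
#' @param g_ligand,g_apo free energies from [delta_g()] (kcal/mol).  If both
#'   carry a `"temperature"` attribute the temperatures must match.
#' @return difference in kcal/mol.
#' @export
delta_delta_g <- function(g_ligand, g_apo) {
  t1 <- attr(g_ligand, "temperature")
  t2 <- attr(g_apo, "temperature")
  if (!is.null(t1) && !is.null(t2) && abs(t1 - t2) > 1e-9) {
    tmfret_error("free energies computed at different temperatures",
                 "tmfret_domain_error")
  }
  out <- as.numeric(g_ligand) - as.numeric(g_apo)
  attr(out, "temperature") <- t1 %||% t2
  out
}

#' Free-energy table for a set of conditions
#'
#' @param f_A2 active-state fractions.
#' @param condition labels, recycled.
#' @param temperature K.
#' @return `data.frame` with columns `condition`, `f_A2`, `delta_g_kcal_mol`,
#'   `temperature_K`.
#' @export
energy_table <- function(f_A2, condition = seq_along(f_A2), temperature = 298) {
  data.frame(condition = as.character(condition), f_A2 = as.numeric(f_A2),
             delta_g_kcal_mol = as.numeric(delta_g(f_A2, temperature)),
             temperature_K = temperature, stringsAsFactors = FALSE)
}

#' Fractional response under ligand depletion
#'
#' The quadratic (exact) binding isotherm for total ligand and protein
#' concentrations, appropriate when the protein concentration is comparable
#' to the dissociation constant so free ligand cannot be equated with total
#' ligand:
#' `response = (A - B) (L + P + KD - sqrt((L + P + KD)^2 - 4 P L)) / (2 P) + B`.
#' At `L = 0` the response is exactly `B`; far above both `KD` and `P` it
#' approaches `A`; as `P -> 0` it reduces to the hyperbolic isotherm
#' `B + (A - B) L / (L + KD)`.
#'
#' @param L_total total ligand concentration(s), uM (>= 0).
#' @param K_D dissociation constant, uM (> 0).
#' @param protein_total total protein (binding-site) concentration, uM (> 0).
#' @param A response at saturating ligand; `B` response without ligand.
#' @param B see `A`.
#' @return fractional response(s).
#' @export
dose_response <- function(L_total, K_D, protein_total, A, B) {
  if (any(L_total < 0)) tmfret_error("L_total must be >= 0", "tmfret_domain_error")
  if (K_D <= 0 || protein_total <= 0) {
    tmfret_error("K_D and protein_total must be > 0", "tmfret_domain_error")
  }
  s <- L_total + protein_total + K_D
  disc <- pmax(s^2 - 4 * protein_total * L_total, 0)  # guard roundoff
  # bound/total = (s - sqrt(disc)) / (2 P), computed in the cancellation-free
  # form 2 L / (s + sqrt(disc)) so the [P] -> 0 limit stays accurate
  (A - B) * 2 * L_total / (s + sqrt(disc)) + B
}

#' Fit the ligand-depletion dose-response relation
#'
#' Least-squares fit of [dose_response()] to titration points
#' `(ligand_total, f_A2)`.  `K_D`, `A`, `B` and (unless fixed) the total
#' protein concentration are estimated.
#'
#' @param series `data.frame` with columns `ligand_total` (uM) and `f_A2`,
#'   at least 4 points spanning sub-saturating and saturating ligand.
#' @param protein_total total protein concentration in uM: the starting
#'   value, or the fixed value when `fix_protein = TRUE`.
#' @param fix_protein hold `protein_total` at the given value (it is usually
#'   corroborated by independent protein quantification).
#' @param start optional named list of starting values (`K_D`, `A`, `B`,
#'   `protein_total`).
#' @return list of class `dose_response_fit`: `K_D`, `protein_total`, `A`,
#'   `B`, `fitted`, `residuals`, `convergence`.
#' @export
fit_dose_response <- function(series, protein_total = NULL,
                              fix_protein = FALSE, start = list()) {
  if (!is.data.frame(series) || !all(c("ligand_total", "f_A2") %in% names(series))) {
    tmfret_error("`series` needs columns ligand_total and f_A2",
                 "tmfret_spec_error")
  }
  L <- as.numeric(series$ligand_total)
  y <- as.numeric(series$f_A2)
  if (anyDuplicated(L)) {
    tmfret_error("duplicated ligand concentrations in titration",
                 "tmfret_spec_error")
  }
  if (length(L) < 4L) {
    tmfret_error("need at least 4 titration points", "tmfret_precondition_error")
  }
  if (diff(range(y)) < 1e-6) {
    tmfret_error("flat response (A = B): K_D is unidentifiable",
                 "tmfret_unidentifiable_error")
  }
  s0 <- merge_starts(list(
    K_D = max(stats::median(L[L > 0]), 1e-3),
    A = max(y), B = min(y),
    protein_total = protein_total %||% 1
  ), start)
  if (fix_protein && is.null(protein_total)) {
    tmfret_error("fix_protein = TRUE needs a protein_total value",
                 "tmfret_spec_error")
  }
  nm <- c("K_D", "A", "B", if (!fix_protein) "protein_total")
  p0 <- unlist(s0[nm])
  lower <- c(1e-9, 0, 0, if (!fix_protein) 1e-9)
  upper <- c(1e6, 1, 1, if (!fix_protein) 1e6)
  resid_fn <- function(p) {
    P <- if (fix_protein) protein_total else p[4L]
    y - dose_response(L, p[1L], P, p[2L], p[3L])
  }
  best <- NULL
  for (kd0 in unique(c(p0[1L], 0.1, 1, 10))) {
    ps <- p0; ps[1L] <- kd0
    att <- lm_least_squares(resid_fn, ps, lower, upper,
                            ftol = 1e-15, xtol = 1e-15)
    if (is.null(best) || att$cost < best$cost) best <- att
  }
  p <- best$par
  P <- if (fix_protein) protein_total else p[4L]
  # saturation diagnostic: K_D is unconstrained if every nonzero ligand
  # point sits far above both K_D and the protein concentration
  Lnz <- L[L > 0]
  if (length(Lnz) && all(Lnz > 50 * (p[1L] + P))) {
    tmfret_error("all titration points are saturating: K_D is unidentifiable",
                 "tmfret_unidentifiable_error")
  }
  structure(list(K_D = unname(p[1L]), protein_total = unname(P),
                 A = unname(p[2L]), B = unname(p[3L]),
                 fitted = dose_response(L, p[1L], P, p[2L], p[3L]),
                 residuals = best$residuals,
                 convergence = list(converged = best$converged,
                                    message = best$message)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> K_D = %.4g uM, [P]total = %.4g uM, A = %.3f, B = %.3f\n",
    x$K_D, x$protein_total, x$A, x$B))
  invisible(x)
}
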