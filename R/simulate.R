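# Synthetic TCSPC data --------------------------------------------------------
#
# Emulates a cuvette TCSPC acquisition: a narrow Gaussian IRF (scattered
# excitation), a sample decay generated by the exact forward model
# (reconvolution of donor + FRET + buffer, plus flat background) and Poisson
# shot noise per bin.  No photon-by-photon simulation, pile-up or dead time:
# TCSPC noise is treated as per-bin Poisson, which is what the fitting model
# assumes.

#' Simulation configuration
#'
#' Defaults describe a study-scale acquisition: 50 ns window, 4096 bins,
#' Gaussian IRF of 0.5 ns FWHM centered at 2 ns, 1e7 expected sample photons
#' and 1e6 IRF photons.
#'
#' @param truth a [fret_parameters()] ground truth.  Its `A0` is ignored;
#'   the amplitude is derived from `total_counts` and recorded in the
#'   returned objects.
#' @param time_window record length in ns.
#' @param n_bins number of bins (>= 64).
#' @param irf_center,irf_fwhm Gaussian IRF center and FWHM in ns.
#' @param total_counts expected sample photons (signal above buffer and
#'   background).
#' @param irf_counts expected IRF photons.
#' @param buffer a [buffer_model()] or `NULL` to use the default dim fast
#'   component (2 ns lifetime at ~1% of the sample amplitude).
#' @param buffer_bkgr flat background of the buffer-only trace, counts/bin.
#' @param acq_sample,acq_buffer acquisition durations in s; their ratio
#'   fixes `f_B`.
#' @param seed integer seed; identical (config, seed) gives bit-identical
#'   histograms.
#' @param label free-text label attached to the histograms.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(truth, time_window = 50, n_bins = 4096L,
                              irf_center = 2, irf_fwhm = 0.5,
                              total_counts = 1e7, irf_counts = 1e6,
                              buffer = NULL, buffer_bkgr = 2,
                              acq_sample = 300, acq_buffer = 60,
                              seed = 1L, label = "") {
  if (!inherits(truth, "fret_parameters")) {
    tmfret_error("`truth` must be fret_parameters", "tmfret_config_error")
  }
  if (n_bins < 64L) tmfret_error("n_bins must be >= 64", "tmfret_config_error")
  if (total_counts < 0 || irf_counts <= 0) {
    tmfret_error("photon budgets must be >= 0 (sample) and > 0 (IRF)",
                 "tmfret_config_error")
  }
  if (irf_fwhm <= 0) tmfret_error("irf_fwhm must be > 0", "tmfret_config_error")
  dt <- time_window / n_bins
  if (irf_fwhm < 2 * dt) {
    tmfret_warn("IRF FWHM below two bin widths: under-resolved IRF",
                "tmfret_irf_resolution_warning")
  }
  structure(list(truth = truth, time_window = time_window,
                 n_bins = as.integer(n_bins), irf_center = irf_center,
                 irf_fwhm = irf_fwhm, total_counts = total_counts,
                 irf_counts = irf_counts, buffer = buffer,
                 buffer_bkgr = buffer_bkgr, acq_sample = acq_sample,
                 acq_buffer = acq_buffer, seed = as.integer(seed),
                 label = label),
            class = "simulation_config")
}

sim_time_grid <- function(cfg) {
  dt <- cfg$time_window / cfg$n_bins
  (seq_len(cfg$n_bins) - 0.5) * dt
}

# noiseless Gaussian IRF shape scaled to `counts` expected photons
ideal_irf_values <- function(cfg, counts = cfg$irf_counts) {
  t <- sim_time_grid(cfg)
  sd <- cfg$irf_fwhm / (2 * sqrt(2 * log(2)))
  shape <- dnorm(t, cfg$irf_center, sd)
  counts * shape / sum(shape)
}

#' Simulate an IRF measurement
#'
#' Gaussian pulse discretized on the grid, scaled to the expected IRF photon
#' count and Poisson-sampled (emulating a scatter measurement).
#'
#' @param cfg a [simulation_config()].
#' @return a [decay_histogram()] with role `"irf"`.
#' @export
simulate_irf <- function(cfg) {
  mu <- ideal_irf_values(cfg)
  counts <- with_seed(cfg$seed * 7L + 1L, rpois(cfg$n_bins, mu))
  decay_histogram(sim_time_grid(cfg), counts, role = "irf",
                  acquisition_time = cfg$acq_sample, label = cfg$label)
}

# expected sample and buffer curves from the noiseless IRF shape
sim_expected <- function(cfg) {
  t <- sim_time_grid(cfg)
  truth <- cfg$truth
  irf_ideal <- model_curve(t, ideal_irf_values(cfg))
  I <- if (is.null(truth$rho2)) {
    fret_intensity_single(truth, t - t[1L])
  } else {
    fret_intensity_two_acceptor(truth, t - t[1L])
  }
  # derive A0 from the photon budget: signal counts = A0 * sum(conv(IRF, I))
  p1 <- truth; p1$A0 <- 1; p1$bkgr_dec <- 0; p1$f_B <- 0
  base <- reconvolve(p1, I, NULL, irf_ideal)$values
  A0 <- cfg$total_counts / sum(base)
  buffer <- cfg$buffer %||% buffer_model(max(0.01 * A0, 1e-12), 2)
  truth$A0 <- A0
  f_B <- cfg$acq_sample / cfg$acq_buffer
  truth$f_B <- f_B
  sample_mu <- reconvolve(truth, I, buffer, irf_ideal)$values
  pb <- truth; pb$A0 <- 0; pb$f_B <- 1; pb$bkgr_dec <- cfg$buffer_bkgr
  buffer_mu <- reconvolve(pb, numeric(cfg$n_bins), buffer, irf_ideal)$values
  if (max(sample_mu) > 2^31) {
    tmfret_error("expected counts exceed 2^31 per bin", "tmfret_config_error")
  }
  list(t = t, sample_mu = sample_mu, buffer_mu = buffer_mu,
       truth = truth, buffer = buffer, f_B = f_B)
}

#' Simulate a matched sample / buffer / IRF acquisition
#'
#' Builds the expected sample curve by [reconvolve()] from the truth
#' parameters and the noiseless IRF shape, replaces every bin by an
#' independent Poisson draw, simulates the buffer-only trace analogously,
#' and Poisson-samples the measured IRF.  The truth (with the derived `A0`
#' and `f_B` and the buffer model) is attached as attribute `"truth"`.
#'
#' @param cfg a [simulation_config()].
#' @param irf optional pre-simulated measured IRF [decay_histogram()] on the
#'   cfg grid (reused across conditions measured in one session).
#' @return an [acquisition_pair()].
#' @export
simulate_decay <- function(cfg, irf = NULL) {
  ex <- sim_expected(cfg)
  if (is.null(irf)) {
    irf <- simulate_irf(cfg)
  } else if (length(irf$time) != cfg$n_bins ||
             max(abs(irf$time - ex$t)) > 1e-9) {
    tmfret_error("supplied IRF is not on the configured time grid",
                 "tmfret_grid_error")
  }
  counts <- with_seed(cfg$seed * 7L + 2L, list(
    sample = rpois(cfg$n_bins, ex$sample_mu),
    buffer = rpois(cfg$n_bins, ex$buffer_mu)
  ))
  sample <- decay_histogram(ex$t, counts$sample, role = "sample",
                            acquisition_time = cfg$acq_sample,
                            label = cfg$label)
  buffer <- decay_histogram(ex$t, counts$buffer, role = "buffer",
                            acquisition_time = cfg$acq_buffer,
                            label = cfg$label)
  pair <- acquisition_pair(sample, buffer, irf)
  attr(pair, "truth") <- list(parameters = ex$truth, buffer = ex$buffer,
                              expected = model_curve(ex$t, ex$sample_mu),
                              seed = cfg$seed)
  pair
}

# Reference truth values for the SthK tmFRET system --------------------------

#' Reference parameter values for the SthK tmFRET system
#'
#' Published fitted parameters for the SthK constructs, used as simulation
#' ground truth: the Acd donor biexponential, the Forster radius of the
#' Acd / Ru(bpy)2phenM pair, resting/active Gaussian distance parameters for
#' the heterotetramer, intersubunit, homotetramer and full-length datasets,
#' state fractions, and dose-response parameters.
#'
#' @return a nested list of reference values (distances in Angstrom,
#'   lifetimes in ns, concentrations in uM, fractions dimensionless).
#' @export
sthk_reference <- function() {
  list(
    donor = list(alpha = c(0.87, 0.13), tau = c(17.6, 4.73)),
    R0 = 43.5,
    cterm_hetero = list(
      resting = c(rbar = 41.7, sigma = 2.3),
      active = c(rbar = 28.8, sigma = 2.1),
      f_apo = 0.08, f_sat = 0.96,
      K_D = 0.22, protein_total = 1.2,
      ligand_uM = c(0, 0.5, 1, 2, 320)),
    intersubunit = list(
      resting = c(rbar = 54.1, sigma = 3.0),
      active = c(rbar = 58.0, sigma = 5.0),
      f_apo = 0.2, f_sat = 0.8),
    cterm_homo = list(
      resting = c(rbar = 41.6, sigma = 3.6),
      active = c(rbar = 29.1, sigma = 4.1),
      f_apo = 0.25, f_sat = 0.94,
      ligand_uM = c(0, 1, 320)),
    full_length = list(
      resting = c(rbar = 39.8, sigma = 4.1),
      active = c(rbar = 31.0, sigma = 2.7),
      f_apo = 0.41, f_sat = 0.99,
      K_D = 0.52, protein_total = 0.025,
      ligand_uM = c(0, 0.25, 0.5, 1, 2, 320)),
    cterm_global = list(f_apo = 0.12, f_sat = 0.96)
  )
}

# default non-distance truth choices for fixtures (see the methods vignette)
fixture_nuisance <- function() {
  list(f_D = 0.15, shift_irf = 0.01, bkgr_dec = 5)
}

fixture_truth <- function(rho1, R0, donor, rho2 = NULL,
                          nuisance = fixture_nuisance()) {
  fret_parameters(f_D = nuisance$f_D,
                  donor = donor_model(donor$alpha, donor$tau),
                  R0 = R0, rho1 = rho1, rho2 = rho2,
                  shift_irf = nuisance$shift_irf, A0 = 1,
                  bkgr_dec = nuisance$bkgr_dec, bkgr_irf = 0)
}

two_state_rho <- function(state, f_A2) {
  if (f_A2 <= 0) {
    distance_distribution(1, state$resting[["rbar"]], state$resting[["sigma"]])
  } else if (f_A2 >= 1) {
    distance_distribution(1, state$active[["rbar"]], state$active[["sigma"]])
  } else {
    distance_distribution(c(1 - f_A2, f_A2),
                          c(state$resting[["rbar"]], state$active[["rbar"]]),
                          c(state$resting[["sigma"]], state$active[["sigma"]]))
  }
}

#' Generate study-style synthetic fixtures
#'
#' Returns matched acquisitions for one of the study scenarios, with the
#' published fitted parameters as ground truth and per-condition active-state
#' fractions taken from the corresponding dose-response relation:
#' \describe{
#'   \item{`donor_only`}{one pair, no acceptor (f_D = 1).}
#'   \item{`cterm_hetero_titration`}{five pairs at 0, 0.5, 1, 2, 320 uM
#'     ligand; single intrasubunit acceptor.}
#'   \item{`intersubunit`}{apo and saturating pairs for the
#'     donor/acceptor-on-different-subunits construct.}
#'   \item{`cterm_homo`}{homotetramer pairs (apo, 1 uM, saturating) with the
#'     two-acceptor model (intersubunit distribution fixed at the
#'     intersubunit-fit values, fraction linked).}
#'   \item{`full_length`}{full-length channel pairs across the ligand range,
#'     two-acceptor model.}
#' }
#'
#' @param scenario scenario tag, see above.
#' @param seed integer seed (one deterministic stream per condition).
#' @param total_counts expected photons per sample decay.
#' @param n_bins bins per histogram.
#' @return list of [acquisition_pair()] objects, one per condition, each
#'   carrying its `"truth"` attribute; conditions in the names.  The shared
#'   measured IRF and scenario metadata are attached as attributes.
#' @export
make_study_fixture <- function(scenario = c("donor_only",
                                            "cterm_hetero_titration",
                                            "intersubunit", "cterm_homo",
                                            "full_length"),
                               seed = 1L, total_counts = 1e7,
                               n_bins = 4096L) {
  scenario <- match.arg(scenario)
  ref <- sthk_reference()
  donor <- ref$donor
  R0 <- ref$R0

  cond_fractions <- function(set) {
    L <- set$ligand_uM
    if (!is.null(set$K_D)) {
      dose_response(L, set$K_D, set$protein_total, set$f_sat, set$f_apo)
    } else {
      # no published K_D: interpolate mid conditions with the heterotetramer
      # binding curve rescaled to this construct's apo/saturating fractions
      h <- ref$cterm_hetero
      dose_response(L, h$K_D, h$protein_total, set$f_sat, set$f_apo)
    }
  }

  build <- function(rho1_list, labels, rho2 = NULL, f_D = NULL) {
    pairs <- vector("list", length(rho1_list))
    irf <- NULL
    buffer <- NULL       # one buffer solution shared by all conditions
    for (i in seq_along(rho1_list)) {
      nuis <- fixture_nuisance()
      if (!is.null(f_D)) nuis$f_D <- f_D
      truth <- fixture_truth(rho1_list[[i]], R0, donor,
                             rho2 = rho2[[i]] %||% NULL, nuisance = nuis)
      cfg <- simulation_config(truth, n_bins = n_bins,
                               total_counts = total_counts,
                               buffer = buffer,
                               seed = seed * 1000L + i, label = labels[i])
      if (is.null(irf)) irf <- simulate_irf(cfg)
      pairs[[i]] <- simulate_decay(cfg, irf)
      if (is.null(buffer)) buffer <- attr(pairs[[i]], "truth")$buffer
    }
    names(pairs) <- labels
    attr(pairs, "irf") <- irf
    attr(pairs, "scenario") <- scenario
    pairs
  }

  if (scenario == "donor_only") {
    rho <- distance_distribution(1, 10 * R0, 1)  # inert: f_D = 1
    truth <- fixture_truth(rho, R0, donor,
                           nuisance = modifyList(fixture_nuisance(),
                                                 list(f_D = 1)))
    cfg <- simulation_config(truth, n_bins = n_bins,
                             total_counts = total_counts,
                             seed = seed * 1000L + 1L, label = "donor_only")
    pairs <- list(donor_only = simulate_decay(cfg))
    attr(pairs, "irf") <- pairs[[1L]]$irf
    attr(pairs, "scenario") <- scenario
    return(pairs)
  }

  if (scenario == "cterm_hetero_titration") {
    set <- ref$cterm_hetero
    f <- cond_fractions(set)
    rho <- lapply(f, function(fa) two_state_rho(set, fa))
    labels <- paste0("cAMP_", set$ligand_uM, "uM")
    out <- build(rho, labels)
    attr(out, "f_A2") <- f
    return(out)
  }

  if (scenario == "intersubunit") {
    # a donor here faces three acceptor-labeled subunits, so the donor-only
    # (all acceptor sites unlabeled) fraction is much smaller than for a
    # single-cysteine construct
    set <- ref$intersubunit
    rho <- list(two_state_rho(set, set$f_apo), two_state_rho(set, set$f_sat))
    out <- build(rho, c("apo", "cAMP_sat"), f_D = 0.05)
    attr(out, "f_A2") <- c(set$f_apo, set$f_sat)
    return(out)
  }

  inter_set <- ref$intersubunit
  set <- if (scenario == "cterm_homo") ref$cterm_homo else ref$full_length
  f <- cond_fractions(set)
  rho1 <- lapply(f, function(fa) two_state_rho(set, fa))
  rho2 <- lapply(f, function(fa) two_state_rho(inter_set, fa))
  labels <- paste0("cAMP_", set$ligand_uM, "uM")
  out <- build(rho1, labels, rho2 = rho2, f_D = 0.05)
  attr(out, "f_A2") <- f
  attr(out, "two_acceptor") <- TRUE
  attr(out, "inter") <- distance_distribution(
    c(0.5, 0.5),
    c(inter_set$resting[["rbar"]], inter_set$active[["rbar"]]),
    c(inter_set$resting[["sigma"]], inter_set$active[["sigma"]]))
  out
}
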