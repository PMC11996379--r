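#' TCSPC decay histogram
#'
#' A measured or simulated photon-count trace on a uniform time grid.  Counts
#' are integer photon numbers; real-valued model estimates use
#' [model_curve()] instead.
#'
#' @param time numeric vector of bin centers in nanoseconds, strictly
#'   increasing and uniformly spaced.
#' @param counts non-negative integer photon counts, same length as `time`
#'   (at least 16 bins).
#' @param role one of `"sample"`, `"buffer"`, `"irf"`.
#' @param acquisition_time acquisition duration in seconds (used to fix the
#'   buffer scaling `f_B` as a ratio of acquisition times).
#' @param label free-text label, e.g. construct and ligand concentration.
#' @return an object of class `decay_histogram`.
#' @seealso [read_histogram()], [write_histogram()], [acquisition_pair()]
#' @export
decay_histogram <- function(time, counts, role = c("sample", "buffer", "irf"),
                            acquisition_time = 1, label = "") {
  role <- match.arg(role)
  time <- as.numeric(time)
  counts <- as.numeric(counts)
  if (length(time) != length(counts)) {
    tmfret_error("`time` and `counts` must have equal length",
                 "tmfret_format_error")
  }
  if (length(time) < 16L) {
    tmfret_error("a decay histogram needs at least 16 bins",
                 "tmfret_format_error")
  }
  check_uniform_grid(time)
  if (anyNA(counts) || any(counts < 0)) {
    tmfret_error("counts must be non-negative and non-missing",
                 "tmfret_format_error")
  }
  if (max(abs(counts - round(counts))) > 1e-9) {
    tmfret_error("counts must be integer-valued; use model_curve() for model estimates",
                 "tmfret_format_error")
  }
  if (!is.numeric(acquisition_time) || length(acquisition_time) != 1L ||
      is.na(acquisition_time) || acquisition_time <= 0) {
    tmfret_error("`acquisition_time` must be a positive scalar (seconds)",
                 "tmfret_format_error")
  }
  structure(
    list(time = time, counts = round(counts), role = role,
         acquisition_time = as.numeric(acquisition_time),
         label = as.character(label)[1L]),
    class = "decay_histogram"
  )
}

check_uniform_grid <- function(time) {
  if (anyNA(time)) tmfret_error("time grid contains NA", "tmfret_grid_error")
  d <- diff(time)
  if (any(d <= 0)) {
    tmfret_error("time grid must be strictly increasing", "tmfret_grid_error")
  }
  dt <- d[1L]
  if (any(abs(d - dt) > 1e-9 * abs(dt))) {
    tmfret_error("time grid must be uniformly spaced", "tmfret_grid_error")
  }
  invisible(dt)
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> role=%s  %d bins, dt=%.4g ns, %.3g counts",
              x$role, length(x$time), diff(x$time[1:2]), sum(x$counts)))
  if (nzchar(x$label)) cat("  [", x$label, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Real-valued model estimate of a decay
#'
#' Same grid contract as [decay_histogram()] but with finite real values,
#' used for expected-count curves before Poisson sampling.
#'
#' @param time bin centers (ns), uniform grid.
#' @param values finite real expected counts.
#' @return an object of class `model_curve`.
#' @export
model_curve <- function(time, values) {
  time <- as.numeric(time)
  values <- as.numeric(values)
  if (length(time) != length(values)) {
    tmfret_error("`time` and `values` must have equal length",
                 "tmfret_format_error")
  }
  check_uniform_grid(time)
  if (!all(is.finite(values))) {
    tmfret_error("model values must be finite", "tmfret_format_error")
  }
  structure(list(time = time, values = values), class = "model_curve")
}

#' Matched sample / buffer / IRF acquisition
#'
#' Groups the three histograms of one TCSPC measurement.  All three must share
#' an identical time grid.  The buffer scaling `f_B` defaults to the ratio of
#' sample to buffer acquisition times, the rule used when the buffer trace is
#' measured for a different duration than the sample.
#'
#' @param sample,buffer,irf [decay_histogram()] objects with roles
#'   `"sample"`, `"buffer"`, `"irf"`.
#' @param f_B buffer scaling; default `sample$acquisition_time /
#'   buffer$acquisition_time`.
#' @return an object of class `acquisition_pair`.
#' @export
acquisition_pair <- function(sample, buffer, irf, f_B = NULL) {
  for (h in list(sample, buffer, irf)) {
    if (!inherits(h, "decay_histogram")) {
      tmfret_error("acquisition_pair() expects decay_histogram objects",
                   "tmfret_format_error")
    }
  }
  if (sample$role != "sample" || buffer$role != "buffer" || irf$role != "irf") {
    tmfret_error("histogram roles must be sample / buffer / irf",
                 "tmfret_format_error")
  }
  if (length(sample$time) != length(buffer$time) ||
      length(sample$time) != length(irf$time) ||
      max(abs(sample$time - buffer$time)) > 1e-9 ||
      max(abs(sample$time - irf$time)) > 1e-9) {
    tmfret_error("sample, buffer and IRF must share an identical time grid",
                 "tmfret_grid_error")
  }
  if (is.null(f_B)) {
    f_B <- sample$acquisition_time / buffer$acquisition_time
  }
  structure(list(sample = sample, buffer = buffer, irf = irf,
                 f_B = as.numeric(f_B)),
            class = "acquisition_pair")
}

#' @export
print.acquisition_pair <- function(x, ...) {
  cat(sprintf("<acquisition_pair> %d bins, f_B=%.4g, sample %.3g counts%s\n",
              length(x$sample$time), x$f_B, sum(x$sample$counts),
              if (nzchar(x$sample$label)) paste0(" [", x$sample$label, "]") else ""))
  invisible(x)
}

# I/O -------------------------------------------------------------------------

#' Read a TCSPC histogram from delimited text
#'
#' Expects two columns (time in ns, counts), tab or comma separated
#' (autodetected), with optional `#`-prefixed header lines carrying
#' `key=value` metadata (`acquisition_time_s`, `label`, `role`).
#'
#' @param path file path.
#' @param role role tag; overrides any role recorded in the file.
#' @return a [decay_histogram()].
#' @export
read_histogram <- function(path, role = NULL) {
  if (!file.exists(path)) {
    tmfret_error(paste0("no such file: ", path), "tmfret_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) {
    tmfret_error("histogram file has no data rows", "tmfret_format_error")
  }
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      meta[[key]] <- val
    }
  }
  sep <- if (grepl("\t", body[1L])) "\t" else if (grepl(",", body[1L])) "," else ""
  df <- tryCatch(
    read.table(text = body, sep = sep, header = FALSE,
               colClasses = "numeric", col.names = c("time_ns", "counts")),
    error = function(e) tmfret_error(
      paste0("cannot parse histogram file: ", conditionMessage(e)),
      "tmfret_format_error")
  )
  if (anyNA(df$time_ns) || anyNA(df$counts)) {
    tmfret_error("non-numeric values in histogram file", "tmfret_format_error")
  }
  if (any(df$counts < 0)) {
    tmfret_error("negative counts in histogram file", "tmfret_format_error")
  }
  if (is.null(role)) role <- meta$role %||% "sample"
  acq <- if (!is.null(meta$acquisition_time_s)) {
    as.numeric(meta$acquisition_time_s)
  } else {
    tmfret_warn(paste0("no acquisition_time_s metadata in ", path,
                       "; defaulting to 1 s"), "tmfret_metadata_warning")
    1
  }
  decay_histogram(df$time_ns, df$counts, role = role,
                  acquisition_time = acq, label = meta$label %||% "")
}

#' Write a TCSPC histogram as delimited text
#'
#' Writes a `#` metadata header (`role`, `acquisition_time_s`, `label`) and a
#' two-column tab-separated body.  Round-trips bit-exactly through
#' [read_histogram()]: counts as integers, time at full precision.
#'
#' @param h a [decay_histogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(h, path) {
  if (!inherits(h, "decay_histogram")) {
    tmfret_error("write_histogram() expects a decay_histogram",
                 "tmfret_format_error")
  }
  hdr <- c(
    paste0("# role=", h$role),
    paste0("# acquisition_time_s=", format(h$acquisition_time, digits = 17)),
    if (nzchar(h$label)) paste0("# label=", h$label)
  )
  body <- paste(format(h$time, digits = 17, scientific = FALSE, trim = TRUE),
                format(as.integer(round(h$counts)), scientific = FALSE),
                sep = "\t")
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) tmfret_error(paste0("cannot write ", path), "tmfret_io_error")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
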