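# Text import/export: two-column CSVs with '#'-prefixed metadata headers,
# '.' decimal, no thousands separators.

.write_csv_with_header <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a laser pulse-energy profile from CSV
#'
#' Expects two columns (wavenumber cm-1, pulse energy mJ); lines starting
#' with `#` are metadata and skipped.
#'
#' @param path CSV path.
#' @return an [energy_profile].
#' @export
read_energy_profile <- function(path) {
  df <- read.csv(path, comment.char = "#")
  if (ncol(df) < 2L) stop("energy profile CSV needs two columns (wn, energy)")
  energy_profile(df[[1L]], df[[2L]])
}

#' @rdname read_energy_profile
#' @param profile an [energy_profile].
#' @return `write_energy_profile`: `path`, invisibly.
#' @export
write_energy_profile <- function(profile, path) {
  stopifnot(inherits(profile, "energy_profile"))
  .write_csv_with_header(
    data.frame(wn_cm1 = profile$wn, energy_mJ = profile$energy), path,
    meta = "laser pulse-energy profile E(wavenumber)")
}

#' Export / import a retrieved IR spectrum as CSV
#'
#' Columns: `wn_cm1`, `sigma_rel`, `stderr`, `n_pairs`, `saturated`;
#' reference mode and normalization go into `#` metadata lines.
#'
#' @param spec an [ir_spectrum].
#' @param path CSV path.
#' @return `path` invisibly (write) or an [ir_spectrum] (read).
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "ir_spectrum"))
  df <- data.frame(wn_cm1 = spec$wn, sigma_rel = spec$sigma_rel,
                   stderr = spec$stderr, n_pairs = spec$n_pairs,
                   saturated = as.integer(spec$saturated))
  .write_csv_with_header(df, path, meta = c(
    paste0("reference_mode: ", attr(spec, "reference_mode")),
    paste0("normalization: ", attr(spec, "normalization"))))
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  pick <- function(key, default) {
    m <- grep(paste0(key, ":"), hdr, value = TRUE)
    if (length(m)) trimws(sub(paste0(".*", key, ":"), "", m[1L])) else default
  }
  df <- read.csv(path, comment.char = "#")
  ir_spectrum(df$wn_cm1, df$sigma_rel, df$stderr, df$n_pairs,
              as.logical(df$saturated),
              normalization = pick("normalization", "none"),
              reference_mode = pick("reference_mode", "untagged_off"))
}

#' Export a mobilogram as CSV
#'
#' Columns: `bin_start_ms`, `counts`.
#'
#' @param mob a [mobilogram].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_mobilogram_csv <- function(mob, path) {
  stopifnot(inherits(mob, "mobilogram"))
  .write_csv_with_header(
    data.frame(bin_start_ms = mob$bin_start, counts = mob$counts), path,
    meta = sprintf("cycle_time_ms: %g; bin_width_ms: %g",
                   mob$cycle_time, mob$bin_width))
}

#' Export / import a TOF calibration as JSON
#'
#' @param cal a [tof_calibration].
#' @param path JSON path.
#' @return `path` invisibly (write) or a [tof_calibration] (read).
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "tof_calibration"))
  jsonlite::write_json(
    list(model = "t = t0 + k*sqrt(mz)", t0 = cal$t0, k = cal$k,
         se_t0 = cal$se[["t0"]], se_k = cal$se[["k"]],
         residual_sd = cal$residual_sd),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  null2na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  tof_calibration(x$t0, x$k, se = c(null2na(x$se_t0), null2na(x$se_k)),
                  residual_sd = null2na(x$residual_sd))
}

#' Read (m/z, flight time) calibrant pairs from CSV
#'
#' Two columns (m/z Th, time us); `#` lines skipped.
#'
#' @param path CSV path.
#' @return data frame with columns `mz`, `tof`.
#' @export
read_calibrant_pairs <- function(path) {
  df <- read.csv(path, comment.char = "#")
  if (ncol(df) < 2L) stop("calibrant CSV needs two columns (mz, tof)")
  data.frame(mz = df[[1L]], tof = df[[2L]])
}
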