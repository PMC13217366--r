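# Binary raw-data container ("CTIR" format, version 1, little endian).
# Header: magic "CTIR" (4 bytes), version u16, t_start f64, dt f64,
#   n_samples u32, wn_start f64, wn_step f64, n_wn u32, cycles_per_wn u32,
#   cal_t0 f64, cal_k f64.
# Records: cycle_index u32, wn_index u32 (1-based), laser_state u8
#   (0 = off, 1 = on), intensities f32 x n_samples.

CTIR_MAGIC <- charToRaw("CTIR")
CTIR_VERSION <- 1L

.ctir_error <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "ctir_error")))
}

#' Write a raw dataset to the CTIR binary container
#'
#' Memory-efficient binary storage of a complete paired on/off scan:
#' intensities as f32 (digitizer-class precision), axes as f64, all little
#' endian, versioned header. Integer digitizer counts below 2^24 round-trip
#' bit-exactly; arbitrary doubles are quantized to f32 once on first write.
#'
#' @param dataset a `raw_dataset` with a uniform time axis and a complete
#'   wavenumber-by-cycle record set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_container <- function(dataset, path) {
  stopifnot(inherits(dataset, "raw_dataset"))
  ns <- vapply(dataset$traces, function(tr) length(tr$counts), 0L)
  if (length(unique(ns)) != 1L)
    stop("all traces must share one time axis")
  if (length(dataset$traces) != dataset$n_wn * dataset$cycles_per_wn * 2L)
    stop("incomplete scan: record count != n_wn * cycles_per_wn * 2")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(CTIR_MAGIC, con)
  writeBin(CTIR_VERSION, con, size = 2L, endian = "little")
  writeBin(c(dataset$t_start, dataset$dt), con, size = 8L, endian = "little")
  writeBin(as.integer(dataset$n_samples), con, size = 4L, endian = "little")
  writeBin(c(dataset$wn_start, dataset$wn_step), con, size = 8L,
           endian = "little")
  writeBin(as.integer(c(dataset$n_wn, dataset$cycles_per_wn)), con,
           size = 4L, endian = "little")
  writeBin(c(dataset$cal$t0, dataset$cal$k), con, size = 8L,
           endian = "little")
  for (tr in dataset$traces) {
    writeBin(as.integer(c(tr$meta$cycle_index, tr$meta$wn_index)), con,
             size = 4L, endian = "little")
    writeBin(as.integer(tr$meta$laser_state == "on"), con, size = 1L)
    writeBin(tr$counts, con, size = 4L, endian = "little")
  }
  invisible(path)
}

.read_or_die <- function(con, what, n, size, path, signed = TRUE) {
  offset_before <- seek(con, where = NA)
  x <- readBin(con, what, n = n, size = size, endian = "little",
               signed = signed)
  if (length(x) != n)
    .ctir_error("ctir_truncated",
                sprintf("truncated container '%s': expected %d more value(s) of %d byte(s) at byte offset %d",
                        path, n, size, offset_before))
  x
}

#' Read a CTIR binary container
#'
#' Validates the magic bytes and format version, then reads records one at
#' a time (streaming: memory per step is one record). With a `record_fun`
#' the traces are not accumulated; the function is called on each
#' [tof_trace] as it is read.
#'
#' @param path file path.
#' @param record_fun optional `function(trace)` called per record for
#'   streaming reads of files larger than memory.
#' @return a `raw_dataset` (with an empty scenario slot), or - when
#'   `record_fun` is given - the header fields only, invisibly.
#' @export
read_container <- function(path, record_fun = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) < 4L || !identical(magic, CTIR_MAGIC))
    .ctir_error("ctir_bad_magic",
                sprintf("'%s' is not a CTIR container (bad magic)", path))
  version <- .read_or_die(con, "integer", 1L, 2L, path)
  if (version != CTIR_VERSION)
    .ctir_error("ctir_bad_version",
                sprintf("unsupported CTIR version %d (reader supports %d)",
                        version, CTIR_VERSION))
  t_start <- .read_or_die(con, "double", 1L, 8L, path)
  dt <- .read_or_die(con, "double", 1L, 8L, path)
  n_samples <- .read_or_die(con, "integer", 1L, 4L, path)
  wn_start <- .read_or_die(con, "double", 1L, 8L, path)
  wn_step <- .read_or_die(con, "double", 1L, 8L, path)
  n_wn <- .read_or_die(con, "integer", 1L, 4L, path)
  cycles_per_wn <- .read_or_die(con, "integer", 1L, 4L, path)
  cal_t0 <- .read_or_die(con, "double", 1L, 8L, path)
  cal_k <- .read_or_die(con, "double", 1L, 8L, path)
  n_rec <- n_wn * cycles_per_wn * 2L
  traces <- if (is.null(record_fun)) vector("list", n_rec) else NULL
  for (r in seq_len(n_rec)) {
    idx <- .read_or_die(con, "integer", 2L, 4L, path)
    state <- .read_or_die(con, "integer", 1L, 1L, path)
    counts <- .read_or_die(con, "double", n_samples, 4L, path)
    tr <- tof_trace(t_start, dt, counts,
                    meta = list(cycle_index = idx[1L], wn_index = idx[2L],
                                wavenumber = wn_start + (idx[2L] - 1L) * wn_step,
                                laser_state = if (state == 1L) "on" else "off"))
    if (is.null(record_fun)) traces[[r]] <- tr else record_fun(tr)
  }
  header <- list(t_start = t_start, dt = dt, n_samples = n_samples,
                 wn_start = wn_start, wn_step = wn_step, n_wn = n_wn,
                 cycles_per_wn = cycles_per_wn,
                 cal = tof_calibration(cal_t0, cal_k), scenario = NULL)
  if (!is.null(record_fun)) return(invisible(header))
  structure(c(header, list(traces = traces)), class = "raw_dataset")
}
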