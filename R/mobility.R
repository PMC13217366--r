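#' Bin arrival-time events into a mobilogram
#'
#' Histogram over half-open bins `[i*w, (i+1)*w)` spanning the mobility
#' cycle; the number of bins is `ceiling(cycle_time / bin_width)` and total
#' counts are conserved.
#'
#' @param events arrival times, ms; all must lie in `[0, cycle_time)`.
#' @param cycle_time mobility cycle time, ms (instrument uses 10 or 25 ms).
#' @param bin_width bin width, ms (about 0.11 ms at the short cycle,
#'   about 0.22 ms at longer ones).
#' @return an object of class `mobilogram`: `cycle_time`, `bin_width`,
#'   `counts`, `bin_start` (left edges, ms), `meta`.
#' @export
bin_events <- function(events, cycle_time = 10, bin_width = 0.11) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  events <- as.numeric(events)
  bad <- which(events < 0 | events >= cycle_time)
  if (length(bad))
    stop(sprintf("events outside [0, %g) ms at indices: %s (values %s)",
                 cycle_time, paste(head(bad, 5L), collapse = ", "),
                 paste(signif(events[head(bad, 5L)], 4), collapse = ", ")))
  n_bins <- as.integer(ceiling(cycle_time / bin_width))
  counts <- tabulate(floor(events / bin_width) + 1L, nbins = n_bins)
  structure(list(cycle_time = cycle_time, bin_width = bin_width,
                 counts = as.numeric(counts),
                 bin_start = bin_width * (seq_len(n_bins) - 1L),
                 meta = list()),
            class = "mobilogram")
}

#' @export
print.mobilogram <- function(x, ...) {
  cat(sprintf("<mobilogram> %d bins x %.3g ms (cycle %g ms), %g events\n",
              length(x$counts), x$bin_width, x$cycle_time, sum(x$counts)))
  invisible(x)
}

# indices of strict-then-weak local maxima, plateau-safe
.local_maxima <- function(y) {
  n <- length(y)
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L] && y[i] >= y[i + 1L]) {
      j <- i
      while (j < n - 1L && y[j + 1L] == y[i]) j <- j + 1L
      if (j == n - 1L && y[n] == y[i]) { i <- j + 1L; next }
      if (y[j + 1L] < y[i]) idx <- c(idx, as.integer(round((i + j) / 2)))
      i <- j + 1L
    } else i <- i + 1L
  }
  idx
}

# half-height crossing on one flank; returns list(time, limited)
.flank_halfwidth <- function(t, y, i, half, dir) {
  j <- i
  repeat {
    nxt <- j + dir
    if (nxt < 1L || nxt > length(y)) return(list(time = NA_real_, limited = TRUE))
    if (y[nxt] <= half) {   # linear interpolation between j and nxt
      frac <- (y[j] - half) / (y[j] - y[nxt])
      return(list(time = t[j] + frac * (t[nxt] - t[j]), limited = FALSE))
    }
    if (y[nxt] > y[j]) return(list(time = t[j], limited = TRUE))  # hit valley
    j <- nxt
  }
}

#' Detect and characterize mobilogram peaks
#'
#' Local maxima with prominence at least `min_prominence` times the global
#' maximum are kept. Apexes are refined by three-point parabolic
#' interpolation; FWHM comes from linear interpolation of the half-height
#' crossings on both flanks, descending at most to the enclosing valleys.
#' When a flank reaches its valley before crossing half height (partially
#' resolved peaks) that side is flagged shoulder-limited and the clean
#' side's half-width is mirrored; if both sides are limited the
#' valley-to-valley width is reported.
#'
#' @param mob a [mobilogram] with at least 3 bins.
#' @param min_prominence prominence threshold as a fraction of the global
#'   maximum (default 0.05).
#' @return data frame (one row per peak, ordered by apex) with columns
#'   `apex` (ms), `fwhm` (ms), `height` (counts), `area` (counts*ms),
#'   `shoulder_limited` (logical).
#' @export
detect_peaks <- function(mob, min_prominence = 0.05) {
  stopifnot(inherits(mob, "mobilogram"))
  y <- mob$counts
  if (length(y) < 3L) stop("need at least 3 bins")
  tc <- mob$bin_start + mob$bin_width / 2
  ymax <- max(y)
  if (ymax <= 0) return(.empty_peaks())
  cand <- .local_maxima(y)
  if (!length(cand)) return(.empty_peaks())
  # prominence: drop to the highest valley separating the peak from higher ground
  prom <- vapply(cand, function(i) {
    lv <- y[i]; j <- i
    while (j > 1L && y[j - 1L] <= y[i]) { j <- j - 1L; lv <- min(lv, y[j]) }
    left <- if (j == 1L && y[1L] <= y[i]) min(lv, y[1L]) else lv
    rv <- y[i]; j <- i
    while (j < length(y) && y[j + 1L] <= y[i]) { j <- j + 1L; rv <- min(rv, y[j]) }
    right <- if (j == length(y) && y[length(y)] <= y[i]) min(rv, y[length(y)]) else rv
    y[i] - max(left, right)
  }, 0)
  keep <- cand[prom >= min_prominence * ymax]
  if (!length(keep)) return(.empty_peaks())
  out <- lapply(keep, function(i) {
    # parabolic apex refinement
    apex <- tc[i]; height <- y[i]
    if (i > 1L && i < length(y)) {
      denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
      if (denom < 0) {
        d <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
        d <- max(-0.5, min(0.5, d))
        apex <- tc[i] + d * mob$bin_width
        height <- y[i] - 0.25 * (y[i - 1L] - y[i + 1L]) * d
      }
    }
    half <- height / 2
    L <- .flank_halfwidth(tc, y, i, half, -1L)
    R <- .flank_halfwidth(tc, y, i, half, +1L)
    fwhm <- if (!L$limited && !R$limited) R$time - L$time
      else if (!L$limited) 2 * (apex - L$time)
      else if (!R$limited) 2 * (R$time - apex)
      else R$time - L$time
    # area between enclosing valleys
    lo <- i; while (lo > 1L && y[lo - 1L] < y[lo]) lo <- lo - 1L
    hi <- i; while (hi < length(y) && y[hi + 1L] < y[hi]) hi <- hi + 1L
    data.frame(apex = apex, fwhm = fwhm, height = height,
               area = sum(y[lo:hi]) * mob$bin_width,
               shoulder_limited = L$limited || R$limited)
  })
  res <- do.call(rbind, out)
  res[order(res$apex), , drop = FALSE]
}

.empty_peaks <- function() {
  data.frame(apex = numeric(), fwhm = numeric(), height = numeric(),
             area = numeric(), shoulder_limited = logical())
}

#' Arrival-time slice window
#'
#' Half-open gating interval `[center - width/2, center + width/2)`
#' emulating the exit-lens gate of the mobility cell.
#'
#' @param center window center, ms.
#' @param width window width, ms (> 0).
#' @return an object of class `slice_window`.
#' @export
slice_window <- function(center, width) {
  if (width <= 0) stop("width must be > 0")
  structure(list(center = center, width = width), class = "slice_window")
}

#' Gate arrival-time events through a slice window
#'
#' Returns exactly the events with
#' `center - width/2 <= t < center + width/2`, in their original order
#' (a sharp gate; the physical gate switches the exit-lens voltage).
#'
#' @param events arrival times, ms.
#' @param window a [slice_window].
#' @return the transmitted events.
#' @export
apply_slice <- function(events, window) {
  stopifnot(inherits(window, "slice_window"))
  lo <- window$center - window$width / 2
  hi <- window$center + window$width / 2
  events[events >= lo & events < hi]
}

#' Gate a measured mobilogram through a slice window
#'
#' Multiplies bin counts by a 0/1 gate: a bin passes when its center lies
#' inside the half-open window.
#'
#' @param mob a [mobilogram].
#' @param window a [slice_window].
#' @return the gated [mobilogram].
#' @export
slice_mobilogram <- function(mob, window) {
  stopifnot(inherits(mob, "mobilogram"), inherits(window, "slice_window"))
  centers <- mob$bin_start + mob$bin_width / 2
  gate <- centers >= window$center - window$width / 2 &
    centers < window$center + window$width / 2
  mob$counts <- mob$counts * as.numeric(gate)
  mob
}

#' Composition and transmission of a sliced, labeled event set
#'
#' Label-aware diagnostic for simulated data: which species make up the
#' transmitted events (purity; sums to 1) and which fraction of each
#' species' events the gate transmits (efficiency).
#'
#' @param times arrival times, ms.
#' @param labels species label per event.
#' @param window a [slice_window].
#' @return data frame with columns `species`, `purity`,
#'   `transmission_efficiency`.
#' @export
slice_purity <- function(times, labels, window) {
  stopifnot(length(times) == length(labels), length(times) > 0L)
  lo <- window$center - window$width / 2
  hi <- window$center + window$width / 2
  trans <- times >= lo & times < hi
  if (!any(trans)) stop("slice window transmits zero events")
  sp <- sort(unique(labels))
  data.frame(
    species = sp,
    purity = vapply(sp, function(s) sum(trans & labels == s) / sum(trans), 0),
    transmission_efficiency = vapply(sp, function(s)
      sum(trans & labels == s) / sum(labels == s), 0),
    row.names = NULL)
}
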