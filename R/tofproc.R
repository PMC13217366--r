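#' TOF calibration t = t0 + k * sqrt(m/z)
#'
#' Under constant acceleration voltages the flight time of an ion is
#' proportional to the square root of its m/z; the two-parameter model
#' `t(m/z) = t0 + k * sqrt(m/z)` maps between the time and m/z domains.
#'
#' @param t0 time offset, us.
#' @param k proportionality constant, us per sqrt(Th) (> 0).
#' @param se standard errors of `(t0, k)` from a fit, if available.
#' @param residual_sd residual standard deviation of the fit, us.
#' @return an object of class `tof_calibration`.
#' @export
tof_calibration <- function(t0, k, se = c(NA_real_, NA_real_),
                            residual_sd = NA_real_) {
  if (!is.finite(k) || k <= 0) stop("k must be finite and > 0")
  structure(list(t0 = t0, k = k, se = setNames(as.numeric(se), c("t0", "k")),
                 residual_sd = residual_sd),
            class = "tof_calibration")
}

#' Default instrument calibration used by the simulator
#'
#' Places m/z 500-600 near 41-45 us, inside one 18 kHz pusher period
#' (55.6 us).
#'
#' @return a [tof_calibration] with `t0 = 2` us, `k = 1.75` us/sqrt(Th).
#' @export
default_calibration <- function() tof_calibration(t0 = 2, k = 1.75)

#' @rdname tof_calibration
#' @param cal a [tof_calibration].
#' @param mz m/z values, Th (> 0).
#' @return `mz_to_tof`: flight times, us.
#' @export
mz_to_tof <- function(cal, mz) {
  stopifnot(inherits(cal, "tof_calibration"))
  if (any(mz <= 0)) stop("m/z must be > 0")
  cal$t0 + cal$k * sqrt(mz)
}

#' @rdname tof_calibration
#' @param t flight times, us (> t0).
#' @return `tof_to_mz`: m/z values, Th.
#' @export
tof_to_mz <- function(cal, t) {
  stopifnot(inherits(cal, "tof_calibration"))
  if (any(t <= cal$t0)) stop("flight time must exceed t0")
  ((t - cal$t0) / cal$k)^2
}

#' @export
print.tof_calibration <- function(x, ...) {
  cat(sprintf("<tof_calibration> t = %.6g + %.6g * sqrt(m/z) us (resid sd %.3g)\n",
              x$t0, x$k, x$residual_sd))
  invisible(x)
}

#' Fit a TOF calibration from (m/z, flight time) pairs
#'
#' Least-squares fit of `t = t0 + k * sqrt(m/z)` (a linear model in
#' `sqrt(m/z)`), returning parameter standard errors and residual
#' diagnostics.
#'
#' @param pairs data frame with columns `mz` (Th) and `tof` (us); at least
#'   two distinct m/z values.
#' @return a [tof_calibration] with `se`, `residual_sd` and a `residuals`
#'   attribute.
#' @examples
#' cal <- fit_calibration(data.frame(mz = c(100, 400), tof = c(19.5, 37)))
#' cal$k
#' @export
fit_calibration <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (!all(c("mz", "tof") %in% names(pairs)))
    stop("pairs needs columns mz and tof")
  if (nrow(pairs) < 2L || length(unique(pairs$mz)) < 2L)
    stop("need >= 2 pairs with distinct m/z")
  fit <- lm(tof ~ I(sqrt(mz)), data = pairs)
  cf <- coef(fit)
  if (cf[2] <= 0) stop("fitted k is not positive; calibration degenerate")
  res <- unname(stats::residuals(fit))
  n <- nrow(pairs)
  if (n > 2L) {
    sigma <- sqrt(sum(res^2) / (n - 2L))
    X <- cbind(1, sqrt(pairs$mz))
    se <- sigma * sqrt(diag(solve(crossprod(X))))
  } else {
    sigma <- 0
    se <- c(NA_real_, NA_real_)
  }
  cal <- tof_calibration(unname(cf[1]), unname(cf[2]), se = se,
                         residual_sd = sigma)
  attr(cal, "residuals") <- res
  cal
}

#' A digitized TOF transient
#'
#' Uniformly sampled time-domain record of one pusher extraction, with
#' acquisition metadata (cycle index, laser state, wavenumber).
#'
#' @param t_start first sample time, us.
#' @param dt sample spacing, us (> 0).
#' @param counts nonnegative-length numeric vector of digitizer counts.
#' @param meta metadata list.
#' @return an object of class `tof_trace`.
#' @export
tof_trace <- function(t_start, dt, counts, meta = list()) {
  if (dt <= 0) stop("dt must be > 0")
  if (length(counts) < 1L) stop("counts must have length >= 1")
  structure(list(t_start = t_start, dt = dt,
                 counts = if (is.double(counts)) counts
                          else as.numeric(counts),
                 meta = meta), class = "tof_trace")
}

#' Time axis of a trace
#' @param trace a [tof_trace].
#' @return numeric vector of sample times, us.
#' @export
trace_times <- function(trace) {
  trace$t_start + trace$dt * (seq_along(trace$counts) - 1L)
}

#' @export
print.tof_trace <- function(x, ...) {
  cat(sprintf("<tof_trace> %d samples, %.4g-%.4g us, dt %.4g us [%s]\n",
              length(x$counts), x$t_start,
              x$t_start + x$dt * (length(x$counts) - 1L), x$dt,
              paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Rolling-quantile baseline subtraction
#'
#' Estimates the baseline as a low rolling quantile of the trace and
#' subtracts it. Peaks occupy a small fraction of any window, so a low
#' quantile tracks the offset without following the peaks; after
#' subtraction, peak-free regions average about zero (negative samples are
#' retained). For speed the quantile is evaluated every `stride` samples and
#' linearly interpolated between evaluation points; `stride = 1` gives the
#' exact rolling quantile.
#'
#' @param trace a [tof_trace].
#' @param window window length in samples (odd, >= 3, <= trace length).
#' @param quantile_ baseline quantile in `(0, 0.5]` (default 0.1).
#' @param stride evaluation stride in samples; default `max(1, window %/% 8)`.
#' @return the baseline-corrected [tof_trace].
#' @export
baseline_correct <- function(trace, window = 501L, quantile_ = 0.1,
                             stride = NULL) {
  stopifnot(inherits(trace, "tof_trace"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  n <- length(trace$counts)
  if (window > n) stop("window longer than trace")
  if (quantile_ <= 0 || quantile_ > 0.5) stop("quantile_ must be in (0, 0.5]")
  if (is.null(stride)) stride <- max(1L, window %/% 8L)
  h <- window %/% 2L
  at <- unique(c(seq.int(1L, n, by = as.integer(stride)), n))
  # type-7 sample quantile via partial sort (hot path)
  q7 <- function(x, p) {
    m <- length(x)
    v <- 1 + (m - 1) * p
    j <- floor(v)
    g <- v - j
    s <- sort.int(x, partial = c(j, min(j + 1, m)))
    if (g > 0) (1 - g) * s[j] + g * s[j + 1L] else s[j]
  }
  q <- vapply(at, function(i) {
    lo <- if (i > h) i - h else 1L
    hi <- if (i + h < n) i + h else n
    q7(trace$counts[lo:hi], quantile_)
  }, 0)
  base <- if (length(at) == n) q else approx(at, q, xout = seq_len(n))$y
  tof_trace(trace$t_start, trace$dt, trace$counts - base, meta = trace$meta)
}

#' A calibrated mass spectrum
#'
#' @param mz strictly increasing m/z grid, Th.
#' @param intensity intensities (may be negative after baseline
#'   subtraction).
#' @param meta metadata list, inherited from the source trace.
#' @return an object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, meta = list()) {
  if (length(mz) != length(intensity)) stop("mz and intensity length mismatch")
  if (is.unsorted(mz, strictly = TRUE)) stop("mz grid must be strictly increasing")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 meta = meta), class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %d points, m/z %.3f-%.3f\n",
              length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

#' Convert a TOF trace to a calibrated mass spectrum
#'
#' Samples at `t <= t0` (no physical m/z) are dropped; the remaining times
#' map to `m/z = ((t - t0)/k)^2`. By default intensities are rescaled by the
#' Jacobian `dt/dmz = k^2 / (2 (t - t0))` so that integrals are conserved
#' between domains: a peak's m/z-domain area then equals its time-domain
#' area regardless of where it sits on the flight-time axis. Set
#' `jacobian = FALSE` to carry raw per-sample intensities over unchanged
#' (window integrals then acquire a slow sqrt(m/z) tilt).
#'
#' @param trace a [tof_trace].
#' @param cal a [tof_calibration].
#' @param jacobian rescale intensities to conserve area (default `TRUE`).
#' @return a [mass_spectrum].
#' @export
trace_to_spectrum <- function(trace, cal, jacobian = TRUE) {
  if (!inherits(trace, "tof_trace") || !inherits(cal, "tof_calibration"))
    stop("need a tof_trace and a tof_calibration")
  t <- trace_times(trace)
  keep <- t > cal$t0
  if (!any(keep)) stop("entire trace lies at t <= t0; calibration invalid here")
  t <- t[keep]
  y <- trace$counts[keep]
  mz <- ((t - cal$t0) / cal$k)^2
  if (jacobian) y <- y * cal$k^2 / (2 * (t - cal$t0))
  mass_spectrum(mz, y, meta = trace$meta)
}

#' Trapezoidal window integral of a mass spectrum
#'
#' Integrates intensity over the half-open window `[lo, hi)` by the
#' trapezoidal rule, with the boundary ordinates obtained by linear
#' interpolation, so integrals are exactly additive over adjacent windows.
#' A window entirely outside the spectrum returns 0 with a warning.
#'
#' @param spec a [mass_spectrum].
#' @param lo,hi window bounds, Th (`lo < hi`).
#' @return integrated intensity (counts, m/z-domain units).
#' @export
integrate_window <- function(spec, lo, hi) {
  if (!inherits(spec, "mass_spectrum")) stop("spec must be a mass_spectrum")
  if (!(lo < hi)) stop("need lo < hi")
  mz <- spec$mz; y <- spec$intensity
  n <- length(mz)
  a <- max(lo, mz[1L]); b <- min(hi, mz[n])
  if (a >= b) {
    warning("integration window outside spectrum range; returning 0")
    return(0)
  }
  interp1 <- function(x) {          # linear interpolation on the sorted grid
    i <- findInterval(x, mz, rightmost.closed = TRUE)
    if (i >= n) return(y[n])
    y[i] + (x - mz[i]) / (mz[i + 1L] - mz[i]) * (y[i + 1L] - y[i])
  }
  i0 <- findInterval(a, mz) + 1L          # first grid point strictly > a
  i1 <- findInterval(b, mz, left.open = TRUE)  # last grid point strictly < b
  if (i0 > i1) {                    # no interior points: one trapezoid
    return((b - a) * (interp1(a) + interp1(b)) / 2)
  }
  xs <- c(a, mz[i0:i1], b)
  ys <- c(interp1(a), y[i0:i1], interp1(b))
  m <- length(xs)
  sum((xs[-1L] - xs[-m]) * (ys[-1L] + ys[-m])) / 2
}

#' N2 tag series of one base ion
#'
#' Intensities of the 0, 1, ..., N tag peaks, integrated in windows of
#' half-width `window_halfwidth` around `base_mz + n * 28.006 / |z|`, plus
#' intensity-weighted centroids of each window.
#'
#' @param spec a [mass_spectrum].
#' @param base_mz m/z of the untagged ion, Th.
#' @param charge signed integer charge.
#' @param max_tags largest tag count extracted (>= 0).
#' @param window_halfwidth integration half-width, Th; must be positive and
#'   below half the tag spacing so windows cannot overlap.
#' @return an object of class `tag_series`: list with `base_mz`, `charge`,
#'   `intensities` (length `max_tags + 1`), `centroids`,
#'   `window_halfwidth`.
#' @export
extract_tag_series <- function(spec, base_mz, charge, max_tags = 6L,
                               window_halfwidth = 0.35) {
  stopifnot(inherits(spec, "mass_spectrum"))
  charge <- as.integer(charge)
  if (charge == 0L) stop("charge must be nonzero")
  if (max_tags < 0L) stop("max_tags must be >= 0")
  spacing <- TAG_MASS_DA / abs(charge)
  if (window_halfwidth <= 0 || window_halfwidth >= spacing / 2)
    stop(sprintf("window_halfwidth must be in (0, %.4g) to keep tag windows disjoint",
                 spacing / 2))
  n <- 0:max_tags
  centers <- base_mz + n * spacing
  intens <- cents <- numeric(length(n))
  for (i in seq_along(n)) {
    lo <- centers[i] - window_halfwidth
    hi <- centers[i] + window_halfwidth
    intens[i] <- integrate_window(spec, lo, hi)
    inside <- spec$mz >= lo & spec$mz < hi
    w <- pmax(spec$intensity[inside], 0)
    cents[i] <- if (sum(w) > 0) sum(spec$mz[inside] * w) / sum(w) else NA_real_
  }
  structure(list(base_mz = base_mz, charge = charge, intensities = intens,
                 centroids = cents, window_halfwidth = window_halfwidth),
            class = "tag_series")
}

#' @export
print.tag_series <- function(x, ...) {
  cat(sprintf("<tag_series> base m/z %.4f (z=%+d): %s\n", x$base_mz, x$charge,
              paste(sprintf("I%d=%.3g", seq_along(x$intensities) - 1L,
                            x$intensities), collapse = " ")))
  invisible(x)
}

#' Mean N2 tag count of a tag series
#'
#' `sum(n * I_n) / sum(I_n)` with negative intensities clipped to zero
#' before the sums (noise below baseline carries no tag information).
#'
#' @param series a [tag_series].
#' @return mean tag count (dimensionless).
#' @export
mean_tag_count <- function(series) {
  stopifnot(inherits(series, "tag_series"))
  I <- pmax(series$intensities, 0)
  if (sum(I) <= 0) stop("all-zero tag series; mean tag count undefined")
  n <- seq_along(I) - 1L
  sum(n * I) / sum(I)
}
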