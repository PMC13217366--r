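#' Pair laser-on/off window integrals per wavenumber
#'
#' For every trace: baseline-correct, calibrate to m/z, integrate the
#' monitored m/z window. Integrals are then paired (off, on) within each
#' acquisition cycle using the traces' metadata, so trace order is
#' irrelevant. Unpaired trailing cycles are dropped with a warning; a
#' wavenumber with no complete pair is an error.
#'
#' @param dataset a `raw_dataset` (see [simulate_scan()] /
#'   [read_container()]).
#' @param mz_window numeric `c(lo, hi)` monitored m/z window, Th.
#' @param cal a [tof_calibration] (default: the dataset's).
#' @param baseline_window,baseline_quantile rolling-quantile baseline
#'   settings passed to [baseline_correct()].
#' @return list with `wn` (wavenumber grid) and `pairs`: one
#'   `n_pairs x 2` matrix per wavenumber with columns `I_off`, `I_on`.
#' @export
pair_cycles <- function(dataset, mz_window, cal = dataset$cal,
                        baseline_window = 501L, baseline_quantile = 0.1) {
  stopifnot(inherits(dataset, "raw_dataset"), length(mz_window) == 2L,
            mz_window[1] < mz_window[2])
  meta <- lapply(dataset$traces, `[[`, "meta")
  wn_idx <- vapply(meta, `[[`, 0, "wn_index")
  cyc <- vapply(meta, `[[`, 0, "cycle_index")
  state <- vapply(meta, `[[`, "", "laser_state")
  wn_val <- vapply(meta, `[[`, 0, "wavenumber")
  ints <- vapply(dataset$traces, function(tr) {
    bw <- min(baseline_window,
              if (length(tr$counts) %% 2L) length(tr$counts)
              else length(tr$counts) - 1L)
    sp <- trace_to_spectrum(baseline_correct(tr, bw, baseline_quantile), cal)
    integrate_window(sp, mz_window[1], mz_window[2])
  }, 0)
  wn_levels <- sort(unique(wn_idx))
  out <- vector("list", length(wn_levels))
  wn_out <- numeric(length(wn_levels))
  dropped <- 0L
  for (i in seq_along(wn_levels)) {
    sel <- wn_idx == wn_levels[i]
    wn_out[i] <- wn_val[sel][1L]
    cycles <- sort(unique(cyc[sel]))
    rows <- lapply(cycles, function(cc) {
      io <- ints[sel & cyc == cc & state == "off"]
      ii <- ints[sel & cyc == cc & state == "on"]
      if (length(io) == 1L && length(ii) == 1L) c(I_off = io, I_on = ii)
      else NULL
    })
    dropped <- dropped + sum(vapply(rows, is.null, TRUE))
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (!length(rows))
      stop(sprintf("no complete on/off pair at wavenumber %g cm-1", wn_out[i]))
    out[[i]] <- do.call(rbind, rows)
  }
  if (dropped > 0L)
    warning(sprintf("dropped %d unpaired trap cycle(s)", dropped))
  list(wn = wn_out, pairs = out)
}

#' Depleted fraction from paired intensities
#'
#' `F = (I_on - I_off) / I_off` for the untagged reference (the monitored
#' untagged peak gains intensity when tags are lost), or
#' `F = (I_off - I_on) / I_off` for the tagged reference (the summed tag
#' series loses intensity). Noise can make F negative; strong depletion can
#' push the untagged-reference F past 1 (see [linearize()]).
#'
#' @param I_on,I_off integrated window intensities; `I_off` must be > 0.
#' @param reference_mode `"untagged_off"` (default) or `"tagged_off"`.
#' @return the depleted fraction (dimensionless); vectorized.
#' @export
depletion_fraction <- function(I_on, I_off,
                               reference_mode = c("untagged_off",
                                                  "tagged_off")) {
  reference_mode <- match.arg(reference_mode)
  if (any(I_off <= 0)) stop("reference signal I_off vanished (<= 0)")
  if (reference_mode == "untagged_off") (I_on - I_off) / I_off
  else (I_off - I_on) / I_off
}

#' Saturation linearization of the depleted fraction
#'
#' Ions that already lost their tag cannot report further absorption, so
#' the observed depleted fraction saturates; `S = -log(1 - F)` undoes this.
#' F is capped below 1 before the log; capped points are flagged saturated.
#' Negative F (pure noise around zero) passes through the formula, giving
#' small negative S, which keeps null spectra symmetric about zero.
#'
#' @param F depleted fraction(s).
#' @param cap saturation cap in (0, 1) (default 0.999).
#' @return list with `S` (linearized signal) and `saturated` (logical).
#' @export
linearize <- function(F, cap = 0.999) {
  if (cap <= 0 || cap >= 1) stop("cap must be in (0, 1)")
  saturated <- F >= cap
  list(S = -log(1 - pmin(F, cap)), saturated = saturated)
}

#' Photon-flux normalization
#'
#' The photon flux of a near-diffraction-limited focus is proportional to
#' pulse energy over wavelength, i.e. to `E * wn`; dividing the linearized
#' signal by it yields the relative absorption cross-section
#' `sigma_rel = S / (E * wn)` (equal to the wavelength-form expression up
#' to a fixed unit constant absorbed by the relative scale).
#'
#' @param S linearized depletion signal(s).
#' @param wn wavenumber, cm-1 (> 0).
#' @param energy pulse energy, mJ (> 0).
#' @return sigma_rel (arbitrary units); vectorized.
#' @export
flux_normalize <- function(S, wn, energy) {
  if (any(energy <= 0)) stop("pulse energy must be > 0")
  if (any(wn <= 0)) stop("wavenumber must be > 0")
  S / (energy * wn)
}

#' Retrieved relative absorption spectrum
#'
#' @param wn wavenumber grid, cm-1.
#' @param sigma_rel relative cross-section values.
#' @param stderr per-point standard errors (>= 0).
#' @param n_pairs on/off pairs per point.
#' @param saturated logical saturation flags.
#' @param F_dep,S_lin intermediate depleted fraction and linearized signal.
#' @param normalization `"none"` or `"max1"`.
#' @param reference_mode reference mode used in retrieval.
#' @return an object of class `ir_spectrum` (also a data frame).
#' @export
ir_spectrum <- function(wn, sigma_rel, stderr, n_pairs, saturated,
                        F_dep = NA_real_, S_lin = NA_real_,
                        normalization = "none",
                        reference_mode = "untagged_off") {
  df <- data.frame(wn = wn, sigma_rel = sigma_rel, stderr = stderr,
                   n_pairs = n_pairs, saturated = saturated,
                   F_dep = F_dep, S_lin = S_lin)
  structure(df, class = c("ir_spectrum", "data.frame"),
            normalization = normalization, reference_mode = reference_mode)
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d points, %g-%g cm-1 (%s reference, normalization %s)\n",
              nrow(x), min(x$wn), max(x$wn), attr(x, "reference_mode"),
              attr(x, "normalization")))
  NextMethod()
}

#' @export
plot.ir_spectrum <- function(x, ...) {
  plot(x$wn, x$sigma_rel, type = "l", xlab = "wavenumber (cm-1)",
       ylab = "relative cross-section (arb.)", ...)
  segments(x$wn, x$sigma_rel - x$stderr, x$wn, x$sigma_rel + x$stderr,
           col = "grey60")
  invisible(x)
}

#' Retrieve an IR spectrum from a paired on/off dataset
#'
#' Implements the full inverse chain: per wavenumber, on and off window
#' integrals are summed over pairs (ratio of sums - lower bias than the
#' mean of per-pair ratios at low counts; `per_pair = TRUE` gives the
#' alternative), the depleted fraction is formed against the chosen
#' reference, linearized with the saturation cap, and divided by the photon
#' flux `E * wn`. Per-point standard errors come from a leave-one-pair-out
#' jackknife. The laser-off reference in each cycle absorbs drifts in both
#' overall signal intensity and tagging efficiency.
#'
#' @param dataset a `raw_dataset`.
#' @param mz_window monitored m/z window `c(lo, hi)`: the untagged peak for
#'   `reference_mode = "untagged_off"`, the summed tag series for
#'   `"tagged_off"`.
#' @param profile an [energy_profile] covering the scan grid (default: the
#'   simulating scenario's).
#' @param reference_mode `"untagged_off"` (default) or `"tagged_off"`.
#' @param cap saturation cap passed to [linearize()].
#' @param normalization `"none"` or `"max1"` (scale so max sigma_rel = 1).
#' @param per_pair average per-pair ratios instead of the ratio of sums.
#' @param cal,baseline_window,baseline_quantile passed to [pair_cycles()].
#' @return an [ir_spectrum].
#' @export
retrieve_spectrum <- function(dataset, mz_window,
                              profile = dataset$scenario$scan$energy_profile,
                              reference_mode = c("untagged_off", "tagged_off"),
                              cap = 0.999,
                              normalization = c("none", "max1"),
                              per_pair = FALSE,
                              cal = dataset$cal,
                              baseline_window = 501L,
                              baseline_quantile = 0.1) {
  reference_mode <- match.arg(reference_mode)
  normalization <- match.arg(normalization)
  if (is.null(profile)) stop("an energy profile is required")
  pc <- pair_cycles(dataset, mz_window, cal, baseline_window,
                    baseline_quantile)
  energies <- interp_energy(profile, pc$wn)
  sgn <- if (reference_mode == "untagged_off") 1 else -1
  point <- function(on, off, wn, energy) {
    if (any(off <= 0)) stop("reference signal I_off vanished (<= 0)")
    Fv <- if (per_pair) mean(sgn * (on - off) / off)
      else sgn * (sum(on) - sum(off)) / sum(off)
    saturated <- Fv >= cap
    S <- -log(1 - min(Fv, cap))
    list(F = Fv, S = S, saturated = saturated, sigma = S / (energy * wn))
  }
  n_wn <- length(pc$wn)
  sig <- Fv <- Sv <- se <- numeric(n_wn)
  sat <- logical(n_wn)
  npair <- integer(n_wn)
  for (i in seq_len(n_wn)) {
    m <- pc$pairs[[i]]
    on <- m[, "I_on"]; off <- m[, "I_off"]
    npair[i] <- nrow(m)
    full <- point(on, off, pc$wn[i], energies[i])
    sig[i] <- full$sigma; Fv[i] <- full$F; Sv[i] <- full$S
    sat[i] <- full$saturated
    if (nrow(m) >= 2L) {
      loo <- vapply(seq_len(nrow(m)), function(j)
        point(on[-j], off[-j], pc$wn[i], energies[i])$sigma, 0)
      nj <- length(loo)
      se[i] <- sqrt((nj - 1) / nj * sum((loo - mean(loo))^2))
    } else se[i] <- NA_real_
  }
  if (normalization == "max1") {
    mx <- max(sig)
    if (mx <= 0) stop("cannot normalize: maximum sigma_rel is not positive")
    sig <- sig / mx
    se <- se / mx
  }
  ir_spectrum(pc$wn, sig, se, npair, sat, F_dep = Fv, S_lin = Sv,
              normalization = normalization, reference_mode = reference_mode)
}
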