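#' Draw N2 tag counts for a population of trapped ions
#'
#' Tag attachment is modeled as independent rare events, giving a Poisson
#' tag-count distribution with the species' mean. An alternative sampler can
#' be injected for non-Poisson tagging statistics.
#'
#' @param mean_tags Poisson mean tag count (>= 0).
#' @param n_ions number of ions (>= 0).
#' @param seed integer seed (optional).
#' @param sampler function `(n, mean)` returning `n` nonnegative integer
#'   counts; defaults to `rpois`.
#' @return integer vector of length `n_ions`.
#' @export
sample_tag_counts <- function(mean_tags, n_ions, seed = NULL,
                              sampler = function(n, mean) rpois(n, mean)) {
  if (mean_tags < 0) stop("mean_tags must be >= 0")
  if (n_ions < 0) stop("n_ions must be >= 0")
  with_seed(seed, as.integer(sampler(n_ions, mean_tags)))
}

#' Per-tag photodetachment probability
#'
#' Single-photon tag loss under a pulse with fluence proportional to
#' `energy * wn` (the photon flux of a near-diffraction-limited focus is
#' proportional to pulse energy over wavelength, i.e. to E times the
#' wavenumber): `p = 1 - exp(-fluence_scale * sigma * energy * wn)`.
#' Vectorized over its arguments.
#'
#' @param true_sigma_value relative absorption cross-section (>= 0).
#' @param wn wavenumber, cm-1 (>= 0).
#' @param energy pulse energy, mJ (>= 0).
#' @param fluence_scale dimensionless calibration constant (>= 0).
#' @return detachment probability in `[0, 1)`.
#' @export
detag_probability <- function(true_sigma_value, wn, energy, fluence_scale) {
  if (any(true_sigma_value < 0) || any(wn < 0) || any(energy < 0) ||
      any(fluence_scale < 0))
    stop("all detag_probability inputs must be >= 0")
  1 - exp(-fluence_scale * true_sigma_value * energy * wn)
}

#' Apply one laser pulse to a tagged ion population
#'
#' Each attached tag detaches independently with probability `p`; tag counts
#' never increase. Laser-off cycles correspond to `p = 0` and return the
#' input unchanged.
#'
#' @param tag_counts integer vector of tag counts.
#' @param p per-tag detachment probability in `[0, 1]`.
#' @param seed integer seed (optional).
#' @return integer vector of surviving tag counts.
#' @export
apply_laser <- function(tag_counts, p, seed = NULL) {
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single probability in [0, 1]")
  tag_counts <- as.integer(tag_counts)
  if (any(tag_counts < 0)) stop("tag counts must be >= 0")
  if (p == 0 || length(tag_counts) == 0L) return(tag_counts)
  with_seed(seed, as.integer(rbinom(length(tag_counts), tag_counts, 1 - p)))
}

#' Sample ion arrival times after mobility separation
#'
#' Gaussian arrival-time distribution parameterized by apex and FWHM
#' (sd = FWHM / 2.3548).
#'
#' @param spec an [ion_species].
#' @param n number of events (>= 0).
#' @param seed integer seed (optional).
#' @return numeric vector of arrival times, ms.
#' @export
sample_arrival_times <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "ion_species"))
  if (n < 0) stop("n must be >= 0")
  with_seed(seed, rnorm(n, spec$arrival_mean, spec$arrival_fwhm / FWHM_SD))
}

#' Sample labeled arrival events from a whole scenario
#'
#' Events are allocated to species in proportion to their relative
#' abundances and drawn from each species' arrival-time distribution; times
#' are clamped into `[0, cycle_time)` (the instrument wraps nothing - the
#' presets place all mass far inside the cycle).
#'
#' @param scenario_ a [scenario].
#' @param n total number of events.
#' @param seed integer seed (optional).
#' @return data frame with columns `time` (ms) and `species` (label).
#' @export
sample_scenario_events <- function(scenario_, n, seed = NULL) {
  stopifnot(inherits(scenario_, "scenario"))
  w <- vapply(scenario_$species, function(s) s$rel_abundance, 0)
  with_seed(seed, {
    idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    t <- numeric(n)
    for (i in seq_along(scenario_$species)) {
      k <- idx == i
      t[k] <- rnorm(sum(k), scenario_$species[[i]]$arrival_mean,
                    scenario_$species[[i]]$arrival_fwhm / FWHM_SD)
    }
    t <- pmin(pmax(t, 0), scenario_$cycle_time_ms - 1e-9)
    data.frame(time = t,
               species = vapply(scenario_$species, function(s) s$name,
                                "")[idx])
  })
}

#' Synthesize one digitized TOF transient
#'
#' Each population row contributes a Gaussian peak centered at the flight
#' time of its m/z, with time-domain area `n_ions * area_per_ion`. A
#' constant baseline offset is added, and (optionally) Poisson counting
#' noise is drawn per sample. An empty population yields pure baseline.
#'
#' @param populations data frame (or list) with elements `mz` (Th) and
#'   `n_ions` (>= 0), one entry per peak.
#' @param calibration a [tof_calibration].
#' @param t_start,t_end,dt uniform time axis, us.
#' @param peak_fwhm_us TOF peak full width at half maximum, us (> 0).
#' @param baseline constant baseline offset, counts per sample.
#' @param area_per_ion time-domain peak area contributed by one ion,
#'   counts*us.
#' @param noise add Poisson counting noise (`FALSE` gives the expectation).
#' @param seed integer seed for the noise draw.
#' @param meta metadata list (`cycle_index`, `laser_state`, `wavenumber`).
#' @return a [tof_trace].
#' @export
synth_tof_trace <- function(populations, calibration, t_start, t_end,
                            dt = 0.001, peak_fwhm_us = 0.01, baseline = 5,
                            area_per_ion = 0.01, noise = TRUE, seed = NULL,
                            meta = list()) {
  if (!inherits(calibration, "tof_calibration"))
    stop("calibration must be a tof_calibration")
  if (peak_fwhm_us <= 0) stop("peak_fwhm_us must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  pop_mz <- populations$mz
  pop_n <- populations$n_ions
  if (length(pop_n) > 0 && any(pop_n < 0)) stop("populations must be >= 0")
  if (length(pop_mz) > 0 && any(pop_mz <= 0)) stop("m/z must be > 0")
  nt <- floor((t_end - t_start) / dt) + 1L
  t <- t_start + dt * (seq_len(nt) - 1L)
  y <- numeric(nt)
  s <- peak_fwhm_us / FWHM_SD
  for (i in seq_along(pop_n)) {
    if (pop_n[i] == 0) next
    tc <- calibration$t0 + calibration$k * sqrt(pop_mz[i])
    amp <- pop_n[i] * area_per_ion / (s * sqrt(2 * pi))
    lo <- max(1L, floor((tc - 6 * s - t_start) / dt) + 1L)
    hi <- min(nt, ceiling((tc + 6 * s - t_start) / dt) + 1L)
    if (lo > hi) next
    y[lo:hi] <- y[lo:hi] + amp * exp(-((t[lo:hi] - tc)^2) / (2 * s^2))
  }
  y <- y + baseline
  if (noise) y <- with_seed(seed, rpois(length(y), y))
  tof_trace(t_start, dt, as.numeric(y), meta = meta)
}

# expected tag-count population vector 0..n_max for one species
.expected_tag_pop <- function(n_total, mu, p = 0, n_max = NULL) {
  if (is.null(n_max))
    n_max <- max(2L, stats::qpois(1 - 1e-9, max(mu, 1e-9)) + 2L)
  pop <- n_total * dpois(0:n_max, mu)
  if (p > 0) {
    out <- numeric(n_max + 1L)
    for (k in 0:n_max)  # binomial thinning of each k-tag class
      out[1:(k + 1L)] <- out[1:(k + 1L)] + pop[k + 1L] * dbinom(0:k, k, 1 - p)
    pop <- out
  }
  pop
}

# per-(species, tag-count) populations for one trap cycle
# (returns a plain list(mz, n_ions); hot path of the simulator)
.cycle_populations <- function(scenario_, wn, laser_on, stochastic, energy) {
  fs <- scenario_$scan$fluence_scale
  w_tot <- sum(vapply(scenario_$species, function(s) s$rel_abundance, 0))
  mzs <- ns <- list()
  for (i in seq_along(scenario_$species)) {
    sp <- scenario_$species[[i]]
    p <- if (laser_on)
      detag_probability(eval_sigma(sp, wn), wn, energy, fs) else 0
    if (stochastic) {
      n <- rpois(1L, scenario_$ions_per_cycle * sp$rel_abundance / w_tot)
      counts <- sample_tag_counts(sp$mean_tags, n)
      if (laser_on) counts <- apply_laser(counts, p)
      if (n > 0) {
        tb <- tabulate(counts + 1L, nbins = max(counts) + 1L)
        mzs[[i]] <- tag_mz(sp, seq_along(tb) - 1L)
        ns[[i]] <- as.numeric(tb)
      }
    } else {
      n <- scenario_$ions_per_cycle * sp$rel_abundance / w_tot
      pop <- .expected_tag_pop(n, sp$mean_tags, p)
      mzs[[i]] <- tag_mz(sp, seq_along(pop) - 1L)
      ns[[i]] <- pop
    }
  }
  list(mz = unlist(mzs), n_ions = unlist(ns))
}

#' Simulate a full paired laser-on/laser-off IR scan
#'
#' For every wavenumber on the scan grid, `cycles_per_wavenumber` acquisition
#' cycles are generated, each holding one laser-off and one laser-on trap
#' cycle. Per-cycle ion numbers fluctuate as Poisson draws around the source
#' rate (electrospray fluctuation), tag counts are Poisson, the laser removes
#' tags independently with the wavenumber-dependent probability, and traces
#' carry Poisson counting noise on a constant baseline. With
#' `stochastic = FALSE` every draw is replaced by its expectation, producing
#' the noiseless dataset used for round-trip validation.
#'
#' @param scenario_ a [scenario].
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @param stochastic draw ion numbers, tag counts and counting noise
#'   (`TRUE`), or use expectations (`FALSE`).
#' @return a `raw_dataset`: list with the time axis, wavenumber grid,
#'   `cycles_per_wn`, the calibration, the scenario, and a list of
#'   [tof_trace] objects ordered by wavenumber then cycle, off before on.
#' @export
simulate_scan <- function(scenario_, seed = NULL, stochastic = TRUE) {
  stopifnot(inherits(scenario_, "scenario"))
  wn_grid <- scan_grid(scenario_$scan)
  energies <- interp_energy(scenario_$scan$energy_profile, wn_grid)
  tofp <- scenario_$tof
  n_cyc <- scenario_$trap$cycles_per_wavenumber
  with_seed(seed, {
    traces <- vector("list", length(wn_grid) * n_cyc * 2L)
    k <- 0L
    for (iw in seq_along(wn_grid)) {
      for (ic in seq_len(n_cyc)) {
        for (state in c("off", "on")) {
          pop <- .cycle_populations(scenario_, wn_grid[iw], state == "on",
                                    stochastic, energies[iw])
          k <- k + 1L
          traces[[k]] <- synth_tof_trace(
            pop, scenario_$cal, tofp$t_start, tofp$t_end, tofp$dt,
            tofp$peak_fwhm_us, tofp$baseline, tofp$area_per_ion,
            noise = stochastic,
            meta = list(cycle_index = ic, wn_index = iw,
                        wavenumber = wn_grid[iw], laser_state = state))
        }
      }
    }
    structure(list(
      t_start = tofp$t_start, dt = tofp$dt,
      n_samples = length(traces[[1L]]$counts),
      wn_start = scenario_$scan$wn_start, wn_step = scenario_$scan$wn_step,
      n_wn = length(wn_grid), cycles_per_wn = n_cyc,
      cal = scenario_$cal, scenario = scenario_, traces = traces
    ), class = "raw_dataset")
  })
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat(sprintf("<raw_dataset> %d wavenumbers x %d pairs (%d traces, %d samples each)\n",
              x$n_wn, x$cycles_per_wn, length(x$traces), x$n_samples))
  invisible(x)
}

#' Simulate a single tagging mass spectrum
#'
#' Generates one population of `n_ions` ions from the scenario (all species,
#' abundance-weighted), tags them, optionally fires the laser, synthesizes a
#' TOF transient, baseline-corrects it and calibrates it to the m/z domain.
#' Convenience wrapper for tag-series work that does not need a full scan.
#'
#' @param scenario_ a [scenario].
#' @param n_ions total number of ions (split by relative abundance).
#' @param seed integer seed.
#' @param laser_state `"off"` or `"on"`.
#' @param wn wavenumber used when the laser is on, cm-1.
#' @param stochastic sample (`TRUE`) or use expectations (`FALSE`).
#' @return a [mass_spectrum].
#' @export
simulate_tagging_spectrum <- function(scenario_, n_ions = 1e5, seed = NULL,
                                      laser_state = c("off", "on"),
                                      wn = NULL, stochastic = TRUE) {
  stopifnot(inherits(scenario_, "scenario"))
  laser_state <- match.arg(laser_state)
  if (laser_state == "on" && is.null(wn))
    stop("wn is required when laser_state = 'on'")
  sc <- scenario_
  sc$ions_per_cycle <- n_ions
  energy <- if (laser_state == "on")
    interp_energy(sc$scan$energy_profile, wn) else 0
  tofp <- sc$tof
  with_seed(seed, {
    pop <- .cycle_populations(sc, if (is.null(wn)) 0 else wn,
                              laser_state == "on", stochastic, energy)
    tr <- synth_tof_trace(pop, sc$cal, tofp$t_start, tofp$t_end, tofp$dt,
                          tofp$peak_fwhm_us, tofp$baseline, tofp$area_per_ion,
                          noise = stochastic,
                          meta = list(cycle_index = 1L, laser_state = laser_state,
                                      wavenumber = if (is.null(wn)) NA_real_ else wn))
    trace_to_spectrum(baseline_correct(tr), sc$cal)
  })
}

#' Restrict a scenario to an arrival-time slice
#'
#' Emulates exit-lens gating at the scenario level: each species' relative
#' abundance is multiplied by the fraction of its Gaussian arrival-time
#' distribution falling inside the (sharp, half-open) window, which is what
#' the trap downstream of the gate receives.
#'
#' @param scenario_ a [scenario].
#' @param window a [slice_window].
#' @return the gated [scenario].
#' @export
slice_scenario <- function(scenario_, window) {
  stopifnot(inherits(scenario_, "scenario"), inherits(window, "slice_window"))
  lo <- window$center - window$width / 2
  hi <- window$center + window$width / 2
  for (i in seq_along(scenario_$species)) {
    sp <- scenario_$species[[i]]
    sdv <- sp$arrival_fwhm / FWHM_SD
    frac <- pnorm(hi, sp$arrival_mean, sdv) - pnorm(lo, sp$arrival_mean, sdv)
    scenario_$species[[i]]$rel_abundance <- sp$rel_abundance * frac
  }
  tot <- sum(vapply(scenario_$species, function(s) s$rel_abundance, 0))
  if (tot <= 0) stop("slice window transmits no ions")
  scenario_$name <- paste0(scenario_$name, "_sliced")
  scenario_
}
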