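#' Ground-truth description of one analyte species
#'
#' An `ion_species` carries everything the forward simulator needs: the mass
#' and adduct defining the base m/z, the arrival-time distribution after the
#' mobility cell, the mean N2 tag count in the cryogenic trap, and a true
#' relative absorption cross-section curve given as a sum of Gaussian bands.
#'
#' @param name species label.
#' @param neutral_mass monoisotopic neutral mass, Da (> 0).
#' @param adduct_mass adduct ion mass, Da (proton 1.00728, sodium 22.98922).
#' @param charge signed integer charge; sign encodes the instrument polarity.
#' @param arrival_mean apex of the arrival-time distribution, ms.
#' @param arrival_fwhm full width at half maximum of the arrival-time
#'   distribution, ms (> 0).
#' @param rel_abundance relative abundance weight (>= 0).
#' @param mean_tags Poisson mean of the N2 tag count (>= 0).
#' @param sigma_bands data frame with columns `center` (cm-1), `fwhm` (cm-1)
#'   and `amplitude` (>= 0): Gaussian bands summed into the true relative
#'   cross-section curve.
#' @param label_mz optional nominal (printed) m/z label; the exact base m/z is
#'   always computed from the masses and never reconciled with the label.
#' @return an object of class `ion_species`.
#' @examples
#' sp <- ion_species("demo", 555.26935, 1.00728, 1L, 5, 0.4,
#'                   sigma_bands = data.frame(center = 1600, fwhm = 30, amplitude = 1))
#' base_mz(sp)
#' eval_sigma(sp, c(1500, 1600))
#' @export
ion_species <- function(name, neutral_mass, adduct_mass, charge,
                        arrival_mean, arrival_fwhm,
                        rel_abundance = 1, mean_tags = 1,
                        sigma_bands, label_mz = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(neutral_mass) || neutral_mass <= 0)
    stop("neutral_mass must be > 0")
  charge <- as.integer(charge)
  if (charge == 0L) stop("charge must be nonzero")
  if (arrival_fwhm <= 0) stop("arrival_fwhm must be > 0")
  if (rel_abundance < 0) stop("rel_abundance must be >= 0")
  if (mean_tags < 0) stop("mean_tags must be >= 0")
  sigma_bands <- as.data.frame(sigma_bands)
  need <- c("center", "fwhm", "amplitude")
  if (!all(need %in% names(sigma_bands)))
    stop("sigma_bands needs columns center, fwhm, amplitude")
  if (any(sigma_bands$fwhm <= 0) || any(sigma_bands$amplitude < 0))
    stop("sigma_bands: fwhm must be > 0 and amplitude >= 0")
  structure(list(
    name = name, neutral_mass = neutral_mass, adduct_mass = adduct_mass,
    charge = charge, arrival_mean = arrival_mean, arrival_fwhm = arrival_fwhm,
    rel_abundance = rel_abundance, mean_tags = mean_tags,
    sigma_bands = sigma_bands[need], label_mz = label_mz
  ), class = "ion_species")
}

#' Base (untagged) m/z of a species
#'
#' `(neutral_mass + adduct_mass * |z|) / |z|`; always computed from the exact
#' masses, independent of any nominal `label_mz`.
#'
#' @param species an [ion_species].
#' @return base m/z, Th.
#' @export
base_mz <- function(species) {
  z <- abs(species$charge)
  (species$neutral_mass + species$adduct_mass * z) / z
}

#' m/z of the n-tag peak of a species
#'
#' Tag peaks sit at `base_mz + n * 28.006 / |z|`.
#'
#' @param species an [ion_species].
#' @param n integer vector of tag counts (>= 0).
#' @return m/z values, Th.
#' @export
tag_mz <- function(species, n) {
  base_mz(species) + n * TAG_MASS_DA / abs(species$charge)
}

#' Evaluate a species' true relative cross-section curve
#'
#' Sum of the Gaussian bands in `sigma_bands`; nonnegative everywhere and
#' expressed in arbitrary relative units.
#'
#' @param species an [ion_species].
#' @param wn wavenumber(s), cm-1.
#' @return numeric vector, same length as `wn`.
#' @export
eval_sigma <- function(species, wn) {
  b <- species$sigma_bands
  v <- numeric(length(wn))
  for (i in seq_len(nrow(b))) {
    s <- b$fwhm[i] / FWHM_SD
    v <- v + b$amplitude[i] * exp(-((wn - b$center[i])^2) / (2 * s^2))
  }
  v
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s  m/z %.4f (z=%+d)  tags ~Pois(%.3g)  arrival %.2f ms (FWHM %.2f)\n",
              x$name, base_mz(x), x$charge, x$mean_tags,
              x$arrival_mean, x$arrival_fwhm))
  invisible(x)
}

#' Trap-cycle timing configuration
#'
#' Timing of one trapping cycle: ion accumulation and tagging, irradiation,
#' and release to the TOF pusher. Defaults reflect 50 ms accumulation, laser
#' fire at 50.092 ms, a pusher retriggered at 18 kHz inside the 50.045-50.099
#' ms release window, and a 100 ms acquisition cycle holding one laser-off
#' plus one laser-on trap cycle (20 Hz alternation against a 10 Hz laser).
#' These values are carried as metadata and consistency-checked; they do not
#' enter the depletion statistics.
#'
#' @param accumulation_ms ion accumulation interval, ms (start, end).
#' @param gas_pulse_lead_ms tagging-gas pulse lead before ions enter, ms.
#' @param laser_fire_ms laser firing time within the trap cycle, ms.
#' @param pusher_window_ms pusher trigger window, ms (start, end).
#' @param pusher_freq_kHz pusher retrigger frequency, kHz.
#' @param acquisition_cycle_ms one full on+off acquisition cycle, ms.
#' @param cycles_per_wavenumber number of on/off pairs averaged per grid point.
#' @param on_off_alternation alternate laser-off/laser-on trap cycles.
#' @return an object of class `trap_cycle_config`.
#' @export
trap_cycle_config <- function(accumulation_ms = c(0, 50),
                              gas_pulse_lead_ms = 2,
                              laser_fire_ms = 50.092,
                              pusher_window_ms = c(50.045, 50.099),
                              pusher_freq_kHz = 18,
                              acquisition_cycle_ms = 100,
                              cycles_per_wavenumber = 75L,
                              on_off_alternation = TRUE) {
  stopifnot(length(accumulation_ms) == 2L, length(pusher_window_ms) == 2L)
  if (accumulation_ms[2] > pusher_window_ms[1])
    stop("accumulation must end before the pusher release window opens")
  if (laser_fire_ms < pusher_window_ms[1] || laser_fire_ms > pusher_window_ms[2])
    stop("laser_fire_ms must lie inside the release window")
  cycles_per_wavenumber <- as.integer(cycles_per_wavenumber)
  if (cycles_per_wavenumber < 1L) stop("cycles_per_wavenumber must be >= 1")
  structure(list(
    accumulation_ms = accumulation_ms, gas_pulse_lead_ms = gas_pulse_lead_ms,
    laser_fire_ms = laser_fire_ms, pusher_window_ms = pusher_window_ms,
    pusher_freq_kHz = pusher_freq_kHz,
    acquisition_cycle_ms = acquisition_cycle_ms,
    cycles_per_wavenumber = cycles_per_wavenumber,
    on_off_alternation = on_off_alternation
  ), class = "trap_cycle_config")
}

#' Laser pulse-energy profile E(nu)
#'
#' Two-column table of wavenumber (cm-1, strictly increasing) and pulse
#' energy (mJ, > 0). Queries interpolate linearly in wavenumber;
#' extrapolation outside the recorded grid is an error.
#'
#' @param wn wavenumber grid, cm-1.
#' @param energy pulse energy at each grid point, mJ.
#' @return an object of class `energy_profile`.
#' @export
energy_profile <- function(wn, energy) {
  wn <- as.numeric(wn); energy <- as.numeric(energy)
  if (length(wn) != length(energy) || length(wn) < 2L)
    stop("energy_profile needs >= 2 matched (wn, energy) points")
  if (any(diff(wn) <= 0)) stop("energy_profile grid must be strictly increasing")
  if (any(energy <= 0)) stop("pulse energies must be > 0")
  structure(list(wn = wn, energy = energy), class = "energy_profile")
}

#' Interpolate a pulse-energy profile
#'
#' @param profile an [energy_profile].
#' @param wn query wavenumber(s), cm-1; must lie inside the recorded grid.
#' @return pulse energies, mJ.
#' @export
interp_energy <- function(profile, wn) {
  stopifnot(inherits(profile, "energy_profile"))
  if (any(wn < min(profile$wn) | wn > max(profile$wn)))
    stop(sprintf("wavenumber outside recorded energy profile [%g, %g] cm-1",
                 min(profile$wn), max(profile$wn)))
  approx(profile$wn, profile$energy, xout = wn)$y
}

#' Default mid-IR OPO/OPA pulse-energy profile
#'
#' A smooth synthetic stand-in for a measured pyroelectric power-sensor
#' profile: rises roughly linearly from 1.5 mJ near 1000 cm-1 (10 um) toward
#' 3.5 mJ at 2000 cm-1 (5 um), matching the class of benchtop difference-
#' frequency sources used for fingerprint-region tagging spectroscopy.
#'
#' @param wn_min,wn_max grid limits, cm-1.
#' @param step grid spacing, cm-1.
#' @return an [energy_profile].
#' @export
default_energy_profile <- function(wn_min = 900, wn_max = 1950, step = 25) {
  wn <- seq(wn_min, wn_max, by = step)
  energy_profile(wn, 1.5 + 2.0 * (wn - 1000) / 1000)
}

#' Laser scan configuration
#'
#' Wavenumber grid of the IR scan plus the pulse-energy profile and the
#' fluence calibration constant that converts `sigma * E * wn` into the
#' detagging exponent of the forward model.
#'
#' @param wn_start,wn_stop scan limits, cm-1 (start < stop).
#' @param wn_step scan increment, cm-1 (> 0); the grid has
#'   `floor((stop-start)/step) + 1` points.
#' @param energy_profile an [energy_profile] covering the grid.
#' @param fluence_scale dimensionless calibration constant (>= 0).
#' @return an object of class `laser_scan_config`.
#' @export
laser_scan_config <- function(wn_start = 990, wn_stop = 1810, wn_step = 2,
                              energy_profile = default_energy_profile(),
                              fluence_scale = 1e-4) {
  if (!(wn_start < wn_stop)) stop("wn_start must be < wn_stop")
  if (wn_step <= 0) stop("wn_step must be > 0")
  if (fluence_scale < 0) stop("fluence_scale must be >= 0")
  stopifnot(inherits(energy_profile, "energy_profile"))
  structure(list(wn_start = wn_start, wn_stop = wn_stop, wn_step = wn_step,
                 energy_profile = energy_profile,
                 fluence_scale = fluence_scale),
            class = "laser_scan_config")
}

#' Wavenumber grid of a scan configuration
#'
#' @param scan a [laser_scan_config].
#' @return numeric vector of grid points, cm-1.
#' @export
scan_grid <- function(scan) {
  stopifnot(inherits(scan, "laser_scan_config"))
  n <- floor((scan$wn_stop - scan$wn_start) / scan$wn_step) + 1L
  scan$wn_start + scan$wn_step * (seq_len(n) - 1L)
}
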