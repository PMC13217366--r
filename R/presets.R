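#' Assemble a simulation scenario
#'
#' A scenario bundles the species list with the trap timing, laser scan,
#' TOF calibration and trace-synthesis settings, and is the single input the
#' forward simulator consumes.
#'
#' @param species list of [ion_species] objects (at least one).
#' @param trap a [trap_cycle_config].
#' @param scan a [laser_scan_config].
#' @param cal a [tof_calibration] used both to synthesize and to read back
#'   traces.
#' @param ions_per_cycle expected number of ions released per trap cycle
#'   (electrospray source rate; per-cycle numbers fluctuate as Poisson draws).
#' @param cycle_time_ms ion-mobility cycle time, ms (10 or 25 on the
#'   instrument; arrival times live in `[0, cycle_time_ms)`).
#' @param tof list of trace-synthesis settings: `dt` (sample spacing, us),
#'   `peak_fwhm_us` (TOF peak width), `baseline` (counts per sample),
#'   `area_per_ion` (counts*us per ion), and optional `t_start`/`t_end` (us;
#'   derived from the species m/z range when omitted).
#' @param name scenario label.
#' @return an object of class `scenario`.
#' @export
scenario <- function(species, trap = trap_cycle_config(),
                     scan = laser_scan_config(),
                     cal = default_calibration(),
                     ions_per_cycle = 2000,
                     cycle_time_ms = 10,
                     tof = list(), name = "custom") {
  if (inherits(species, "ion_species")) species <- list(species)
  stopifnot(length(species) >= 1L,
            all(vapply(species, inherits, TRUE, "ion_species")),
            inherits(trap, "trap_cycle_config"),
            inherits(scan, "laser_scan_config"),
            inherits(cal, "tof_calibration"))
  if (ions_per_cycle <= 0) stop("ions_per_cycle must be > 0")
  defaults <- list(dt = 0.001, peak_fwhm_us = 0.01, baseline = 5,
                   area_per_ion = 0.01, t_start = NULL, t_end = NULL)
  tof <- modifyList(defaults, tof)
  if (is.null(tof$t_start) || is.null(tof$t_end)) {
    mu_max <- max(vapply(species, function(s) s$mean_tags, 0))
    n_hi <- stats::qpois(1 - 1e-9, max(mu_max, 1e-6)) + 2L
    mz_lo <- min(vapply(species, base_mz, 0)) - 4
    mz_hi <- max(vapply(species, tag_mz, 0, n = n_hi)) + 4
    if (is.null(tof$t_start)) tof$t_start <- mz_to_tof(cal, mz_lo)
    if (is.null(tof$t_end))   tof$t_end   <- mz_to_tof(cal, mz_hi)
  }
  structure(list(name = name, species = species, trap = trap, scan = scan,
                 cal = cal, ions_per_cycle = ions_per_cycle,
                 cycle_time_ms = cycle_time_ms, tof = tof),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %d species, scan %g-%g cm-1 step %g, %d pairs/point\n",
              x$name, length(x$species), x$scan$wn_start, x$scan$wn_stop,
              x$scan$wn_step, x$trap$cycles_per_wavenumber))
  for (s in x$species) print(s)
  invisible(x)
}

# exact monoisotopic masses (Da)
.MASS_LEU_ENK <- 555.26935   # leucine enkephalin, C28H37N5O7
.MASS_TRISACCH <- 504.16903  # C18H32O16 (melezitose / cellotriose)
.MASS_PROTON <- 1.00728
.MASS_SODIUM <- 22.98922     # Na+ (electron subtracted)

.preset_bands <- function(which) {
  switch(which,
    leu_enk = data.frame(  # peptide fingerprint: amide II/I, strongest at 1688
      center    = c(1080, 1245, 1520, 1602, 1688),
      fwhm      = c(45, 50, 42, 30, 28),
      amplitude = c(0.35, 0.45, 0.60, 0.50, 1.00)),
    melezitose = data.frame(  # C-O stretch/deformation-dominated pattern
      center    = c(1035, 1075, 1150, 1245, 1440, 1640),
      fwhm      = c(40, 35, 45, 60, 50, 40),
      amplitude = c(1.00, 0.70, 0.55, 0.30, 0.25, 0.15)),
    cellotriose = data.frame(  # isomer: same bond types, shifted band pattern
      center    = c(1020, 1060, 1165, 1370, 1520, 1700),
      fwhm      = c(40, 35, 45, 60, 50, 40),
      amplitude = c(0.80, 1.00, 0.50, 0.35, 0.20, 0.10)))
}

.species_melezitose <- function(rel_abundance = 0.4, mean_tags = 1) {
  ion_species("melezitose", .MASS_TRISACCH, .MASS_SODIUM, 1L,
              arrival_mean = 4.75, arrival_fwhm = 0.4,
              rel_abundance = rel_abundance, mean_tags = mean_tags,
              sigma_bands = .preset_bands("melezitose"), label_mz = 526.4)
}

#' Built-in ground-truth scenarios
#'
#' Three presets emulating the instrument's demonstration measurements:
#' \describe{
#'   \item{`"leu_enk"`}{one species, protonated leucine enkephalin monomer
#'     (\[M+H\]+ m/z 556.277, z = +1), mean tag count 1 - so the tagging
#'     yield P(>= 1 tag) is 1 - 1/e (about 63\%, comfortably above half).}
#'   \item{`"trisaccharide_mixture"`}{sodiated melezitose and cellotriose,
#'     isobaric trisaccharides at the same exact m/z (527.158; nominal label
#'     526.4), arrival apexes 4.75 and 5.35 ms, FWHM 0.4 ms, relative
#'     abundances 0.4/0.6. Mean tag counts 1 and 8/3, so the mixture's
#'     abundance-weighted mean tag count is exactly 2 while the early
#'     (melezitose) component's is 1.}
#'   \item{`"melezitose_sliced"`}{the early mixture component alone, i.e. the
#'     ideal outcome of slicing a 0.5 ms arrival-time window centered on
#'     4.75 ms.}
#' }
#' The per-preset fluence calibration constant is set so that the strongest
#' band reaches 92.5\% depletion of the tagged-ion series at the default
#' pulse-energy profile - the middle of the 90-95\% operating window used to
#' maximize dynamic range without fully saturating tag depletion.
#'
#' @param preset_name one of `"leu_enk"`, `"trisaccharide_mixture"`,
#'   `"melezitose_sliced"`.
#' @param cycles_per_wavenumber on/off pairs averaged per wavenumber
#'   (default 75).
#' @return a [scenario].
#' @examples
#' sc <- make_preset("trisaccharide_mixture")
#' vapply(sc$species, function(s) s$arrival_mean, 0)
#' @export
make_preset <- function(preset_name, cycles_per_wavenumber = 75L) {
  valid <- c("leu_enk", "trisaccharide_mixture", "melezitose_sliced")
  if (!is.character(preset_name) || length(preset_name) != 1L ||
      !preset_name %in% valid)
    stop("unknown preset; valid names: ", paste(valid, collapse = ", "))
  species <- switch(preset_name,
    leu_enk = list(
      ion_species("leucine_enkephalin_H", .MASS_LEU_ENK, .MASS_PROTON, 1L,
                  arrival_mean = 5.0, arrival_fwhm = 0.4,
                  rel_abundance = 1, mean_tags = 1,
                  sigma_bands = .preset_bands("leu_enk"))),
    trisaccharide_mixture = list(
      .species_melezitose(rel_abundance = 0.4, mean_tags = 1),
      ion_species("cellotriose", .MASS_TRISACCH, .MASS_SODIUM, 1L,
                  arrival_mean = 5.35, arrival_fwhm = 0.4,
                  rel_abundance = 0.6, mean_tags = 8 / 3,
                  sigma_bands = .preset_bands("cellotriose"),
                  label_mz = 526.4)),
    melezitose_sliced = list(
      .species_melezitose(rel_abundance = 1, mean_tags = 1)))
  sc <- scenario(species,
                 trap = trap_cycle_config(
                   cycles_per_wavenumber = cycles_per_wavenumber),
                 scan = laser_scan_config(fluence_scale = 0),
                 name = preset_name)
  sc$scan$fluence_scale <- fluence_for_depletion(sc, target = 0.925,
                                                 reference_mode = "tagged_off")
  sc
}

#' Expected depleted fraction of the forward model (closed form)
#'
#' Analytic expectation of the depleted fraction F at each wavenumber, under
#' Poisson tag counts and independent per-tag removal with probability
#' `p = 1 - exp(-fluence_scale * sigma * E * wn)`. For the untagged
#' reference (the retrieval's default) the gain of the untagged peak is
#' normalized by its laser-off level; for the tagged reference the loss of
#' the summed tag series is normalized by its laser-off level. Species are
#' combined with their relative abundances (isobaric species share the
#' monitored window).
#'
#' @param scenario_ a [scenario].
#' @param wn wavenumbers, cm-1 (default: the scan grid).
#' @param reference_mode `"untagged_off"` or `"tagged_off"`.
#' @param fluence_scale override of the scenario's fluence constant.
#' @return numeric vector of expected F values.
#' @export
expected_depletion <- function(scenario_, wn = scan_grid(scenario_$scan),
                               reference_mode = c("untagged_off", "tagged_off"),
                               fluence_scale = scenario_$scan$fluence_scale) {
  reference_mode <- match.arg(reference_mode)
  E <- interp_energy(scenario_$scan$energy_profile, wn)
  off <- on <- numeric(length(wn))
  for (sp in scenario_$species) {
    w <- sp$rel_abundance
    mu <- sp$mean_tags
    p <- detag_probability(eval_sigma(sp, wn), wn, E, fluence_scale)
    if (reference_mode == "untagged_off") {
      off <- off + w * exp(-mu)
      on  <- on  + w * exp(-mu * (1 - p))
    } else {
      off <- off + w * (1 - exp(-mu))
      on  <- on  + w * (1 - exp(-mu * (1 - p)))
    }
  }
  if (reference_mode == "untagged_off") (on - off) / off else (off - on) / off
}

#' Fluence constant reaching a target peak depletion
#'
#' Solves for the fluence calibration constant at which the maximum expected
#' depleted fraction over the scan grid equals `target`; used to place a
#' scenario in a chosen operating regime (e.g. the 90-95\% tag-depletion
#' setting, or a weak-depletion linear regime for validation).
#'
#' @param scenario_ a [scenario].
#' @param target peak depleted fraction in (0, 1).
#' @param reference_mode `"untagged_off"` or `"tagged_off"` (see
#'   [expected_depletion()]).
#' @return fluence scale (dimensionless).
#' @export
fluence_for_depletion <- function(scenario_, target,
                                  reference_mode = c("untagged_off",
                                                     "tagged_off")) {
  reference_mode <- match.arg(reference_mode)
  if (target <= 0 || target >= 1) stop("target must be in (0, 1)")
  wn <- scan_grid(scenario_$scan)
  g <- function(fs) max(expected_depletion(scenario_, wn, reference_mode,
                                           fluence_scale = fs)) - target
  hi <- 1e-6
  while (g(hi) < 0 && hi < 1e6) hi <- hi * 10
  if (g(hi) < 0) stop("target depletion not reachable in this mode")
  uniroot(g, c(1e-15, hi), tol = 1e-12)$root
}
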