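---
title: "Retrieving messenger-tagging IR spectra: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieving messenger-tagging IR spectra: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cirispec)
```

## The measurement this package models

In messenger-tagging (cryogenic) IR ion spectroscopy, ions are accumulated
in a cold trap (30–45 K), where weakly bound N2 "messenger" tags attach and
shift each ion by +28 Da per tag per charge. A tunable mid-IR pulse then
irradiates the released ion packet: if the ion absorbs a single resonant
photon, the redistributed energy evaporates a tag. Comparing mass spectra
recorded with and without the laser therefore reports IR absorption — tagged
peaks shrink and the untagged peak grows — and scanning the laser over the
fingerprint region (here 990–1810 cm⁻¹, 2 cm⁻¹ steps) traces out an action
spectrum. Because the platform also performs traveling-wave ion-mobility
separation, an arrival-time gate upstream of the trap can select a single
mobility feature (e.g. one trisaccharide isomer from an isobaric mixture)
before spectroscopy.

`cirispec` implements both directions of this experiment:

* a **forward simulator** (trap cycle, Poisson tagging, mobilograms, TOF
  transient synthesis) that generates raw paired laser-on/laser-off data
  with known ground truth, and
* the **retrieval pipeline** (baseline correction, √(m/z) calibration,
  window integration, tag-series extraction, depletion linearization,
  photon-flux normalization, jackknife uncertainties) that turns such raw
  data — simulated or measured — into relative absorption cross-sections.

## The retrieval equations

For each wavenumber $\tilde\nu$, the monitored m/z window is integrated in
laser-on and laser-off cycles of the same acquisition cycle, giving
$I_\mathrm{ON}$ and $I_\mathrm{OFF}$. The depleted fraction is

$$F(\tilde\nu) = \frac{I_\mathrm{ON}(\tilde\nu) - I_\mathrm{OFF}(\tilde\nu)}{I_\mathrm{OFF}(\tilde\nu)}$$

with the laser-off signal of the *untagged* ion as the reference
(`reference_mode = "untagged_off"`); the off-reference in every cycle
absorbs drifts in total ion signal and in tagging efficiency. Since an ion
that has already lost its tag cannot report a second absorption in the same
cycle, the observed fraction saturates, and is linearized as

$$S(\tilde\nu) = -\ln\!\left(1 - F(\tilde\nu)\right).$$

The photon flux of a near-diffraction-limited focus is proportional to
pulse energy over wavelength, i.e. to $E(\tilde\nu)\cdot\tilde\nu$, so the
relative cross-section is

$$\sigma_\mathrm{rel}(\tilde\nu) = \frac{S(\tilde\nu)}{E(\tilde\nu)\,\tilde\nu},$$

equal to the wavelength-form expression up to a fixed constant that the
relative (arbitrary-unit) scale absorbs.

### The two reference modes

The literature's text formula normalizes the *gain of the untagged peak* by
its own laser-off level, while the operating prescription — "set pulse
energies for 90–95 % tag depletion" — refers to the *loss of the tagged
series*. These differ materially. Writing $\mu$ for the Poisson mean tag
count and $p$ for the per-tag detachment probability, the expectation of
the forward model gives

* untagged reference: $F = e^{\mu p} - 1$ (super-linear in $p$; exceeds 1
  when $\mu p > \ln 2$), and
* tagged reference: $F = \frac{e^{-\mu(1-p)} - e^{-\mu}}{1 - e^{-\mu}}$
  (approaches $p$ exactly as $\mu \to 0$).

Both are implemented (`reference_mode = "untagged_off"` is the default,
matching the text formula; `"tagged_off"` monitors the summed tag series),
and the closed forms above are available as `expected_depletion()`. Two
consequences, verified analytically before the test suite froze its
expectations:

1. **The linearization correction is a tagged-reference concept.** At 90 %
   tag depletion the linearized retrieval is strictly closer to the true
   cross-section than the raw-$F$ retrieval in tagged-reference mode
   (relative RMS 0.056 vs 0.075 on the benchmark band set), whereas in
   untagged-reference mode the raw $F$ is itself already super-linear and
   $-\ln(1-F)$ over-corrects. The saturation-benefit test therefore runs in
   tagged-reference mode, at the fluence that `fluence_for_depletion()`
   places at 90 % peak tag depletion.
2. **Untagged-reference retrieval is shape-faithful only at weak
   depletion.** Round-trip validation against ground truth therefore runs
   in a weak-depletion linear regime (peak depleted fraction 0.10, where
   the residual shape distortion is 1.4 % RMS, inside the 2 % validation
   budget). This mirrors practice: quantitative band shapes require an
   unsaturated operating point, while the 90–95 % setting maximizes
   dynamic range for band *positions*.

### Averaging and uncertainties

Within one wavenumber the on/off integrals are summed over the averaged
acquisition cycles before the ratio is formed (ratio of sums), which is
less biased at low counts than averaging per-pair ratios; `per_pair =
TRUE` provides the alternative, and the two agree exactly on noiseless
data. Per-point standard errors come from a leave-one-pair-out jackknife
of the full statistic ($F \to S \to \sigma_\mathrm{rel}$). A simulation
study (10 replicates of a 103-point null scan at 75 pairs/point) found the
jackknife 3-SE exceedance rate to be 0.0039, matching the $t_{74}$
expectation of 0.0037 — the estimator is well calibrated, and null spectra
are consistent with zero at the advertised rate.

Negative $F$ from noise passes through the linearization (giving small
negative $S$), keeping null spectra symmetric about zero; the saturation
cap (default 0.999) replaces the $\ln$ domain error, and capped points are
flagged rather than dropped.

## The forward model and what it does (not) emulate

* **Tag counts** are Poisson with the species' mean — the minimal model for
  independent rare attachment events; the sampler is injectable for other
  distributions. The benchmark peptide preset uses mean 1, giving a
  tagging yield $P(\ge 1\ \mathrm{tag}) = 1 - e^{-1} \approx 63\%$.
* **Detagging**: one absorbed photon removes one tag; tags detach
  independently with probability
  $p = 1 - e^{-c\,\sigma(\tilde\nu)\,E(\tilde\nu)\,\tilde\nu}$, where the
  fluence constant $c$ is set per scenario by `fluence_for_depletion()`
  (presets: 92.5 % peak tag depletion, the middle of the 90–95 % operating
  window). Retagging after release is not modeled (irradiating after
  release suppresses it on the instrument).
* **Arrival times** are Gaussian (apex, FWHM), because only apex and FWHM
  are characterized experimentally; the trisaccharide presets use apexes
  4.75/5.35 ms and FWHM 0.4 ms on a 10 ms mobility cycle. The exit-lens
  gate is modeled as a sharp half-open window — the physical edge response
  is not known, so no transfer function is imposed.
* **TOF transients**: each (species, tag count) contributes a Gaussian peak
  at $t = t_0 + k\sqrt{m/z}$ (defaults $t_0 = 2$ µs, $k = 1.75$
  µs/√Th, placing m/z 500–600 inside one 18 kHz pusher period), peak FWHM
  0.01 µs, area proportional to ion number (0.01 counts·µs per ion), on a
  constant baseline (5 counts/sample) with per-sample Poisson counting
  noise; per-cycle ion numbers are Poisson around the source rate (2000
  ions/cycle) to emulate electrospray fluctuation. Setting
  `stochastic = FALSE` replaces every draw by its expectation — the
  noiseless datasets used for round-trip validation.
* **Not modeled**: RF confinement, gas dynamics, cryostat thermodynamics,
  temperature/pressure dependence of tagging (temperature is metadata
  only), retagging, and real band positions — the synthetic cross-section
  curves are arbitrary sums of Gaussians chosen to be distinct between
  isomers. Passing tests therefore demonstrate correctness of the
  *processing*, not agreement with any physical spectrum.

### Preset composition

The isomer-mixture preset fixes relative abundances 0.4 (melezitose,
early) / 0.6 (cellotriose, late) — the early component somewhat less
abundant — and mean tag counts 1 and 8/3, so the mixture's
abundance-weighted mean tag count is exactly 2 while the early component's
is 1, reproducing the sliced-vs-unsliced tagging contrast. The
trisaccharides are isobaric: both sit at the exact [M+Na]⁺ m/z 527.158
(C18H32O16 + Na⁺). The nominal printed value 526.4 is stored separately as
a label and never reconciled with the exact mass.

## Numerical choices

* **Baseline**: rolling 10th-percentile (window 501 samples), evaluated
  every `window %/% 8` samples and linearly interpolated — `stride = 1`
  gives the exact rolling quantile. A low quantile tracks the offset
  without following peaks; the correction is idempotent up to noise. The
  residual positive offset this leaves under pure Poisson noise cancels in
  $F$ (numerator) and is negligible against peak integrals.
* **Time→m/z conversion** multiplies intensities by the Jacobian
  $\mathrm{d}t/\mathrm{d}(m/z) = k^2/(2(t-t_0))$, conserving areas between
  domains. Without this (available as `jacobian = FALSE`), window
  integrals acquire a √(m/z) tilt of ≈2.5 % per 28 Da near m/z 527 —
  enough to bias a mean-tag-count of 2 by +2.5 %, which is why
  area conservation is the default.
* **Window integration** is trapezoidal with linearly interpolated window
  edges, making integrals exactly additive over adjacent windows; tag-series
  windows (default half-width 0.35 Th at z = 1) are required to be
  disjoint. Tag peaks are ~0.27 Th FWHM, so ±0.35 Th captures 99.8 % of
  each peak, identically for every ladder member.
* **Peak detection** keeps local maxima whose prominence exceeds 5 % of the
  global maximum, refines apexes by 3-point parabolic interpolation, and
  measures FWHM by linear interpolation of the half-height crossings,
  descending at most to the enclosing valleys. For partially resolved
  peaks a flank that reaches its valley above half height is flagged
  shoulder-limited and the clean side is mirrored — exactly the situation
  of the 4.75/5.35 ms doublet, whose inner flanks meet at a valley just
  above half height.
* **Mobilograms** are parameterized by bin width (default 0.11 ms) rather
  than bin count. The instrument fixes the number of bins per mobility
  cycle and varies the time per bin with the m/z range (≈0.11 ms at the
  short cycle, ≈0.22 ms at longer ones); parameterizing by width keeps
  binning independent of that instrument detail while reproducing the
  published widths.
* **Negative intensities** after baseline subtraction are retained in
  spectra (keeping window integrals unbiased) but clipped to zero inside
  `mean_tag_count()` (keeping the estimator in range).
* **Energy profiles** interpolate linearly in wavenumber; extrapolation is
  an error. The synthetic default profile rises from 1.5 mJ near 1000
  cm⁻¹ to 3.5 mJ at 2000 cm⁻¹, the energy range of benchtop OPO/OPA
  difference-frequency systems in this region.

## Problem sizes used in validation

Round-trip validation uses noiseless expectation-mode scans over the full
411-point default grid (one pair per point). Stochastic checks use 1e5
ions or events, where 2 % tolerances sit several standard errors away from
their targets. The zero-fluence null suite uses a 821-point scan at 75
pairs per point with traces restricted to the monitored window: with ~0.4 %
per-point 3-SE exceedance, the "≥ 99 % of points consistent with zero"
assertion then has comfortable binomial margin, whereas on a short grid a
single ordinary outlier would decide it. Monte-Carlo calibration recovery
runs 1000 replicates of 50 calibrant pairs at 0.01 µs timing noise.

## Known limitations

* The untagged-reference retrieval saturates structurally once
  $\mu p > \ln 2$; points at or past the cap are flagged, not repaired.
  Quantitative work should either use the weak-depletion regime or the
  tagged reference.
* The simulator's TOF peaks are pure Gaussians without isotope structure,
  detector ringing or charge-state interference; tag-series extraction is
  window integration, not deconvolution.
* Arrival-time distributions are single Gaussians per species;
  conformer fine structure within one mobility peak is not represented.
* Collision-cross-section calibration of arrival times is out of scope
  (it requires external calibrants).
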