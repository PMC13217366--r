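test_that("presets encode the documented study conditions", {
  mix <- make_preset("trisaccharide_mixture")
  expect_length(mix$species, 2L)
  means <- sort(vapply(mix$species, function(s) s$arrival_mean, 0))
  expect_equal(means, c(4.75, 5.35))
  expect_equal(vapply(mix$species, function(s) s$arrival_fwhm, 0), c(0.4, 0.4))
  # abundance-weighted mean tag count of the mixture is exactly 2
  w <- vapply(mix$species, function(s) s$rel_abundance, 0)
  mu <- vapply(mix$species, function(s) s$mean_tags, 0)
  expect_equal(sum(w * mu) / sum(w), 2)

  le <- make_preset("leu_enk")
  expect_length(le$species, 1L)
  expect_equal(le$species[[1]]$mean_tags, 1)
  expect_equal(base_mz(le$species[[1]]), 556.27663, tolerance = 1e-7)

  sl <- make_preset("melezitose_sliced")
  expect_length(sl$species, 1L)
  early <- mix$species[[which.min(vapply(mix$species,
                                         function(s) s$arrival_mean, 0))]]
  expect_equal(sl$species[[1]]$mean_tags, early$mean_tags)
  expect_equal(sl$species[[1]]$arrival_mean, early$arrival_mean)
  expect_equal(sl$species[[1]]$sigma_bands, early$sigma_bands)
  # isobaric trisaccharides: exact m/z differs from the nominal label
  expect_equal(base_mz(sl$species[[1]]), 527.15825, tolerance = 1e-7)
  expect_equal(sl$species[[1]]$label_mz, 526.4)

  expect_error(make_preset("nope"), "leu_enk")
})

test_that("tag-count sampling is Poisson with the requested mean", {
  expect_identical(sample_tag_counts(0, 50, seed = 1), rep(0L, 50))
  x <- sample_tag_counts(1, 1e6, seed = 11)
  expect_lt(abs(mean(x) - 1), 0.01)            # law of large numbers
  expect_lt(abs(mean(x >= 1) - (1 - exp(-1))), 0.005)  # Poisson tail
  expect_identical(sample_tag_counts(2, 100, seed = 5),
                   sample_tag_counts(2, 100, seed = 5))
  expect_error(sample_tag_counts(-1, 10), ">= 0")
  expect_error(sample_tag_counts(1, -1), ">= 0")
})

test_that("detag probability follows the single-photon fluence model", {
  expect_equal(detag_probability(0, 1500, 2, 1), 0)
  expect_equal(detag_probability(1, 1500, 0, 1), 0)
  # exponent ln 20 gives 95% detachment (the upper operating setting)
  expect_equal(detag_probability(log(20), 1, 1, 1), 0.95)
  expect_error(detag_probability(-1, 1500, 2, 1), ">= 0")
  # nondecreasing in every argument
  set.seed(401)
  for (rep in 1:20) {
    base <- runif(4, 0.1, 2)
    for (i in 1:4) {
      hi <- base; hi[i] <- hi[i] * 1.5
      expect_gte(detag_probability(hi[1], hi[2], hi[3], hi[4]),
                 detag_probability(base[1], base[2], base[3], base[4]))
    }
  }
})

test_that("laser application thins tags and never adds any", {
  counts <- c(0L, 1L, 2L, 5L)
  expect_identical(apply_laser(counts, 0), counts)
  expect_identical(apply_laser(counts, 1), rep(0L, 4L))
  expect_error(apply_laser(counts, 1.2), "probability")
  x <- apply_laser(rep(2L, 1e5), 0.5, seed = 9)
  expect_lt(abs(mean(x) - 1), 0.02)            # binomial thinning expectation
  for (s in 1:5) {
    n0 <- sample_tag_counts(2, 500, seed = s)
    expect_true(all(apply_laser(n0, 0.3, seed = s + 100) <= n0))
  }
  expect_identical(apply_laser(counts, 0.5, seed = 2),
                   apply_laser(counts, 0.5, seed = 2))
})

test_that("arrival-time sampling reproduces apex and width", {
  sc <- make_preset("trisaccharide_mixture")
  sp <- sc$species[[1]]
  expect_length(sample_arrival_times(sp, 0, seed = 1), 0L)
  t <- sample_arrival_times(sp, 1e5, seed = 21)
  expect_lt(abs(mean(t) - 4.75), 0.01)
  fwhm_hat <- sd(t) * 2 * sqrt(2 * log(2))
  expect_lt(abs(fwhm_hat - 0.4) / 0.4, 0.03)
  # mixture gives a bimodal histogram with modes near both apexes
  ev <- sample_scenario_events(sc, 2e5, seed = 22)
  mob <- bin_events(ev$time, 10, 0.11)
  pk <- detect_peaks(mob)
  expect_equal(nrow(pk), 2L)
  expect_lt(abs(pk$apex[1] - 4.75), 0.11)
  expect_lt(abs(pk$apex[2] - 5.35), 0.11)
})

test_that("synthesized TOF traces place tag peaks 28 Da apart", {
  cal <- default_calibration()
  pop <- data.frame(mz = 556.277 + 28.006 * (0:2), n_ions = c(4e4, 4e4, 2e4))
  tr <- synth_tof_trace(pop, cal, t_start = 41, t_end = 46.5, noise = TRUE,
                        seed = 3)
  spec <- trace_to_spectrum(baseline_correct(tr), cal)
  ts <- extract_tag_series(spec, 556.277, 1L, max_tags = 2)
  expect_equal(round(diff(ts$centroids)), c(28, 28))
  # recovered intensity fractions match the generating populations
  expect_equal(ts$intensities / sum(ts$intensities), c(0.4, 0.4, 0.2),
               tolerance = 0.02)
})

test_that("empty populations give pure baseline and the model is linear", {
  cal <- default_calibration()
  none <- data.frame(mz = numeric(), n_ions = numeric())
  tr <- synth_tof_trace(none, cal, 41, 45, baseline = 5, noise = TRUE,
                        seed = 8)
  expect_lt(abs(mean(tr$counts) - 5), 0.1)
  pop <- data.frame(mz = 556.277, n_ions = 5e4)
  area <- function(p, seed) {
    t1 <- synth_tof_trace(p, cal, 41, 45, noise = TRUE, seed = seed)
    s1 <- trace_to_spectrum(baseline_correct(t1), cal)
    integrate_window(s1, 556.277 - 0.35, 556.277 + 0.35)
  }
  a1 <- area(pop, 1)
  pop2 <- pop; pop2$n_ions <- 2 * pop2$n_ions
  expect_equal(area(pop2, 2) / a1, 2, tolerance = 0.02)
})

test_that("a simulated scan has the right shape, metadata and determinism", {
  expect_length(scan_grid(laser_scan_config(990, 1810, 2)), 411L)
  sc <- small_leu_enk(1600, 1620, 10, cycles = 2L)
  ds <- simulate_scan(sc, seed = 5)
  expect_s3_class(ds, "raw_dataset")
  expect_length(ds$traces, 3L * 2L * 2L)
  states <- vapply(ds$traces, function(tr) tr$meta$laser_state, "")
  expect_equal(sum(states == "on"), sum(states == "off"))
  wns <- unique(vapply(ds$traces, function(tr) tr$meta$wavenumber, 0))
  expect_equal(sort(wns), c(1600, 1610, 1620))
  ds2 <- simulate_scan(sc, seed = 5)
  expect_identical(ds, ds2)                     # bit-identical given the seed
  expect_false(identical(ds, simulate_scan(sc, seed = 6)))
})

test_that("with zero fluence, laser-on and laser-off cycles are statistically alike", {
  sc <- small_leu_enk(1650, 1690, 20, cycles = 12L)
  sc$scan$fluence_scale <- 0
  ds <- simulate_scan(sc, seed = 17)
  pc <- pair_cycles(ds, untagged_window(sc))
  all_pairs <- do.call(rbind, pc$pairs)
  tt <- t.test(all_pairs[, "I_on"], all_pairs[, "I_off"], paired = TRUE)
  expect_gt(tt$p.value, 0.01)
})

test_that("scenario slicing keeps only the gated share of each species", {
  mix <- make_preset("trisaccharide_mixture")
  win <- slice_window(4.75, 0.5)
  gated <- slice_scenario(mix, win)
  # melezitose retains ~86% of its arrival distribution, cellotriose ~2%
  sdv <- 0.4 / (2 * sqrt(2 * log(2)))
  frac_mel <- pnorm(5.0, 4.75, sdv) - pnorm(4.5, 4.75, sdv)
  frac_cel <- pnorm(5.0, 5.35, sdv) - pnorm(4.5, 5.35, sdv)
  expect_equal(gated$species[[1]]$rel_abundance, 0.4 * frac_mel)
  expect_equal(gated$species[[2]]$rel_abundance, 0.6 * frac_cel)
  expect_error(slice_scenario(mix, slice_window(50, 0.1)), "no ions")
})
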