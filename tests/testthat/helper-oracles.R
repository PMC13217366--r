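# Shared fixtures and independent oracles, built in code at test time.

# scale-free relative RMS between a retrieved curve and ground truth,
# after least-squares matching of the single global scale factor
rel_rms <- function(retrieved, truth) {
  cc <- sum(retrieved * truth) / sum(truth^2)
  sqrt(mean((retrieved - cc * truth)^2)) / sqrt(mean((cc * truth)^2))
}

# leu_enk preset restricted to a short scan for fast retrieval tests
small_leu_enk <- function(wn_start = 1500, wn_stop = 1800, wn_step = 10,
                          cycles = 2L) {
  sc <- make_preset("leu_enk", cycles_per_wavenumber = cycles)
  sc$scan$wn_start <- wn_start
  sc$scan$wn_stop <- wn_stop
  sc$scan$wn_step <- wn_step
  sc
}

# monitored m/z window around the untagged peak of the first species
untagged_window <- function(sc, halfwidth = 0.35) {
  b <- base_mz(sc$species[[1]])
  c(b - halfwidth, b + halfwidth)
}

# m/z window covering the summed tagged series (n >= 1)
tagged_window <- function(sc, max_tags = 8) {
  b <- base_mz(sc$species[[1]])
  sp <- 28.006 / abs(sc$species[[1]]$charge)
  c(b + sp / 2, b + (max_tags + 0.5) * sp)
}

# narrow, coarsely sampled TOF axis around the untagged peak: cheap traces
# for statistics-heavy null tests that only monitor one m/z window
narrow_tof <- function(sc, halfwidth_mz = 6, dt = 0.004) {
  b <- base_mz(sc$species[[1]])
  sc$tof$t_start <- mz_to_tof(sc$cal, b - halfwidth_mz)
  sc$tof$t_end <- mz_to_tof(sc$cal, b + halfwidth_mz)
  sc$tof$dt <- dt
  sc
}
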