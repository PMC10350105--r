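# Scaled configurations used across the suite. The default configuration is
# the full study condition; these shrink the problem (fewer shots, coarser
# resolution, fewer channels) where a test only needs the mechanics.

# small dataset at the default physics
small_config <- function(n_shots = 20, shift = 0, ...) {
  cfg <- default_config()
  cfg$dataset$n_shots <- n_shots
  cfg$crystal$edge_shift_true <- shift
  mods <- list(...)
  for (nm in names(mods)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], mods[[nm]])
  cfg
}

# fully well-specified conditions: smooth mosaic in data and model, exact
# metadata, no cell jitter (forward model matches the generator bit for bit)
matched_config <- function(n_shots = 10, shift = 0) {
  cfg <- small_config(n_shots, shift)
  cfg$dataset$mosaic_mode <- "smooth"
  cfg$dataset$cell_jitter <- 0
  cfg$metadata$scale_sdlog_est <- 0
  cfg$metadata$orientation_mrad_est <- 0
  cfg
}

# coarse, fast profile for interval/coverage simulations
coarse_config <- function(n_shots = 16, shift = 0) {
  cfg <- small_config(n_shots, shift)
  cfg$dataset$d_min <- 2.6
  cfg$dataset$shoebox_half <- 3
  cfg$dataset$max_refl_per_shot <- 10
  cfg$spectrum$n_channels <- 15
  cfg$fit$scan_lo <- -3; cfg$fit$scan_hi <- 3
  cfg
}

# rotation taking unit vector a to unit vector b (for constructed
# orientations in geometry tests)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) return(if (cth > 0) diag(3) else diag(c(-1, -1, 1)))
  axis_angle_rotation(v, atan2(s, cth))
}

# default detector/spectrum/crystal trio used by shoebox-level tests
toy_scene <- function(cfg = default_config(), shift = 0) {
  curve <- shift_edge(mn_reference_curve(), shift)
  list(det = detector(),
       spec = spectrum_from_config_test(cfg),
       crystal = crystal_model(
         unit_cell(cfg$crystal$cell$a, cfg$crystal$cell$b, cfg$crystal$cell$c),
         sfxspread:::atoms_from_config(cfg, curve),
         mosaic_model(cfg$mosaic$n_domains, cfg$mosaic$angular_spread,
                      cfg$mosaic$domain_cells)))
}

spectrum_from_config_test <- function(cfg) {
  s <- cfg$spectrum
  gaussian_spectrum(s$center, s$fwhm, s$n_channels, s$span)
}
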