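#' Default experiment configuration
#'
#' Nested list describing the full simulate/fit/pvae pipeline: the toy
#' crystal (orthorhombic cell, six atoms with one Mn-like anomalous site),
#' the incident spectrum (30 channels, Gaussian, FWHM 30 eV centered at
#' 6550 eV), a flat single-panel detector, the mosaic model, dataset sizes
#' and noise, metadata-perturbation levels emulating imperfect upstream
#' estimates, an optional injected model error, and the solver
#' hyperparameters. [load_config()] merges a YAML file over these defaults.
#'
#' @return configuration list (class `spread_config`).
#' @export
default_config <- function() {
  structure(list(
    crystal = list(
      cell = list(a = 15, b = 18, c = 22, alpha = 90, beta = 90, gamma = 90),
      atoms = list(
        list(element = "Mn", frac = c(0.15, 0.25, 0.35), b_factor = 8,
             occupancy = 1, anomalous = TRUE),
        list(element = "S", frac = c(0.40, 0.10, 0.70), b_factor = 10,
             occupancy = 1, anomalous = FALSE),
        list(element = "O", frac = c(0.55, 0.65, 0.15), b_factor = 12,
             occupancy = 1, anomalous = FALSE),
        list(element = "O", frac = c(0.80, 0.45, 0.90), b_factor = 12,
             occupancy = 1, anomalous = FALSE),
        list(element = "N", frac = c(0.30, 0.85, 0.55), b_factor = 14,
             occupancy = 1, anomalous = FALSE),
        list(element = "C", frac = c(0.65, 0.20, 0.05), b_factor = 15,
             occupancy = 1, anomalous = FALSE)),
      edge_energy = 6550,
      edge_shift_true = 0,
      curve = "mn_synthetic"),
    spectrum = list(center = 6550, fwhm = 30, n_channels = 30, span = 90),
    detector = list(distance = 60, pixel_size = 0.2, n_fast = 512,
                    n_slow = 512, beam_center = c(256, 256)),
    mosaic = list(n_domains = 24, angular_spread = 1.0,
                  domain_cells = c(8, 8, 8)),
    dataset = list(n_shots = 200, scale_sdlog = 0.3, cell_jitter = 0.001,
                   flux = 1.0, background_rate = 2, d_min = 2.3,
                   shell_mult = 3, shoebox_half = 4, max_refl_per_shot = 16,
                   noise = TRUE, mosaic_mode = "explicit"),
    metadata = list(scale_sdlog_est = 0.05, orientation_mrad_est = 0.5),
    model_error = list(kind = "none", magnitude = 0),
    fit = list(scan_lo = -4, scan_hi = 4, scan_step = 1, tol = 1e-9,
               grad_tol = 1e-6, max_iter = 2000, newton_sweeps = 40),
    pvae = list(hidden = 16, epochs = 300, lr = 0.02, penalty_weight = 1,
                correction = TRUE, val_frac = 0.1, prior_shift_sd = 3,
                prior_scale_sd = 0.1, prior_bg_sd = 0.5),
    seed = 1
  ), class = "spread_config")
}

# schema-driven recursive validation: every key in cfg must exist in the
# defaults (unknown keys rejected with their path), missing keys filled in
merge_validate <- function(default, given, path = "") {
  if (!is.list(default)) return(given)
  if (!is.list(given))
    stop("config field '", path, "' must be a mapping")
  unnamed <- is.null(names(default))   # e.g. the atoms list
  if (unnamed) return(given)
  extra <- setdiff(names(given), names(default))
  if (length(extra))
    stop("unknown config key", if (length(extra) > 1) "s", ": ",
         paste0(path, extra, collapse = ", "))
  for (nm in names(default)) {
    sub <- paste0(path, nm, ".")
    if (nm %in% names(given))
      default[[nm]] <- merge_validate(default[[nm]], given[[nm]], sub)
  }
  default
}

#' Validate a configuration and fill defaults
#'
#' @param config partial or full configuration list.
#' @return validated full configuration (class `spread_config`).
#' @export
validate_config <- function(config) {
  cfg <- merge_validate(unclass(default_config()), unclass(config))
  ds <- cfg$dataset
  if (ds$n_shots < 0) stop("config field 'dataset.n_shots' must be >= 0")
  if (!ds$mosaic_mode %in% c("explicit", "smooth"))
    stop("config field 'dataset.mosaic_mode' must be 'explicit' or 'smooth'")
  if (ds$flux <= 0) stop("config field 'dataset.flux' must be > 0")
  if (ds$background_rate < 0)
    stop("config field 'dataset.background_rate' must be >= 0")
  for (a in cfg$crystal$atoms)
    if (!all(c("element", "frac") %in% names(a)))
      stop("config field 'crystal.atoms' entries need 'element' and 'frac'")
  structure(cfg, class = "spread_config")
}

#' Load / save experiment configurations as YAML
#'
#' `load_config()` reads a YAML file, merges it over [default_config()]
#' (unknown keys are rejected, naming the offending path) and validates it.
#' `save_config()` writes the full validated configuration back to YAML, so
#' a save/load round trip is the identity.
#'
#' @param path YAML file path.
#' @return [load_config()]: a validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  given <- yaml::read_yaml(path)
  if (is.null(given)) given <- list()
  validate_config(given)
}

#' @rdname load_config
#' @param config configuration to write.
#' @export
save_config <- function(config, path) {
  config <- validate_config(config)
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' 32-bit FNV-1a hash of the canonical JSON serialization; used to stamp
#' every derived artifact so numbers are traceable to the configuration
#' that produced them.
#'
#' @param config configuration list.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(validate_config(config)), digits = NA,
                        auto_unbox = TRUE)
  bytes <- utf8ToInt(as.character(s)) %% 256
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime, split to stay in double range
    lo <- (h %% 65536) * p
    hi <- ((h %/% 65536) * p) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# --- constructors from config ------------------------------------------------

cell_from_config <- function(cfg) {
  cc <- cfg$crystal$cell
  unit_cell(cc$a, cc$b, cc$c, cc$alpha, cc$beta, cc$gamma)
}

reference_curve_from_config <- function(cfg) {
  cv <- cfg$crystal$curve
  if (identical(cv, "mn_synthetic"))
    mn_reference_curve(edge_energy = cfg$crystal$edge_energy)
  else read_anomalous_curve(cv)
}

atoms_from_config <- function(cfg, curve) {
  lapply(cfg$crystal$atoms, function(a) {
    atom_site(a$element, a$frac,
              b_factor = if (is.null(a$b_factor)) 0 else a$b_factor,
              occupancy = if (is.null(a$occupancy)) 1 else a$occupancy,
              anomalous_curve = if (isTRUE(a$anomalous)) curve else NULL)
  })
}

detector_from_config <- function(cfg) {
  d <- cfg$detector
  detector(d$distance, d$pixel_size, d$n_fast, d$n_slow, d$beam_center)
}

spectrum_from_config <- function(cfg) {
  s <- cfg$spectrum
  gaussian_spectrum(s$center, s$fwhm, s$n_channels, s$span)
}

mosaic_from_config <- function(cfg) {
  m <- cfg$mosaic
  mosaic_model(m$n_domains, m$angular_spread, m$domain_cells)
}
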