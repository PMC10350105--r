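#' Predict diffracting reflections for a still shot
#'
#' Enumerates Miller indices inside the resolution limit and keeps those
#' whose reciprocal-lattice point lies within an acceptance shell of the
#' Ewald sphere for at least one spectrum channel, and whose diffracted ray
#' hits the panel. The shell half-width is `shell_mult` times the combined
#' broadening sigma_eff(q) = sqrt(sigma_size^2 + (|q| * spread)^2); the
#' spectrum channels span the bandwidth term.
#'
#' @param orientation 3 x 3 crystal orientation matrix U.
#' @param crystal a [crystal_model()] (supplies cell and mosaic).
#' @param det a [detector()].
#' @param spec a [spectrum()].
#' @param d_min resolution limit in Angstrom.
#' @param shell_mult acceptance-shell width in units of sigma_eff.
#' @param cell optional [unit_cell()] overriding `crystal$cell` (per-shot
#'   jittered cells).
#' @return data.frame with columns `h, k, l, fast, slow, q_mag, d, eps_min,
#'   e_best` (predicted impact position in pixels, scattering-vector
#'   magnitude, resolution, minimal Ewald offset over channels in
#'   1/Angstrom, and the channel energy attaining it), ordered by `eps_min`.
#' @export
predict_reflections <- function(orientation, crystal, det, spec,
                                d_min = 2.3, shell_mult = 3, cell = NULL) {
  if (is.null(cell)) cell <- crystal$cell
  stopifnot(inherits(cell, "unit_cell"))
  hmax <- floor(cell$a / d_min); kmax <- floor(cell$b / d_min)
  lmax <- floor(cell$c / d_min)
  hkl <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  hkl <- hkl[rowSums(hkl != 0) > 0, , drop = FALSE]
  q_mag <- scattering_vector_magnitude(cell, hkl)
  keep <- q_mag <= 1 / d_min
  hkl <- hkl[keep, , drop = FALSE]; q_mag <- q_mag[keep]
  qlab <- hkl %*% t(cell$recip) %*% t(orientation)   # rows: U B h
  invlam <- 1 / ev_to_angstrom(spec$energies)
  # Ewald offset |q + k_in| - |k_in| per channel
  q2xy <- qlab[, 1]^2 + qlab[, 2]^2
  eps <- sqrt(outer(q2xy, rep(1, length(invlam))) +
                outer(qlab[, 3], invlam, "+")^2) -
    rep(invlam, each = nrow(qlab))
  aeps <- abs(eps)
  jbest <- max.col(-aeps, ties.method = "first")
  eps_min <- aeps[cbind(seq_len(nrow(qlab)), jbest)]
  sig <- profile_sigma(crystal$mosaic$domain_cells, cell)
  sig_eff <- sqrt(sig^2 + (q_mag * crystal$mosaic$angular_spread * 1e-3)^2)
  il <- invlam[jbest]
  vz <- qlab[, 3] + il
  ok <- eps_min < shell_mult * sig_eff & vz > 0
  fast <- qlab[, 1] / vz * det$distance / det$pixel_size + det$beam_center[1]
  slow <- qlab[, 2] / vz * det$distance / det$pixel_size + det$beam_center[2]
  ok <- ok & fast >= 0 & fast < det$n_fast & slow >= 0 & slow < det$n_slow
  out <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    fast = fast, slow = slow, q_mag = q_mag, d = 1 / q_mag,
                    eps_min = eps_min,
                    e_best = spec$energies[jbest])[ok, , drop = FALSE]
  out[order(out$eps_min), , drop = FALSE]
}

# bounding box of a fixed odd-size shoebox centered on the predicted impact
# pixel, clipped at panel edges; half-open [f0, f1) x [s0, s1)
shoebox_bbox <- function(fast, slow, det, half = 4) {
  cf <- floor(fast); cs <- floor(slow)
  c(max(cf - half, 0), min(cf + half + 1, det$n_fast),
    max(cs - half, 0), min(cs + half + 1, det$n_slow))
}

# multiplicative panel gain field / additive background ramp used by
# inject_model_error; u, v are panel coordinates normalized to [-1, 1]
panel_uv <- function(det, fast, slow) {
  list(u = 2 * (fast + 0.5) / det$n_fast - 1,
       v = 2 * (slow + 0.5) / det$n_slow - 1)
}
gain_field_value <- function(det, fast, slow, magnitude) {
  uv <- panel_uv(det, fast, slow)
  1 + magnitude * uv$u * uv$v
}
background_ramp_value <- function(det, fast, slow, magnitude) {
  uv <- panel_uv(det, fast, slow)
  1 + magnitude * uv$u
}

#' Simulate one diffraction-spot shoebox
#'
#' Renders the expected photon counts of a fixed-size pixel block around a
#' predicted reflection by summing |F_h(E)|^2 times the lattice interference
#' profile over spectrum channels and mosaic domains, scaled by the per-shot
#' factor, pixel solid angle and flux, plus a flat background; optionally
#' draws independent Poisson counts per pixel.
#'
#' @param hkl reflection index (length-3).
#' @param orientation 3 x 3 crystal orientation U.
#' @param crystal a [crystal_model()]; its atoms' anomalous curves are the
#'   data-generating truth.
#' @param det a [detector()].
#' @param spec a [spectrum()].
#' @param scale per-shot scale factor g (> 0).
#' @param flux overall intensity constant (photons per unit solid angle per
#'   unit |F|^2 at unit profile).
#' @param background_rate flat background in counts/pixel.
#' @param mosaic_mode `"explicit"` (incoherent sum over drawn domain
#'   rotations) or `"smooth"` (analytic mosaic-broadened profile).
#' @param domain_rotations optional list of 3 x 3 mosaic rotations (drawn
#'   from the mosaic model when NULL and mode is explicit).
#' @param noise draw Poisson counts (TRUE) or return expected counts.
#' @param half shoebox half-size in pixels (box is `2 * half + 1` square).
#' @param cell optional per-shot [unit_cell()] override.
#' @param gain_error,ramp_error magnitudes of an injected multiplicative
#'   panel gain field / background ramp (0 = nominal model).
#' @param prediction optional one-row prediction (from
#'   [predict_reflections()]) to skip re-prediction.
#' @return a `shoebox` list: `bbox` (fast_min, fast_max, slow_min, slow_max;
#'   half-open), `counts` (fast x slow matrix), `hkl`, `expected` (noise-off
#'   expectation), `metadata`.
#' @export
simulate_shoebox <- function(hkl, orientation, crystal, det, spec,
                             scale = 1, flux = 1, background_rate = 2,
                             mosaic_mode = c("explicit", "smooth"),
                             domain_rotations = NULL, noise = TRUE,
                             half = 4, cell = NULL,
                             gain_error = 0, ramp_error = 0,
                             prediction = NULL) {
  mosaic_mode <- match.arg(mosaic_mode)
  if (is.null(cell)) cell <- crystal$cell
  mos <- crystal$mosaic
  if (is.null(prediction)) {
    pr <- predict_reflections(orientation, crystal, det, spec, cell = cell)
    pr <- pr[pr$h == hkl[1] & pr$k == hkl[2] & pr$l == hkl[3], , drop = FALSE]
    if (!nrow(pr))
      stop(sprintf("reflection (%d %d %d) is not predicted for this shot",
                   hkl[1], hkl[2], hkl[3]))
    prediction <- pr[1, ]
  }
  bbox <- shoebox_bbox(prediction$fast, prediction$slow, det, half)
  fasts <- bbox[1]:(bbox[2] - 1L); slows <- bbox[3]:(bbox[4] - 1L)
  px <- expand.grid(fast = fasts, slow = slows)   # fast varies fastest
  geom <- pixel_geometry(det, px$fast, px$slow)
  invlam <- 1 / ev_to_angstrom(spec$energies)
  f2 <- abs(structure_factor(cell, crystal$atoms, rbind(as.numeric(hkl)),
                             spec$energies))^2
  f2 <- as.numeric(f2)
  qcen <- as.numeric(orientation %*% cell$recip %*% as.numeric(hkl))
  sig <- profile_sigma(mos$domain_cells, cell)
  ntot2 <- prod(mos$domain_cells)^2
  if (mosaic_mode == "explicit") {
    if (is.null(domain_rotations))
      domain_rotations <- replicate(
        mos$n_domains, random_small_rotation(mos$angular_spread * 1e-3),
        simplify = FALSE)
    qdom <- t(vapply(domain_rotations, function(r) as.numeric(r %*% qcen),
                     numeric(3)))
    sig2 <- sig^2
    signal <- .shoebox_expected_cpp(geom$dirs, geom$omega, invlam,
                                    spec$weights, f2, qdom, sig2,
                                    ntot2 / length(domain_rotations))
  } else {
    qn <- sqrt(sum(qcen^2))
    sig_t2 <- sig^2 + (qn * mos$angular_spread * 1e-3)^2
    p <- .design_profile_cpp(geom$dirs, geom$omega, invlam, qcen, sig^2,
                             sig_t2, ntot2 * sig^2 / sig_t2)
    signal <- as.numeric(p %*% (spec$weights * f2))
  }
  bg <- background_rate *
    background_ramp_value(det, px$fast, px$slow, ramp_error)
  expected <- gain_field_value(det, px$fast, px$slow, gain_error) *
    (flux * scale * signal + bg)
  counts <- if (noise) stats::rpois(length(expected), expected) else expected
  nf <- length(fasts)
  structure(list(
    bbox = bbox,
    counts = matrix(counts, nrow = nf,
                    dimnames = list(fast = fasts, slow = slows)),
    hkl = as.integer(hkl),
    expected = matrix(expected, nrow = nf),
    metadata = list(fast = prediction$fast, slow = prediction$slow,
                    d = prediction$d, e_best = prediction$e_best)),
    class = "shoebox")
}

#' Inject a forward-model error into a simulation configuration
#'
#' Returns a configuration whose data-generating process deviates from the
#' nominal forward model that inference assumes:
#' `pixel_gain_field` multiplies every expected count by a smooth panel
#' field `1 + magnitude * u * v` (u, v panel coordinates in \[-1, 1\]), so
#' the ratio to nominal stays within `1 +/- magnitude`;
#' `background_gradient` replaces the flat background with the ramp
#' `rate * (1 + magnitude * u)`; `mosaic_misspecification` generates data
#' with the mosaic spread scaled by `1 + magnitude` while inference keeps
#' the nominal value. Magnitude 0 reproduces the nominal simulator exactly.
#'
#' @param config an experiment configuration (see [default_config()]).
#' @param kind one of `"pixel_gain_field"`, `"mosaic_misspecification"`,
#'   `"background_gradient"`.
#' @param magnitude perturbation size (dimensionless).
#' @return the modified configuration.
#' @export
inject_model_error <- function(config, kind, magnitude) {
  kinds <- c("pixel_gain_field", "mosaic_misspecification",
             "background_gradient")
  if (!kind %in% kinds)
    stop("unknown model-error kind '", kind, "'; options: ",
         paste(kinds, collapse = ", "))
  config$model_error <- list(kind = kind, magnitude = magnitude)
  config
}

#' Simulate a serial-crystallography dataset
#'
#' Draws `n_shots` independent still shots: a Haar-random orientation, a
#' log-normal per-shot scale, jittered cell lengths and (in explicit mode)
#' mosaic-domain rotations per shot; predicts reflections, renders each
#' shoebox and applies Poisson noise. Shot metadata carries DIALS-style
#' imperfect estimates (perturbed orientation and scale, exact cell); the
#' generating truth is returned in a sidecar that inference never reads.
#' All randomness comes from R's RNG seeded once, with draws ordered
#' deterministically (shots, then domains, then pixels).
#'
#' @param config experiment configuration, see [default_config()].
#' @param seed integer seed.
#' @return list with `data` (class `spread_dataset`: shots with estimated
#'   metadata and shoeboxes, plus nominal crystal/detector/spectrum the
#'   inference model uses) and `truth` (class `spread_truth` sidecar: true
#'   edge shift, per-shot orientations/scales/cells, injected model error).
#' @export
simulate_dataset <- function(config = default_config(), seed = 1) {
  config <- validate_config(config)
  set.seed(seed)
  det <- detector_from_config(config)
  spec <- spectrum_from_config(config)
  ref_curve <- reference_curve_from_config(config)
  true_curve <- shift_edge(ref_curve, config$crystal$edge_shift_true)
  mos_nominal <- mosaic_from_config(config)
  mos_true <- mos_nominal
  err <- config$model_error
  if (err$kind == "mosaic_misspecification")
    mos_true$angular_spread <- mos_true$angular_spread * (1 + err$magnitude)
  atoms_true <- atoms_from_config(config, true_curve)
  cell0 <- cell_from_config(config)
  crystal_true <- crystal_model(cell0, atoms_true, mos_true)
  ds <- config$dataset
  gain_m <- if (err$kind == "pixel_gain_field") err$magnitude else 0
  ramp_m <- if (err$kind == "background_gradient") err$magnitude else 0
  shots <- vector("list", ds$n_shots)
  truth_shots <- vector("list", ds$n_shots)
  for (s in seq_len(ds$n_shots)) {
    u <- random_orientation()
    jit <- exp(stats::rnorm(3, 0, ds$cell_jitter))
    cell_s <- unit_cell(cell0$a * jit[1], cell0$b * jit[2], cell0$c * jit[3],
                        cell0$alpha, cell0$beta, cell0$gamma)
    g <- stats::rlnorm(1, 0, ds$scale_sdlog)
    u_est <- random_small_rotation(config$metadata$orientation_mrad_est * 1e-3) %*% u
    g_est <- g * stats::rlnorm(1, 0, config$metadata$scale_sdlog_est)
    dom <- NULL
    if (ds$mosaic_mode == "explicit")
      dom <- replicate(mos_true$n_domains,
                       random_small_rotation(mos_true$angular_spread * 1e-3),
                       simplify = FALSE)
    pred <- predict_reflections(u, crystal_true, det, spec,
                                d_min = ds$d_min, shell_mult = ds$shell_mult,
                                cell = cell_s)
    if (nrow(pred) > ds$max_refl_per_shot)
      pred <- pred[seq_len(ds$max_refl_per_shot), , drop = FALSE]
    boxes <- vector("list", nrow(pred))
    for (i in seq_len(nrow(pred))) {
      sb <- simulate_shoebox(
        hkl = c(pred$h[i], pred$k[i], pred$l[i]), orientation = u,
        crystal = crystal_true, det = det, spec = spec, scale = g,
        flux = ds$flux, background_rate = ds$background_rate,
        mosaic_mode = ds$mosaic_mode, domain_rotations = dom,
        noise = ds$noise, half = ds$shoebox_half, cell = cell_s,
        gain_error = gain_m, ramp_error = ramp_m,
        prediction = pred[i, ])
      sb$metadata$shot_id <- s
      sb$expected <- NULL   # expectation is truth; inference never sees it
      boxes[[i]] <- sb
    }
    shots[[s]] <- list(shot_id = s, orientation = u_est, scale_estimate = g_est,
                       cell = cell_s, shoeboxes = boxes)
    truth_shots[[s]] <- list(orientation = u, scale = g, cell = cell_s)
  }
  data <- structure(list(
    shots = shots, detector = det, spectrum = spec,
    cell = cell0, atoms = atoms_from_config(config, ref_curve),
    mosaic = mos_nominal, reference_curve = ref_curve,
    config = config, seed = seed), class = "spread_dataset")
  truth <- structure(list(
    edge_shift = config$crystal$edge_shift_true, shots = truth_shots,
    model_error = err, true_curve = true_curve, seed = seed),
    class = "spread_truth")
  list(data = data, truth = truth)
}

#' @export
print.spread_dataset <- function(x, ...) {
  nsb <- sum(vapply(x$shots, function(s) length(s$shoeboxes), 0L))
  cat(sprintf("<spread_dataset> %d shots, %d shoeboxes, seed %d\n",
              length(x$shots), nsb, x$seed))
  invisible(x)
}
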