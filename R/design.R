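# Precomputed inference design: everything about the forward model that
# does not depend on the fitted parameters. For every shoebox, the
# geometric kernel P[pixel, channel] (solid angle x flux x smooth mosaic
# profile, built from the *estimated* orientation and cell in the shot
# metadata), the structure-factor decomposition F(E) = A + c(E) M, pixel
# counts, and index maps pixel -> shoebox -> shot. The model intensity is
#   lambda[pix] = g[shot] * rowSums(Pw * F2[sb, ]) + bg[sb]
# with Pw = P * spectrum weight, so evaluating a new edge shift only costs
# a curve interpolation and one elementwise product.

#' Build the inference design for a dataset
#'
#' @param dataset a `spread_dataset`.
#' @return object of class `spread_design`.
#' @export
build_design <- function(dataset) {
  stopifnot(inherits(dataset, "spread_dataset"))
  det <- dataset$detector; spec <- dataset$spectrum
  mos <- dataset$mosaic; atoms <- dataset$atoms
  curve <- dataset$reference_curve
  flux <- dataset$config$dataset$flux
  invlam <- 1 / ev_to_angstrom(spec$energies)
  ntot2 <- prod(mos$domain_cells)^2
  p_blocks <- list(); counts <- list(); geoms <- list()
  pix_u <- list(); pix_v <- list()
  A <- complex(); M <- complex()
  sb_shot <- integer(); sb_npix <- integer()
  sig_r2 <- numeric(); sig_eff2 <- numeric(); amp <- numeric()
  bg0 <- numeric(); hkl_rows <- list(); meta_rows <- list()
  orientations <- vector("list", length(dataset$shots))
  recips <- vector("list", length(dataset$shots))
  for (shot in dataset$shots) {
    u <- shot$orientation; cell_s <- shot$cell
    orientations[[shot$shot_id]] <- u
    recips[[shot$shot_id]] <- cell_s$recip
    sig <- profile_sigma(mos$domain_cells, cell_s)
    for (sb in shot$shoeboxes) {
      bbox <- sb$bbox
      fasts <- bbox[1]:(bbox[2] - 1L); slows <- bbox[3]:(bbox[4] - 1L)
      px <- expand.grid(fast = fasts, slow = slows)
      geom <- pixel_geometry(det, px$fast, px$slow)
      uv <- panel_uv(det, px$fast, px$slow)
      qcen <- as.numeric(u %*% cell_s$recip %*% as.numeric(sb$hkl))
      qn <- sqrt(sum(qcen^2))
      s2 <- sig^2 + (qn * mos$angular_spread * 1e-3)^2
      a <- ntot2 * sig^2 / s2
      p <- .design_profile_cpp(geom$dirs, geom$omega, invlam, qcen, sig^2,
                               s2, a)
      dec <- sf_decompose(cell_s, atoms, rbind(as.numeric(sb$hkl)))
      i <- length(p_blocks) + 1L
      p_blocks[[i]] <- p * rep(flux * spec$weights, each = nrow(p))
      counts[[i]] <- as.numeric(sb$counts)
      geoms[[i]] <- geom
      pix_u[[i]] <- uv$u; pix_v[[i]] <- uv$v
      A[i] <- dec$A; M[i] <- dec$M
      sb_shot[i] <- shot$shot_id
      sb_npix[i] <- nrow(p)
      sig_r2[i] <- sig^2; sig_eff2[i] <- s2; amp[i] <- a
      bg0[i] <- max(perimeter_mean(sb$counts), 0.05)
      hkl_rows[[i]] <- sb$hkl
      meta_rows[[i]] <- sb$metadata
    }
  }
  if (!length(p_blocks)) stop("dataset has no shoeboxes")
  n_sb <- length(p_blocks)
  structure(list(
    Pw = do.call(rbind, p_blocks),
    counts = unlist(counts),
    dec = list(A = A, M = M),
    energies = spec$energies,
    weights = spec$weights,
    invlam = invlam,
    flux = flux,
    curve = curve,
    sb_of_pix = rep.int(seq_len(n_sb), sb_npix),
    sb_npix = sb_npix,
    pix_rows = split(seq_len(sum(sb_npix)), rep.int(seq_len(n_sb), sb_npix)),
    shot_of_sb = sb_shot,
    shot_of_pix = rep.int(sb_shot, sb_npix),
    n_sb = n_sb,
    n_shot = length(dataset$shots),
    g0 = vapply(dataset$shots, function(s) s$scale_estimate, 0),
    bg0 = bg0,
    hkl = do.call(rbind, hkl_rows),
    meta = meta_rows,
    geom = geoms,
    beam_center = det$beam_center,
    pix_u = unlist(pix_u, use.names = FALSE),
    pix_v = unlist(pix_v, use.names = FALSE),
    sig_r2 = sig_r2,
    sig_eff2 = sig_eff2,
    amp = amp,
    ntot2 = ntot2,
    orientations = orientations,
    recips = recips,
    lgamma_k = sum(lgamma(unlist(counts) + 1))),
    class = "spread_design")
}

# Rebuild the Pw rows of the shoeboxes belonging to one shot for a new
# orientation U and profile-width multiplier (used by the per-shot
# refinement of orientation offsets and effective mosaic width).
design_shot_pw <- function(design, shot_id, u, width_mult = 1) {
  idx <- which(design$shot_of_sb == shot_id)
  recip <- design$recips[[shot_id]]
  lapply(idx, function(i) {
    qcen <- as.numeric(u %*% recip %*% as.numeric(design$hkl[i, ]))
    # the multiplier scales the mosaic (tangential) variance component only
    st2 <- design$sig_r2[i] +
      (design$sig_eff2[i] - design$sig_r2[i]) * width_mult
    amp <- design$ntot2 * design$sig_r2[i] / st2
    p <- .design_profile_cpp(design$geom[[i]]$dirs, design$geom[[i]]$omega,
                             design$invlam, qcen, design$sig_r2[i], st2, amp)
    p * rep(design$flux * design$weights, each = nrow(p))
  })
}

# model intensity per pixel (before scale/background) at a given edge shift,
# optionally with the derivative wrt the shift
design_model <- function(design, edge_shift, deriv = FALSE,
                         curve = design$curve) {
  ci <- curve_interp(curve, design$energies - edge_shift)
  f2 <- sf_intensity(design$dec, ci$f_prime, ci$f_double_prime)
  sb0 <- design$sb_of_pix - 1L
  m <- .pixel_model_cpp(design$Pw, f2, sb0)
  if (!deriv) return(list(m = m))
  df2 <- sf_intensity_dshift(design$dec, ci$f_prime, ci$f_double_prime,
                             ci$df_prime, ci$df_double_prime)
  list(m = m, dm = .pixel_model_cpp(design$Pw, df2, sb0))
}
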