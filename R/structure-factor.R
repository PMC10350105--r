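#' Wavelength-dependent complex structure factor
#'
#' Evaluates F_h(E) = sum_m occ_m \[f0_m(|Q|) + df'_m(E) + i df''_m(E)\]
#' exp(2 pi i r_m . h) exp(-B_m |Q|^2 / 4) over the atom list. Anomalous
#' terms are zero for atoms without an attached curve; for atoms with one,
#' the requested energies must lie within that curve's grid.
#'
#' @param cell a [unit_cell()].
#' @param atoms non-empty list of [atom_site()].
#' @param hkl a [miller_index()] / length-3 vector, or an n x 3 matrix.
#' @param energy photon energies in eV (vector allowed).
#' @return complex matrix (n_hkl x n_energy); a plain complex vector when a
#'   single reflection is requested.
#' @export
structure_factor <- function(cell, atoms, hkl, energy) {
  stopifnot(inherits(cell, "unit_cell"), length(atoms) >= 1)
  m <- hkl_matrix(hkl)
  q <- scattering_vector_magnitude(cell, m)
  ne <- length(energy)
  out <- matrix(0 + 0i, nrow = nrow(m), ncol = ne)
  for (at in atoms) {
    phase <- exp(2i * pi * as.numeric(m %*% at$frac_coords))
    damp <- exp(-at$b_factor * q^2 / 4)
    geom <- at$occupancy * phase * damp          # per hkl, energy-independent
    f0 <- eval_f0(at$element, q)
    if (is.null(at$anomalous_curve)) {
      out <- out + outer(geom * f0, rep(1 + 0i, ne))
    } else {
      ci <- tryCatch(curve_interp(at$anomalous_curve, energy),
                     error = function(e) stop(
                       "atom '", at$element, "': ", conditionMessage(e),
                       call. = FALSE))
      fa <- complex(real = ci$f_prime, imaginary = ci$f_double_prime)
      out <- out + outer(geom, fa) + outer(geom * f0, rep(1 + 0i, ne))
    }
  }
  if (nrow(m) == 1L) out[1, ] else out
}

# Split F(hkl, E) = A + c(E) * M for the solvers: A collects every
# energy-independent contribution (all f0 terms plus non-fitted anomalous
# atoms would go here too); M is the geometric factor of the atoms whose
# anomalous curve is being fitted, so that c(E) = df'(E) + i df''(E).
# Returns complex vectors A and M over the rows of the hkl matrix.
sf_decompose <- function(cell, atoms, hkl_mat) {
  q <- scattering_vector_magnitude(cell, hkl_mat)
  A <- complex(real = numeric(nrow(hkl_mat)), imaginary = 0)
  M <- A
  for (at in atoms) {
    phase <- exp(2i * pi * as.numeric(hkl_mat %*% at$frac_coords))
    geom <- at$occupancy * phase * exp(-at$b_factor * q^2 / 4)
    A <- A + geom * eval_f0(at$element, q)
    if (!is.null(at$anomalous_curve)) M <- M + geom
  }
  list(A = A, M = M)
}

# |F|^2 over energies from the decomposition and interpolated curve values.
# A, M complex (n_hkl); fp, fpp numeric (n_e). Returns n_hkl x n_e matrix.
sf_intensity <- function(dec, fp, fpp) {
  cAM <- Conj(dec$A) * dec$M
  c2 <- fp^2 + fpp^2
  outer(abs(dec$A)^2, rep(1, length(fp))) +
    2 * (outer(Re(cAM), fp) - outer(Im(cAM), fpp)) +
    outer(abs(dec$M)^2, c2)
}

# d|F|^2/dE at shifted energies: derivative of c(E - dE) wrt the edge shift
# is -(dfp, dfpp). Returns n_hkl x n_e matrix of d|F|^2/d(edge shift).
sf_intensity_dshift <- function(dec, fp, fpp, dfp, dfpp) {
  cAM <- Conj(dec$A) * dec$M
  -(2 * (outer(Re(cAM), dfp) - outer(Im(cAM), dfpp)) +
      outer(abs(dec$M)^2, 2 * (fp * dfp + fpp * dfpp)))
}
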