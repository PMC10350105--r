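#' Crystallographic unit cell
#'
#' @param a,b,c cell lengths in Angstrom (> 0).
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180); the
#'   implied metric tensor must be positive definite.
#' @return object of class `unit_cell` with the direct basis matrix (columns
#'   a, b, c in an orthonormal lab frame), the reciprocal basis matrix
#'   (convention a* . a = 1, no 2 pi factor) and the cell volume precomputed.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("invalid cell: lengths must be positive")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("invalid cell: angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  vol2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vol2 <= 1e-12)
    stop("invalid cell: metric tensor is not positive definite")
  v <- a * b * c * sqrt(vol2)
  # direct basis, columns = a, b, c (standard PDB-style orthogonalization)
  amat <- matrix(c(
    a, 0, 0,
    b * cg, b * sg, 0,
    c * cb, c * (ca - cb * cg) / sg, v / (a * b * sg)
  ), nrow = 3)
  bmat <- t(solve(amat))  # reciprocal basis, a* . a = 1
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 direct = amat, recip = bmat, volume = v),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.4g b=%.4g c=%.4g A, %g/%g/%g deg, V=%.5g A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Miller index triple
#'
#' @param h,k,l integers.
#' @return integer vector of length 3 with class `miller_index`.
#' @export
miller_index <- function(h, k, l) {
  hkl <- c(h, k, l)
  if (any(hkl != round(hkl))) stop("Miller indices must be integers")
  structure(as.integer(round(hkl)), class = "miller_index")
}

#' Scattering-vector magnitude |Q| for a reflection
#'
#' Length of the reciprocal-lattice vector for `hkl` under the d-spacing
#' convention |Q| = 1/d_hkl (reciprocal basis without the 2 pi factor). This
#' is the |Q| that enters the B-factor damping exp(-B |Q|^2 / 4); note the
#' exponent differs by (2 pi)^2 from the physics convention |Q| = 2 pi / d.
#'
#' @param cell a [unit_cell()].
#' @param hkl a [miller_index()] or length-3 integer vector, or an n x 3
#'   matrix of indices.
#' @return |Q| in 1/Angstrom (vector of length n).
#' @export
scattering_vector_magnitude <- function(cell, hkl) {
  stopifnot(inherits(cell, "unit_cell"))
  m <- hkl_matrix(hkl)
  q <- m %*% t(cell$recip)   # rows = reciprocal vectors
  sqrt(rowSums(q^2))
}

#' Resolution d-spacing of a reflection
#' @inheritParams scattering_vector_magnitude
#' @return d in Angstrom (Inf for (0,0,0)).
#' @export
d_spacing <- function(cell, hkl) 1 / scattering_vector_magnitude(cell, hkl)

# coerce hkl input to an n x 3 numeric matrix
hkl_matrix <- function(hkl) {
  if (is.matrix(hkl)) {
    stopifnot(ncol(hkl) == 3)
    hkl
  } else {
    stopifnot(length(hkl) == 3)
    matrix(as.numeric(hkl), nrow = 1)
  }
}
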