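#' Mosaic-domain model
#'
#' A still crystal is modeled as `n_domains` small coherent blocks, each of
#' `domain_cells` unit cells, misoriented from the mean orientation by small
#' random rotations of standard deviation `angular_spread`. Spot intensity
#' is summed incoherently over domains.
#'
#' @param n_domains number of mosaic blocks (>= 1).
#' @param angular_spread standard deviation of domain misorientation in
#'   milliradians (>= 0).
#' @param domain_cells integer length-3 (N_a, N_b, N_c) unit cells per
#'   domain along each axis (each >= 1).
#' @return object of class `mosaic_model`.
#' @export
mosaic_model <- function(n_domains = 24, angular_spread = 1.0,
                         domain_cells = c(8, 8, 8)) {
  if (!is.finite(n_domains) || n_domains < 1) stop("n_domains must be >= 1")
  if (!is.finite(angular_spread) || angular_spread < 0)
    stop("angular_spread must be >= 0")
  domain_cells <- as.integer(domain_cells)
  stopifnot(length(domain_cells) == 3)
  if (any(domain_cells < 1)) stop("domain_cells must each be >= 1")
  structure(list(n_domains = as.integer(n_domains),
                 angular_spread = angular_spread,
                 domain_cells = domain_cells),
            class = "mosaic_model")
}

# Gaussian width (1/Angstrom) of the domain-size broadening implied by the
# finite coherent block: sigma = 1 / (2 pi N_bar a_bar), with N_bar and
# a_bar geometric means of the cell counts and cell lengths.
profile_sigma <- function(domain_cells, cell) {
  nbar <- prod(domain_cells)^(1 / 3)
  abar <- (cell$a * cell$b * cell$c)^(1 / 3)
  1 / (2 * pi * nbar * abar)
}

#' Isotropic Gaussian lattice interference profile
#'
#' Dimensionless shape factor of a reciprocal-space peak as a function of
#' the distance `offset` from the exact Bragg condition, for a coherent
#' block of `domain_cells` unit cells. An isotropic Gaussian approximation
#' to the product of Laue interference functions: peak value
#' (N_a N_b N_c)^2 at zero offset, characteristic width
#' 1 / (2 pi N_bar a_bar) in 1/Angstrom.
#'
#' @param offset reciprocal-space distance(s) from the Bragg condition in
#'   1/Angstrom, >= 0.
#' @param domain_cells integer length-3 unit-cell counts of the block.
#' @param cell a [unit_cell()].
#' @return shape factor(s), same length as `offset`.
#' @export
lattice_profile <- function(offset, domain_cells, cell) {
  if (any(offset < 0)) stop("offset must be >= 0")
  sig <- profile_sigma(domain_cells, cell)
  prod(domain_cells)^2 * exp(-offset^2 / (2 * sig^2))
}
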