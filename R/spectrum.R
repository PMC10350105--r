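#' Discretized incident spectrum
#'
#' A polychromatic XFEL pulse represented as a set of energy channels with
#' nonnegative weights summing to 1. Still-shot spots are superpositions of
#' contributions from every channel.
#'
#' @param energies channel energies in eV (uniformly spaced, >= 3 points).
#' @param weights nonnegative channel weights; normalized to sum to 1.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(energies, weights) {
  energies <- as.numeric(energies)
  if (length(energies) >= 3) {
    grid <- as.numeric(energy_grid(energies))
  } else {
    # mono- or two-channel beams are allowed for oracle-style checks
    if (any(!is.finite(energies)) || any(energies <= 0) ||
        is.unsorted(energies, strictly = TRUE))
      stop("energies must be positive and strictly increasing")
    grid <- energies
  }
  weights <- as.numeric(weights)
  if (length(weights) != length(grid))
    stop("weights must match the number of channels")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and >= 0")
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  structure(list(energies = as.numeric(grid), weights = weights / s),
            class = "spectrum")
}

#' Gaussian incident spectrum
#'
#' Default beam: channels spanning `center +/- span/2` with Gaussian weights
#' of the given full width at half maximum.
#'
#' @param center central energy in eV (default 6550, at the Mn-like edge).
#' @param fwhm spectral full width at half maximum in eV.
#' @param n_channels number of energy channels.
#' @param span total energy span covered by the channels, in eV.
#' @return a [spectrum()].
#' @export
gaussian_spectrum <- function(center = 6550, fwhm = 30, n_channels = 30,
                              span = 90) {
  e <- seq(center - span / 2, center + span / 2, length.out = n_channels)
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  spectrum(e, stats::dnorm(e, center, sd))
}

#' @export
print.spectrum <- function(x, ...) {
  mu <- sum(x$energies * x$weights)
  cat(sprintf("<spectrum> %d channels, %.1f..%.1f eV, mean %.1f eV\n",
              length(x$energies), min(x$energies), max(x$energies), mu))
  invisible(x)
}
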