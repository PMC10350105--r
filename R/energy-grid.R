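#' Uniform photon-energy grid
#'
#' Canonical spectral axis for anomalous-scattering curves and spectra.
#' Energies are in electron volts, strictly increasing with constant spacing.
#' Energy, not wavelength, is the canonical variable throughout the package;
#' wavelength (lambda\[Angstrom\] = 12398.42 / E\[eV\]) is derived only at the
#' diffraction-geometry layer, where the Ewald construction needs it.
#'
#' @param energies numeric vector of photon energies in eV; length >= 3,
#'   all positive, uniformly spaced to a relative tolerance of 1e-9.
#' @return an object of class `energy_grid` (numeric vector with a `step`
#'   attribute).
#' @examples
#' g <- energy_grid(seq(6400, 6700, by = 1))
#' attr(g, "step")
#' @export
energy_grid <- function(energies) {
  energies <- as.numeric(energies)
  if (length(energies) < 3L)
    stop("energy grid needs at least 3 points, got ", length(energies))
  if (any(!is.finite(energies)) || any(energies <= 0))
    stop("energies must be finite and > 0")
  d <- diff(energies)
  if (any(d <= 0))
    stop("energies must be strictly increasing")
  step <- mean(d)
  if (max(abs(d - step)) > 1e-9 * step)
    stop("energy grid must be uniform (relative tolerance 1e-9)")
  structure(energies, step = step, class = "energy_grid")
}

is_energy_grid <- function(x) inherits(x, "energy_grid")

#' @export
print.energy_grid <- function(x, ...) {
  cat(sprintf("<energy_grid> %d points, %.6g..%.6g eV, step %.6g eV\n",
              length(x), x[1], x[length(x)], attr(x, "step")))
  invisible(x)
}

#' Convert photon energy to X-ray wavelength
#'
#' @param energy_ev photon energy in eV.
#' @return wavelength in Angstrom.
#' @export
ev_to_angstrom <- function(energy_ev) 12398.42 / energy_ev
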