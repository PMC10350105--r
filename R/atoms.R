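#' Atom site within the unit cell
#'
#' @param element element symbol (see [ff_elements()]).
#' @param frac_coords fractional coordinates, length 3; reduced mod 1 on
#'   construction (phases are unchanged by lattice translations).
#' @param b_factor isotropic B factor in Angstrom^2, >= 0.
#' @param occupancy site occupancy in \[0, 1\].
#' @param anomalous_curve optional [anomalous_curve()]; atoms without one
#'   contribute no anomalous terms.
#' @return object of class `atom_site`.
#' @export
atom_site <- function(element, frac_coords, b_factor = 0, occupancy = 1,
                      anomalous_curve = NULL) {
  if (!element %in% ff_elements())
    stop("unknown element '", element, "'; available: ",
         paste(ff_elements(), collapse = ", "))
  frac_coords <- as.numeric(frac_coords)
  stopifnot(length(frac_coords) == 3)
  frac_coords <- frac_coords %% 1
  if (!is.finite(b_factor) || b_factor < 0) stop("b_factor must be >= 0")
  if (!is.finite(occupancy) || occupancy < 0 || occupancy > 1)
    stop("occupancy must be in [0, 1]")
  if (!is.null(anomalous_curve) && !inherits(anomalous_curve, "anomalous_curve"))
    stop("anomalous_curve must be an anomalous_curve or NULL")
  structure(list(element = element, frac_coords = frac_coords,
                 b_factor = b_factor, occupancy = occupancy,
                 anomalous_curve = anomalous_curve),
            class = "atom_site")
}

#' Toy crystal model: unit cell, atom sites and mosaic parameters
#'
#' @param cell a [unit_cell()].
#' @param atoms list of [atom_site()] objects (non-empty).
#' @param mosaic a [mosaic_model()].
#' @return object of class `crystal_model`.
#' @export
crystal_model <- function(cell, atoms, mosaic = mosaic_model()) {
  stopifnot(inherits(cell, "unit_cell"), length(atoms) >= 1)
  for (a in atoms) stopifnot(inherits(a, "atom_site"))
  stopifnot(inherits(mosaic, "mosaic_model"))
  structure(list(cell = cell, atoms = atoms, mosaic = mosaic),
            class = "crystal_model")
}

#' @export
print.crystal_model <- function(x, ...) {
  n_anom <- sum(vapply(x$atoms, function(a) !is.null(a$anomalous_curve), TRUE))
  cat(sprintf("<crystal_model> %d atoms (%d anomalous), cell %.3g/%.3g/%.3g A\n",
              length(x$atoms), n_anom, x$cell$a, x$cell$b, x$cell$c))
  invisible(x)
}

#' Read a minimal PDB subset (CRYST1 + ATOM/HETATM)
#'
#' Parses the CRYST1 record for the unit cell and ATOM/HETATM records for
#' element, orthogonal coordinates (converted to fractional internally),
#' occupancy and B factor. Only the fixed PDB columns are read; everything
#' else is ignored. Elements outside the bundled form-factor set are
#' rejected.
#'
#' @param path PDB file path.
#' @param anomalous_elements elements whose sites get `anomalous_curve`
#'   attached (default "Mn").
#' @param anomalous_curve curve for those sites; default [mn_reference_curve()].
#' @return list with `cell` ([unit_cell()]) and `atoms` (list of [atom_site()]).
#' @export
read_pdb_minimal <- function(path, anomalous_elements = "Mn",
                             anomalous_curve = mn_reference_curve()) {
  lines <- readLines(path)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) stop("no CRYST1 record in ", path)
  cell <- unit_cell(as.numeric(substr(cl[1], 7, 15)),
                    as.numeric(substr(cl[1], 16, 24)),
                    as.numeric(substr(cl[1], 25, 33)),
                    as.numeric(substr(cl[1], 34, 40)),
                    as.numeric(substr(cl[1], 41, 47)),
                    as.numeric(substr(cl[1], 48, 54)))
  al <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  if (!length(al)) stop("no ATOM/HETATM records in ", path)
  frac_of <- solve(cell$direct)
  atoms <- lapply(al, function(ln) {
    el <- trimws(substr(ln, 77, 78))
    if (el == "") el <- trimws(substr(ln, 13, 14))
    el <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
    xyz <- as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                        substr(ln, 47, 54)))
    occ <- as.numeric(substr(ln, 55, 60)); if (!is.finite(occ)) occ <- 1
    bfac <- as.numeric(substr(ln, 61, 66)); if (!is.finite(bfac)) bfac <- 0
    atom_site(el, as.numeric(frac_of %*% xyz), b_factor = bfac,
              occupancy = occ,
              anomalous_curve = if (el %in% anomalous_elements)
                anomalous_curve else NULL)
  })
  list(cell = cell, atoms = atoms)
}
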