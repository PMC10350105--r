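#' Flat single-panel detector
#'
#' The beam travels along +z and hits the panel at `beam_center` (pixel
#' units, measured from the panel corner; fast axis first). Pixel (i, j)
#' covers the half-open square \[i, i+1) x \[j, j+1); its center is at
#' (i + 0.5, j + 0.5).
#'
#' @param distance sample-to-detector distance in mm (> 0).
#' @param pixel_size pixel edge in mm (> 0).
#' @param n_fast,n_slow panel size in pixels.
#' @param beam_center length-2 (fast, slow) beam position in pixels; must be
#'   inside the panel.
#' @return object of class `detector`.
#' @export
detector <- function(distance = 60, pixel_size = 0.2,
                     n_fast = 512, n_slow = 512,
                     beam_center = c(n_fast / 2, n_slow / 2)) {
  if (!is.finite(distance) || distance <= 0) stop("distance must be > 0")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  beam_center <- as.numeric(beam_center)
  stopifnot(length(beam_center) == 2)
  if (beam_center[1] < 0 || beam_center[1] > n_fast ||
      beam_center[2] < 0 || beam_center[2] > n_slow)
    stop("beam_center must lie inside the panel")
  structure(list(distance = distance, pixel_size = pixel_size,
                 n_fast = as.integer(n_fast), n_slow = as.integer(n_slow),
                 beam_center = beam_center),
            class = "detector")
}

#' Uniformly random crystal orientations
#'
#' Draws rotation matrices uniformly with respect to Haar measure on SO(3)
#' via normalized Gaussian quaternions. Uses R's global RNG stream, so draws
#' are reproducible under `set.seed()`.
#'
#' @param n number of orientations.
#' @return a 3 x 3 rotation matrix, or a list of them when `n > 1`.
#' @export
random_orientation <- function(n = 1) {
  draws <- lapply(seq_len(n), function(i) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    quat_to_rot(q)
  })
  if (n == 1) draws[[1]] else draws
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3)  # column-major: columns are images of e1, e2, e3
}

#' Rotation about an axis by a small (or any) angle
#'
#' Rodrigues rotation matrix; used for mosaic-domain misorientations and
#' metadata orientation perturbations.
#'
#' @param axis length-3 axis (normalized internally).
#' @param angle rotation angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
axis_angle_rotation <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), nrow = 3)
  diag(3) + sin(angle) * kx + (1 - cos(angle)) * (kx %*% kx)
}

# random small rotation: uniform axis, N(0, sigma_rad) angle
random_small_rotation <- function(sigma_rad) {
  ax <- stats::rnorm(3)
  axis_angle_rotation(ax, stats::rnorm(1, 0, sigma_rad))
}

# Per-pixel unit directions and solid-angle factors for a pixel block.
# fast, slow: integer pixel indices (vectors of equal length, pixel corners).
# Returns list(dirs = n x 3 unit vectors to pixel centers,
#              omega = projected solid angle of each pixel in sr).
pixel_geometry <- function(det, fast, slow) {
  x <- (fast + 0.5 - det$beam_center[1]) * det$pixel_size
  y <- (slow + 0.5 - det$beam_center[2]) * det$pixel_size
  z <- det$distance
  r <- sqrt(x^2 + y^2 + z^2)
  dirs <- cbind(x, y, z) / r
  omega <- det$pixel_size^2 * z / r^3
  list(dirs = dirs, omega = omega)
}
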