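#' Free-per-channel anomalous-curve refinement
#'
#' Alternative parameterization of the classical inversion: instead of a
#' single edge shift applied to the reference curve, delta f'' is freed on a
#' coarse knot grid spanning the incident spectrum (log-parameterized, so
#' delta f'' stays positive), with a second-difference smoothness penalty,
#' and delta f' is re-derived from the full-grid delta f'' with
#' [kramers_kronig()] at every evaluation, so the refined pair remains
#' KK-consistent by construction. Nuisance parameters (scales, backgrounds)
#' are re-solved at each objective evaluation; the knot values are
#' optimized with L-BFGS-B.
#'
#' @param fit a converged [fit_edge_shift()] result (supplies the design,
#'   nuisance warm start and the starting curve at the fitted shift).
#' @param knot_step knot spacing in eV.
#' @param smooth_weight weight of the second-difference penalty on the log
#'   knot values.
#' @param maxit L-BFGS-B iteration cap.
#' @return list with `curve` (the refined [anomalous_curve()]), `nll`,
#'   `penalty`, `knots`, `convergence` (optim code).
#' @export
fit_curve_free <- function(fit, knot_step = 5, smooth_weight = 10,
                           maxit = 60) {
  design <- fit$design
  ref <- design$curve
  grid <- as.numeric(ref$grid)
  # start from the reference translated by the fitted shift
  start_curve <- shift_edge(ref, fit$params$edge_shift)
  span <- range(design$energies)
  knots <- seq(span[1] - knot_step, span[2] + knot_step, by = knot_step)
  in_span <- grid >= knots[1] & grid <= knots[length(knots)]
  theta0 <- log(pmax(stats::approx(grid, start_curve$f_double_prime,
                                   xout = knots, rule = 2)$y, 1e-3))
  g <- exp(fit$params$log_g); b <- exp(fit$params$log_bg)
  curve_of <- function(theta) {
    fpp <- start_curve$f_double_prime
    fpp[in_span] <- stats::approx(knots, exp(theta),
                                  xout = grid[in_span])$y
    anomalous_curve(ref$grid, kramers_kronig(fpp, ref$grid), fpp,
                    start_curve$edge_energy)
  }
  objective <- function(theta) {
    cv <- curve_of(theta)
    m <- design_model(design, 0, curve = cv)$m
    nb <- nuisance_refit(m, design, g, b, sweeps = 15)
    nb$nll + design$lgamma_k + smooth_weight * sum(diff(theta, differences = 2)^2)
  }
  obj0 <- objective(theta0)
  opt <- stats::optim(theta0, objective, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e10))
  cv <- curve_of(opt$par)
  pen <- smooth_weight * sum(diff(opt$par, differences = 2)^2)
  list(curve = cv, nll = opt$value - pen, penalty = pen,
       objective = opt$value, objective0 = obj0,
       knots = data.frame(energy = knots, f_double_prime = exp(opt$par)),
       convergence = opt$convergence)
}
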