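# Conjugate linear-Gaussian toy used to validate the variational
# machinery: n observations x_i ~ N(z, sx^2) of a scalar source
# z ~ N(0, sz^2). The evidence is available in closed form, the expected
# ELBO of a Gaussian posterior q = N(m, exp(s)^2) is analytic, and the
# optimal q is the exact posterior, so the optimized ELBO must meet the
# log evidence (from below).

#' Analytic log evidence of the Gaussian toy model
#'
#' @param x observations.
#' @param sx observation noise standard deviation.
#' @param sz prior standard deviation of the source.
#' @return log p(x).
#' @export
gaussian_toy_evidence <- function(x, sx = 1, sz = 1) {
  n <- length(x)
  tau <- n / sx^2 + 1 / sz^2           # posterior precision
  mpost <- sum(x) / sx^2 / tau
  sum(stats::dnorm(x, 0, sx, log = TRUE)) -
    0.5 * log(sz^2 * tau) + 0.5 * mpost^2 * tau
}

#' Analytic ELBO of the Gaussian toy under a Gaussian posterior
#'
#' Expected complete-data log likelihood minus the KL divergence from the
#' prior, both in closed form (no Monte Carlo), for q = N(m, exp(s)^2) in
#' the standardized space z = sz * zeta, prior zeta ~ N(0, 1). Uses the
#' same KL expression as the P-VAE.
#'
#' @param m,s posterior location and log spread in the standardized space.
#' @inheritParams gaussian_toy_evidence
#' @return scalar ELBO, a lower bound on [gaussian_toy_evidence()].
#' @export
gaussian_toy_elbo <- function(m, s, x, sx = 1, sz = 1) {
  n <- length(x)
  v <- exp(2 * s)
  zm <- sz * m                          # posterior mean of z
  zv <- sz^2 * v
  eloglik <- sum(stats::dnorm(x, zm, sx, log = TRUE)) - n * zv / (2 * sx^2)
  eloglik - kl_std_gaussian(m, s)
}

#' Optimize the Gaussian-toy ELBO with the package's Adam optimizer
#'
#' Gradient ascent on (m, s) using the analytic gradients; at convergence
#' the ELBO equals the log evidence because the family contains the exact
#' posterior.
#'
#' @inheritParams gaussian_toy_evidence
#' @param iters Adam iterations.
#' @param lr learning rate.
#' @return list with `m`, `s`, `elbo`, `evidence`, `gap`.
#' @export
optimize_gaussian_toy <- function(x, sx = 1, sz = 1, iters = 2000,
                                  lr = 0.05) {
  m <- 0; s <- 0
  st_m <- list(t = 0, m = 0, v = 0); st_s <- list(t = 0, m = 0, v = 0)
  n <- length(x)
  for (i in seq_len(iters)) {
    v <- exp(2 * s)
    # d(-elbo)/dm and /ds
    gm <- -sum(x - sz * m) * sz / sx^2 + m
    gs <- n * sz^2 * v / sx^2 + (v - 1)
    st <- adam_step(m, gm, st_m, lr); m <- st$par; st_m <- st$state
    st <- adam_step(s, gs, st_s, lr); s <- st$par; st_s <- st$state
  }
  elbo <- gaussian_toy_elbo(m, s, x, sx, sz)
  ev <- gaussian_toy_evidence(x, sx, sz)
  list(m = m, s = s, elbo = elbo, evidence = ev, gap = ev - elbo)
}
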