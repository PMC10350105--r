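# Classical maximum-likelihood inversion: objective, gradients, fixed
# points, nuisance invariances and interval machinery.

test_that("NLL equals a hand-summed per-pixel oracle with its gradient", {
  sim <- simulate_dataset(small_config(4, shift = 1), seed = 2)
  des <- build_design(sim$data)
  params <- list(edge_shift = 0.5, log_g = log(des$g0) + 0.1,
                 log_bg = log(des$bg0))
  nll <- negative_log_likelihood(params, des, gradient = TRUE)
  # oracle: assemble lambda from the design pieces and sum dpois terms
  m <- sfxspread:::design_model(des, 0.5)$m
  lam <- exp(params$log_g)[des$shot_of_pix] * m +
    exp(params$log_bg)[des$sb_of_pix]
  expect_equal(as.numeric(nll),
               -sum(stats::dpois(des$counts, lam, log = TRUE)),
               tolerance = 1e-10)
  # analytic gradient against central differences
  gr <- attr(nll, "gradient")
  h <- 1e-6
  num_shift <- (negative_log_likelihood(
    modifyList(params, list(edge_shift = 0.5 + h)), des) -
    negative_log_likelihood(
      modifyList(params, list(edge_shift = 0.5 - h)), des)) / (2 * h)
  expect_equal(gr$edge_shift, as.numeric(num_shift), tolerance = 1e-4)
  p2 <- params; p2$log_g[2] <- p2$log_g[2] + h
  p3 <- params; p3$log_g[2] <- p3$log_g[2] - h
  expect_equal(gr$log_g[2],
               as.numeric(negative_log_likelihood(p2, des) -
                            negative_log_likelihood(p3, des)) / (2 * h),
               tolerance = 1e-4)
  p2 <- params; p2$log_bg[5] <- p2$log_bg[5] + h
  p3 <- params; p3$log_bg[5] <- p3$log_bg[5] - h
  expect_equal(gr$log_bg[5],
               as.numeric(negative_log_likelihood(p2, des) -
                            negative_log_likelihood(p3, des)) / (2 * h),
               tolerance = 1e-4)
  # additivity: the objective is an exact sum over shoebox pixel blocks
  one <- which(des$sb_of_pix == 1)
  lam1 <- lam[one]
  expect_equal(as.numeric(nll),
               -sum(stats::dpois(des$counts[one], lam1, log = TRUE)) -
                 sum(stats::dpois(des$counts[-one], lam[-one], log = TRUE)),
               tolerance = 1e-10)
})

test_that("noise-off matched data is a fixed point of the fit", {
  # a whole-grid-step shift keeps the tabulated generator curve and the
  # interpolated model curve identical, so truth is the exact optimum
  cfg <- matched_config(8, shift = 2)
  cfg$dataset$noise <- FALSE
  sim <- simulate_dataset(cfg, seed = 3)
  des <- build_design(sim$data)
  truth_params <- list(
    edge_shift = 2,
    log_g = log(vapply(sim$truth$shots, function(s) s$scale, 0)),
    log_bg = rep(log(cfg$dataset$background_rate), des$n_sb))
  fit <- fit_edge_shift(des, init = truth_params, config = cfg)
  expect_true(fit$converged)
  expect_identical(fit$iterations, 0L)
  expect_lt(fit$grad_norm, cfg$fit$grad_tol)
  expect_equal(fit$params$edge_shift, 2)
  # and from a cold start the optimizer finds the same optimum
  cold <- fit_edge_shift(des, config = cfg, refine_passes = 0)
  expect_equal(cold$params$edge_shift, 2, tolerance = 0.02)
  expect_true(all(diff(cold$loss_trace) <= 0))
})

test_that("identifiability: truth beats a mis-set edge on noise-off data", {
  cfg <- matched_config(6, shift = 0)
  cfg$dataset$noise <- FALSE
  sim <- simulate_dataset(cfg, seed = 9)
  des <- build_design(sim$data)
  p0 <- list(edge_shift = 0,
             log_g = log(vapply(sim$truth$shots, function(s) s$scale, 0)),
             log_bg = rep(log(cfg$dataset$background_rate), des$n_sb))
  n_true <- negative_log_likelihood(p0, des)
  for (off in c(-2, 2)) {
    p1 <- p0; p1$edge_shift <- off
    expect_lt(n_true, negative_log_likelihood(p1, des))
  }
})

test_that("edge shift survives a global rescaling of the per-shot scales", {
  cfg <- small_config(12, shift = 2)
  cfg$dataset$noise <- FALSE
  a <- simulate_dataset(cfg, seed = 6)
  cfg2 <- cfg; cfg2$dataset$flux <- cfg$dataset$flux * 3  # all g x 3
  b <- simulate_dataset(cfg2, seed = 6)
  fa <- fit_edge_shift(build_design(a$data), config = cfg,
                       refine_passes = 0)
  fb <- fit_edge_shift(build_design(b$data), config = cfg2,
                       refine_passes = 0)
  expect_equal(fa$params$edge_shift, fb$params$edge_shift, tolerance = 0.05)
})

test_that("shift recovery lands near the injected value at reduced scale", {
  ests <- vapply(1:2, function(s) {
    sim <- simulate_dataset(small_config(60, shift = 2), seed = s)
    fit_edge_shift(build_design(sim$data))$params$edge_shift
  }, 0)
  expect_true(all(abs(ests - 2) < 0.5))
})

test_that("profile and bootstrap intervals behave", {
  cfg <- matched_config(8, shift = 1)
  cfg$dataset$noise <- FALSE
  sim <- simulate_dataset(cfg, seed = 5)
  fit <- fit_edge_shift(build_design(sim$data), config = cfg,
                        refine_passes = 0)
  # the profile interval brackets the estimate, and its width shrinks as
  # the interval level does (nested deviance thresholds)
  ci <- edge_shift_interval(fit, "profile", level = 0.9)
  expect_lte(ci[1], fit$params$edge_shift)
  expect_gte(ci[2], fit$params$edge_shift)
  ci50 <- edge_shift_interval(fit, "profile", level = 0.5)
  expect_lt(ci50[2] - ci50[1], ci[2] - ci[1])
  pr <- sfxspread:::profile_nll(fit$params$edge_shift, fit$design,
                                exp(fit$params$log_g),
                                exp(fit$params$log_bg))
  expect_equal(2 * (pr$nll - fit$nll), 0, tolerance = 1e-6)
  bad <- fit; bad$converged <- FALSE
  expect_error(edge_shift_interval(bad), "not converged")
})

test_that("parametric-bootstrap null intervals cover zero", {
  # coverage of the parametric bootstrap is a property of the
  # well-specified model, so the generator runs in matched mode
  cfg <- coarse_config(16, shift = 0)
  cfg$dataset$mosaic_mode <- "smooth"
  cfg$metadata$orientation_mrad_est <- 0
  covered <- 0
  for (s in 1:20) {
    sim <- simulate_dataset(cfg, seed = 100 + s)
    fit <- fit_edge_shift(build_design(sim$data), config = cfg,
                          refine_passes = 0)
    set.seed(1000 + s)
    ci <- edge_shift_interval(fit, "bootstrap", level = 0.9, n_boot = 39)
    if (ci[1] <= 0 && ci[2] >= 0) covered <- covered + 1
  }
  expect_gte(covered, 14)
})

test_that("free-per-channel refinement stays KK-consistent and fits", {
  sim <- simulate_dataset(small_config(10, shift = 1), seed = 8)
  fit <- fit_edge_shift(build_design(sim$data), refine_passes = 0)
  fr <- fit_curve_free(fit, knot_step = 8, maxit = 5)
  expect_true(all(fr$curve$f_double_prime >= 0))
  expect_equal(fr$curve$f_prime,
               kramers_kronig(fr$curve$f_double_prime, fr$curve$grid),
               tolerance = 1e-12)
  # the knot optimization never worsens its own penalized objective
  expect_lte(fr$objective, fr$objective0 + 1e-6)
})
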