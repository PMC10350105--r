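# Physics-informed VAE: encoder contracts, pooling, ELBO machinery against
# the conjugate oracle, gradients, training smoke and posterior sampling.

make_small_fit_pieces <- function(n_shots = 4, shift = 1, seed = 2) {
  sim <- simulate_dataset(small_config(n_shots, shift = shift), seed = seed)
  des <- build_design(sim$data)
  list(sim = sim, des = des)
}

test_that("zero-initialized encoder returns the prior everywhere", {
  p <- make_small_fit_pieces()
  model <- pvae_init(p$des, seed = 1)
  enc <- pvae_encode(model, p$des)
  expect_true(all(enc$sb == 0))
  expect_true(all(enc$shot_m == 0))
  expect_true(all(enc$shot_s == 0))
  # identical inputs give identical posteriors (encoder is deterministic)
  m2 <- model
  m2$W2 <- matrix(rnorm(length(m2$W2), 0, 0.1), nrow = 4)
  m2$features$x[2, ] <- m2$features$x[1, ]
  e2 <- pvae_encode(m2, p$des)
  expect_identical(e2$sb[1, ], e2$sb[2, ])
  # prior-equal posteriors and identity correction give zero KL and penalty
  l <- pvae_elbo(model, p$des, seed = 3)
  expect_identical(l$kl, 0)
  expect_identical(l$correction_penalty, 0)
})

test_that("image-level pooling averages natural parameters", {
  m <- c(0.8, -0.4); s <- c(log(0.5), log(2))
  pooled <- pool_posterior(m, s)
  # closed-form two-component pooling
  v <- exp(2 * s)
  prec <- mean(1 / v)
  mean_exp <- mean(m / v) / prec
  expect_equal(pooled$m, mean_exp, tolerance = 1e-12)
  expect_equal(exp(2 * pooled$s), 1 / prec, tolerance = 1e-12)
  # pooling a posterior with itself is the identity
  same <- pool_posterior(c(0.3, 0.3), c(-0.1, -0.1))
  expect_equal(same$m, 0.3, tolerance = 1e-12)
  expect_equal(same$s, -0.1, tolerance = 1e-12)
})

test_that("analytic gradients of the loss match finite differences", {
  p <- make_small_fit_pieces(3, seed = 7)
  model <- pvae_init(p$des, seed = 3)
  set.seed(11)
  model$W2 <- matrix(rnorm(length(model$W2), 0, 0.05), nrow = 4)
  model$b2 <- rnorm(4, 0, 0.05)
  model$mD <- 0.3; model$sD <- -0.2
  model$theta <- rnorm(5, 0, 0.05)
  set.seed(42)
  eps <- list(B = rnorm(p$des$n_sb), I = rnorm(p$des$n_shot), D = rnorm(1))
  l <- sfxspread:::pvae_loss(model, p$des, eps, gradient = TRUE)
  fdiff <- function(field, idx) {
    h <- 1e-5
    up <- model; up[[field]][idx] <- up[[field]][idx] + h
    dn <- model; dn[[field]][idx] <- dn[[field]][idx] - h
    (sfxspread:::pvae_loss(up, p$des, eps)$loss -
       sfxspread:::pvae_loss(dn, p$des, eps)$loss) / (2 * h)
  }
  checks <- list(c("mD", 1), c("sD", 1), c("theta", 3), c("b2", 2),
                 c("b2", 4), c("W2", 7), c("b1", 5), c("W1", 33))
  for (ck in checks) {
    a <- unname(l$grad[[ck[1]]][as.integer(ck[2])])
    n <- fdiff(ck[1], as.integer(ck[2]))
    expect_equal(a, n, tolerance = 1e-4)
  }
})

test_that("penalty component doubles exactly with its weight", {
  p <- make_small_fit_pieces()
  model <- pvae_init(p$des, seed = 1)
  model$theta <- c(0.1, -0.2, 0.05, 0, 0.3)
  l1 <- pvae_elbo(model, p$des, seed = 5)
  m2 <- model; m2$penalty_weight <- model$penalty_weight * 2
  l2 <- pvae_elbo(m2, p$des, seed = 5)
  expect_equal(l1$correction_penalty, l2$correction_penalty)
  expect_equal(l2$total - l1$total, l1$correction_penalty *
                 model$penalty_weight, tolerance = 1e-9)
})

test_that("optimized ELBO meets the conjugate-model evidence from below", {
  set.seed(31)
  x <- rnorm(12, 0.7, 0.9)
  opt <- optimize_gaussian_toy(x, sx = 0.9, sz = 1.5)
  expect_lte(opt$elbo, opt$evidence + 1e-12)
  expect_lt(opt$gap, 1e-3)
  # any non-optimal posterior stays strictly below the evidence
  expect_lt(gaussian_toy_elbo(opt$m + 1, opt$s, x, 0.9, 1.5), opt$evidence)
  expect_lt(gaussian_toy_elbo(opt$m, opt$s + 1, x, 0.9, 1.5), opt$evidence)
})

test_that("training runs reproducibly and nests the classical objective", {
  sim <- simulate_dataset(small_config(12, shift = 2), seed = 4)
  des <- build_design(sim$data)
  cfg <- small_config(12, shift = 2)
  cfg$pvae$epochs <- 80
  cfg$pvae$correction <- FALSE
  a <- train_pvae(des, cfg, seed = 6)
  b <- train_pvae(des, cfg, seed = 6)
  expect_identical(a$trace, b$trace)
  expect_identical(a$posterior, b$posterior)
  expect_true(all(is.finite(a$trace)))
  # with the correction off and zero reparameterization noise, the
  # reconstruction term is exactly the negative classical NLL at the
  # corresponding parameters (the P-VAE nests the classical objective)
  model <- a$model; td <- a$train_design
  enc <- pvae_encode(model, td)
  pr <- model$priors
  params <- list(edge_shift = pr$shift_sd * model$mD,
                 log_g = log(td$g0) + pr$scale_sd * enc$shot_m,
                 log_bg = log(td$bg0) + pr$bg_sd * enc$sb[, 1])
  nll <- as.numeric(negative_log_likelihood(params, td))
  eps0 <- list(B = rep(0, td$n_sb), I = rep(0, td$n_shot), D = 0)
  l0 <- sfxspread:::pvae_loss(model, td, eps0)
  expect_equal(-l0$recon, nll, tolerance = abs(nll) * 0.01)
})

test_that("posterior samples follow the fitted Gaussian and reproduce", {
  sim <- simulate_dataset(small_config(8, shift = 1), seed = 3)
  cfg <- small_config(8, shift = 1); cfg$pvae$epochs <- 60
  pf <- train_pvae(build_design(sim$data), cfg, seed = 3)
  s0 <- sample_posterior(pf, n = 0)
  expect_length(s0$edge_shift, 0)
  expect_true(is.list(s0$summary))
  a <- sample_posterior(pf, n = 50, seed = 9)
  b <- sample_posterior(pf, n = 50, seed = 9)
  expect_identical(a$edge_shift, b$edge_shift)
  big <- sample_posterior(pf, n = 1e4, seed = 10)
  expect_lt(abs(mean(big$edge_shift) - pf$posterior$edge_shift_mean),
            4 * pf$posterior$edge_shift_sd / sqrt(1e4))
  expect_s3_class(big$curves[[1]], "anomalous_curve")
  untrained <- pf; untrained$model$trained <- FALSE
  expect_error(sample_posterior(untrained), "trained")
})

test_that("null-shift posterior intervals usually cover zero", {
  cfg <- small_config(24, shift = 0)
  cfg$pvae$epochs <- 150
  covered <- 0
  for (s in 1:10) {
    sim <- simulate_dataset(cfg, seed = 200 + s)
    pf <- train_pvae(build_design(sim$data), cfg, seed = 200 + s)
    lo <- pf$posterior$edge_shift_mean -
      1.645 * pf$posterior$edge_shift_sd
    hi <- pf$posterior$edge_shift_mean +
      1.645 * pf$posterior$edge_shift_sd
    if (lo <= 0 && hi >= 0) covered <- covered + 1
  }
  expect_gte(covered, 6)
})
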