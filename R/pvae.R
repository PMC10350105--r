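# Physics-informed variational autoencoder for the edge shift.
#
# Hierarchical latent structure, all in standardized (unconstrained) space
# where the prior is N(0, 1):
#   dataset level  eps_D: edge shift  dE = prior_shift_sd * eps_D   [eV]
#   image level    eps_s: per-shot   log g_s = log g_hat_s + prior_scale_sd * eps_s
#   shoebox level  eps_j: per-box    log b_j = log b_hat_j + prior_bg_sd * eps_j
# The generator is the same physics forward model the classical fit uses
# (the precomputed design), composed with a learned multiplicative
# correction exp(phi(u, v) . theta) in log-intensity space, where (u, v)
# are panel coordinates of each pixel: identity at theta = 0, penalized by
# ||theta||^2. The encoder is a one-hidden-layer MLP on the log1p pixel
# counts plus normalized metadata, with two Gaussian heads: a shoebox-level
# posterior and a per-shoebox contribution to the image-level posterior,
# pooled across a shot by natural-parameter averaging. The dataset-level
# posterior is a free (non-amortized) Gaussian. All gradients are derived
# and implemented in closed form (verified against finite differences in
# the test suite) and optimized with Adam.

# --- closed-form pieces ------------------------------------------------------

# KL( N(m, exp(s)^2) || N(0,1) )
kl_std_gaussian <- function(m, s) 0.5 * (m^2 + exp(2 * s) - 1 - 2 * s)

#' Pool Gaussian posteriors by natural-parameter averaging
#'
#' Given per-shoebox Gaussian contributions (mean, log-sd) to a shared
#' image-level latent, returns the pooled Gaussian whose natural parameters
#' (mu/var, 1/var) are the averages of the contributions'.
#'
#' @param m means of the contributions.
#' @param s log standard deviations of the contributions.
#' @return list with pooled `m` and `s`.
#' @export
pool_posterior <- function(m, s) {
  v <- exp(2 * s)
  eta2 <- mean(1 / v)
  eta1 <- mean(m / v)
  list(m = eta1 / eta2, s = -0.5 * log(eta2))
}

# correction basis: smooth low-order field of panel coordinates
correction_basis <- function(u, v) cbind(u, v, u * v, u^2, v^2)

# --- model state -------------------------------------------------------------

# raw encoder feature matrix (n_sb x d): log1p pixel counts (padded for
# edge-clipped boxes) plus metadata the warning about over-explanatory
# metadata allows: resolution, detector radius, integrated counts and the
# perimeter background estimate — never the raw Miller indices
pvae_features_raw <- function(design) {
  npx <- design$sb_npix
  d_pix <- max(npx)
  xm <- t(vapply(seq_len(design$n_sb), function(i) {
    x <- log1p(design$counts[design$pix_rows[[i]]])
    if (length(x) < d_pix) x <- c(x, rep(0, d_pix - length(x)))
    x
  }, numeric(d_pix)))
  bc <- design$beam_center
  meta <- t(vapply(seq_len(design$n_sb), function(i) {
    md <- design$meta[[i]]
    c(md$d, sqrt((md$fast - bc[1])^2 + (md$slow - bc[2])^2),
      log1p(sum(design$counts[design$pix_rows[[i]]])),
      log(design$bg0[i]))
  }, numeric(4)))
  cbind(xm, meta)
}

pvae_features <- function(design) {
  x <- pvae_features_raw(design)
  mu <- colMeans(x)
  sd <- pmax(apply(x, 2, stats::sd), 1e-6)
  list(x = sweep(sweep(x, 2, mu), 2, sd, "/"), mu = mu, sd = sd)
}

#' Initialize a P-VAE model state
#'
#' Encoder hidden weights are drawn small and random; the output heads are
#' zero-initialized so the untrained posteriors equal the priors exactly,
#' and the correction starts at the identity.
#'
#' @param design a [build_design()] object.
#' @param config experiment configuration (the `pvae` block).
#' @param seed integer seed for the weight initialization.
#' @return object of class `pvae_model`.
#' @export
pvae_init <- function(design, config = default_config(), seed = 1) {
  config <- validate_config(config)
  pv <- config$pvae
  feats <- pvae_features(design)
  d <- ncol(feats$x); h <- pv$hidden
  set.seed(seed)
  state <- list(
    W1 = matrix(stats::rnorm(h * d, 0, 1 / sqrt(d)), h, d),
    b1 = rep(0, h),
    W2 = matrix(0, 4, h),       # heads: mB, sB, mI, sI
    b2 = rep(0, 4),
    mD = 0, sD = 0,             # free dataset-level posterior
    theta = rep(0, 5),          # correction coefficients
    features = feats,
    priors = list(shift_sd = pv$prior_shift_sd, scale_sd = pv$prior_scale_sd,
                  bg_sd = pv$prior_bg_sd),
    correction = isTRUE(pv$correction),
    penalty_weight = pv$penalty_weight,
    config = config,
    trained = FALSE)
  class(state) <- "pvae_model"
  state
}

#' Encode shoeboxes into variational posteriors
#'
#' Runs the encoder on every shoebox of the design and pools the
#' image-level contributions per shot. With zero-initialized output heads
#' the returned posteriors equal the priors (location 0, unit spread in
#' the standardized space).
#'
#' @param model a [pvae_init()] (or trained) model state.
#' @param design the [build_design()] the model was built for.
#' @return list: `sb` (matrix n_sb x 4 of head outputs: mB, sB, mI, sI),
#'   `shot_m`, `shot_s` (pooled image-level posteriors per shot), and the
#'   hidden activations (for backpropagation).
#' @export
pvae_encode <- function(model, design) {
  x <- model$features$x
  a1 <- tcrossprod(x, model$W1) + rep(model$b1, each = nrow(x))  # n_sb x h
  z1 <- tanh(a1)
  out <- tcrossprod(z1, model$W2) + rep(model$b2, each = nrow(x)) # n_sb x 4
  shot_m <- numeric(design$n_shot); shot_s <- numeric(design$n_shot)
  for (s in seq_len(design$n_shot)) {
    idx <- which(design$shot_of_sb == s)
    if (!length(idx)) { shot_m[s] <- 0; shot_s[s] <- 0; next }
    p <- pool_posterior(out[idx, 3], out[idx, 4])
    shot_m[s] <- p$m; shot_s[s] <- p$s
  }
  list(sb = out, shot_m = shot_m, shot_s = shot_s, z1 = z1)
}

# --- ELBO and gradients ------------------------------------------------------

# Evaluate the negative ELBO (plus correction penalty) and, optionally, its
# gradient, at given standard-normal draws eps (reparameterization).
# Returns list(loss, recon, kl, penalty, grad).
pvae_loss <- function(model, design, eps, gradient = FALSE) {
  enc <- pvae_encode(model, design)
  pr <- model$priors
  # latents
  mB <- enc$sb[, 1]; sB <- enc$sb[, 2]
  zB <- mB + exp(sB) * eps$B                       # per shoebox
  zI <- enc$shot_m + exp(enc$shot_s) * eps$I       # per shot
  zD <- model$mD + exp(model$sD) * eps$D           # scalar
  dE <- pr$shift_sd * zD
  g <- design$g0 * exp(pr$scale_sd * zI)
  b <- design$bg0 * exp(pr$bg_sd * zB)
  md <- design_model(design, dE, deriv = gradient)
  gp <- g[design$shot_of_pix]; bp <- b[design$sb_of_pix]
  phys <- gp * md$m + bp
  if (model$correction) {
    phi <- correction_basis(design$pix_u, design$pix_v)
    logG <- as.numeric(phi %*% model$theta)
    lam <- pmax(exp(logG) * phys, 1e-12)
  } else {
    phi <- NULL
    lam <- pmax(phys, 1e-12)
  }
  k <- design$counts
  recon <- sum(k * log(lam) - lam) - design$lgamma_k
  klB <- kl_std_gaussian(mB, sB)
  klI <- kl_std_gaussian(enc$shot_m, enc$shot_s)
  klD <- kl_std_gaussian(model$mD, model$sD)
  kl <- sum(klB) + sum(klI) + klD
  pen <- sum(model$theta^2)
  loss <- -recon + kl + model$penalty_weight * pen
  if (!gradient)
    return(list(loss = loss, recon = recon, kl = kl, penalty = pen))
  # d(-recon)/dlam * dlam/d...
  r <- (1 - k / lam)                 # = -(dlogp/dlam) * lam / lam ... per pixel
  G <- if (model$correction) exp(as.numeric(phi %*% model$theta)) else 1
  # wrt theta: dlam/dtheta_j = lam * phi_j
  g_theta <- if (model$correction)
    as.numeric(crossprod(phi, r * lam)) + 2 * model$penalty_weight * model$theta
  else rep(0, 5)
  # wrt dE
  ddE <- sum(r * G * gp * md$dm)
  g_mD <- ddE * pr$shift_sd + model$mD
  g_sD <- ddE * pr$shift_sd * exp(model$sD) * eps$D + exp(2 * model$sD) - 1
  # wrt per-shot zI (through log g): dlam/dzI = G * g * m * scale_sd
  dzI <- as.numeric(rowsum(r * G * gp * md$m, design$shot_of_pix)) *
    pr$scale_sd
  g_shot_m <- dzI + enc$shot_m
  g_shot_s <- dzI * exp(enc$shot_s) * eps$I + exp(2 * enc$shot_s) - 1
  # wrt per-shoebox zB (through log b)
  dzB <- as.numeric(rowsum(r * G * bp, design$sb_of_pix)) * pr$bg_sd
  g_mB <- dzB + mB
  g_sB <- dzB * exp(sB) * eps$B + exp(2 * sB) - 1
  # backprop pooled image posterior to per-shoebox contributions
  g_mI <- numeric(design$n_sb); g_sI <- numeric(design$n_sb)
  for (s in seq_len(design$n_shot)) {
    idx <- which(design$shot_of_sb == s)
    n <- length(idx); if (!n) next
    mi <- enc$sb[idx, 3]; si <- enc$sb[idx, 4]
    vi <- exp(2 * si)
    eta2 <- mean(1 / vi)
    w <- 1 / (n * vi * eta2)
    g_mI[idx] <- g_shot_m[s] * w
    g_sI[idx] <- g_shot_m[s] * (-2 * w * (mi - enc$shot_m[s])) +
      g_shot_s[s] * w
  }
  # encoder backprop
  dout <- cbind(g_mB, g_sB, g_mI, g_sI)        # n_sb x 4
  x <- model$features$x
  gW2 <- crossprod(dout, enc$z1)               # 4 x h
  gb2 <- colSums(dout)
  dz1 <- dout %*% model$W2                     # n_sb x h
  da1 <- dz1 * (1 - enc$z1^2)
  gW1 <- crossprod(da1, x)                     # h x d
  gb1 <- colSums(da1)
  list(loss = loss, recon = recon, kl = kl, penalty = pen,
       grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                   mD = g_mD, sD = g_sD, theta = g_theta))
}

#' Evaluate the P-VAE objective (negative ELBO with correction penalty)
#'
#' Single-sample reparameterized estimate of the negative evidence lower
#' bound plus the weighted correction penalty:
#' total = -reconstruction + kl + weight * penalty. KL terms are computed
#' in closed form for the diagonal Gaussian posteriors. Stochastic, but
#' reproducible for a fixed seed.
#'
#' @param model a `pvae_model`.
#' @param design the matching [build_design()].
#' @param seed seed for the reparameterization draws.
#' @return list of class `elbo_loss`: `total`, `reconstruction`, `kl`,
#'   `correction_penalty`.
#' @export
pvae_elbo <- function(model, design, seed = 1) {
  set.seed(seed)
  eps <- list(B = stats::rnorm(design$n_sb), I = stats::rnorm(design$n_shot),
              D = stats::rnorm(1))
  l <- pvae_loss(model, design, eps)
  structure(list(total = l$loss, reconstruction = l$recon, kl = l$kl,
                 correction_penalty = l$penalty), class = "elbo_loss")
}

# --- training ----------------------------------------------------------------

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  list(par = par - lr * mh / (sqrt(vh) + eps), state = state)
}

#' Train the P-VAE on a dataset
#'
#' Full-batch stochastic-gradient (Adam, one fresh reparameterization draw
#' per epoch) optimization of the encoder, the free dataset-level
#' posterior and the correction coefficients. A fraction of shots is held
#' out; their mean per-pixel deviance at the posterior means is tracked as
#' a validation trace and their pixels never contribute to gradients.
#' Fixed seed gives a reproducible trajectory.
#'
#' @param dataset a `spread_dataset` or prebuilt [build_design()].
#' @param config experiment configuration (`pvae` block).
#' @param seed integer seed.
#' @return object of class `pvae_fit`: `model` (trained state),
#'   `posterior` (edge-shift posterior mean/sd in eV), `trace`
#'   (loss per epoch), `val_trace`, `val_shots`, `design`.
#' @export
train_pvae <- function(dataset, config = NULL, seed = 1) {
  design <- if (inherits(dataset, "spread_design")) dataset
            else build_design(dataset)
  if (is.null(config))
    config <- if (inherits(dataset, "spread_dataset")) dataset$config
              else default_config()
  config <- validate_config(config)
  pv <- config$pvae
  set.seed(seed)
  n_val <- floor(design$n_shot * pv$val_frac)
  val_shots <- if (n_val > 0) sort(sample.int(design$n_shot, n_val))
               else integer(0)
  train_design <- design_subset(design, setdiff(seq_len(design$n_shot),
                                                val_shots))
  val_design <- if (n_val > 0) design_subset(design, val_shots) else NULL
  model <- pvae_init(train_design, config, seed = seed + 1)
  pars <- c("W1", "b1", "W2", "b2", "mD", "sD", "theta")
  ad <- lapply(pars, function(p)
    list(t = 0, m = model[[p]] * 0, v = model[[p]] * 0))
  names(ad) <- pars
  trace <- numeric(pv$epochs); val_trace <- rep(NA_real_, pv$epochs)
  avg <- NULL; n_avg <- 0   # Polyak average over the final phase
  set.seed(seed + 2)
  for (ep in seq_len(pv$epochs)) {
    eps <- list(B = stats::rnorm(train_design$n_sb),
                I = stats::rnorm(train_design$n_shot),
                D = stats::rnorm(1))
    l <- pvae_loss(model, train_design, eps, gradient = TRUE)
    if (!is.finite(l$loss))
      stop(sprintf("P-VAE training aborted: non-finite loss at epoch %d", ep))
    trace[ep] <- l$loss
    # step decay so parameters settle at the end of training
    lr <- pv$lr * if (ep > 0.85 * pv$epochs) 0.02 else
      if (ep > 0.6 * pv$epochs) 0.2 else 1
    for (p in pars) {
      st <- adam_step(model[[p]], l$grad[[p]], ad[[p]], lr)
      model[[p]] <- st$par
      ad[[p]] <- st$state
    }
    if (ep > 0.85 * pv$epochs) {
      n_avg <- n_avg + 1
      if (is.null(avg)) avg <- model[pars]
      else for (p in pars) avg[[p]] <- avg[[p]] + (model[[p]] - avg[[p]]) / n_avg
    }
    if (!is.null(val_design) && ep %% 10 == 0)
      val_trace[ep] <- pvae_heldout_deviance(model, val_design)
  }
  if (!is.null(avg)) for (p in pars) model[[p]] <- avg[[p]]
  model$trained <- TRUE
  post_mean <- pv$prior_shift_sd * model$mD
  post_sd <- pv$prior_shift_sd * exp(model$sD)
  structure(list(model = model, design = design,
                 train_design = train_design, val_design = val_design,
                 val_shots = val_shots,
                 posterior = list(edge_shift_mean = post_mean,
                                  edge_shift_sd = post_sd),
                 trace = trace, val_trace = val_trace,
                 config = config, seed = seed),
            class = "pvae_fit")
}

#' @export
print.pvae_fit <- function(x, ...) {
  cat(sprintf("<pvae_fit> edge-shift posterior %+.3f +/- %.3f eV (%d epochs)\n",
              x$posterior$edge_shift_mean, x$posterior$edge_shift_sd,
              length(x$trace)))
  invisible(x)
}

# restrict a design to a subset of shots (renumbered consecutively)
design_subset <- function(design, shots) {
  keep_sb <- which(design$shot_of_sb %in% shots)
  keep_pix <- which(design$sb_of_pix %in% keep_sb)
  new_shot <- match(design$shot_of_sb[keep_sb], shots)
  npx <- design$sb_npix[keep_sb]
  d <- design
  d$Pw <- design$Pw[keep_pix, , drop = FALSE]
  d$counts <- design$counts[keep_pix]
  d$dec <- list(A = design$dec$A[keep_sb], M = design$dec$M[keep_sb])
  d$sb_of_pix <- rep.int(seq_along(keep_sb), npx)
  d$sb_npix <- npx
  d$pix_rows <- split(seq_along(keep_pix), d$sb_of_pix)
  d$shot_of_sb <- new_shot
  d$shot_of_pix <- rep.int(new_shot, npx)
  d$n_sb <- length(keep_sb)
  d$n_shot <- length(shots)
  d$g0 <- design$g0[shots]
  d$bg0 <- design$bg0[keep_sb]
  d$hkl <- design$hkl[keep_sb, , drop = FALSE]
  d$meta <- design$meta[keep_sb]
  d$geom <- design$geom[keep_sb]
  d$pix_u <- design$pix_u[keep_pix]
  d$pix_v <- design$pix_v[keep_pix]
  d$sig_r2 <- design$sig_r2[keep_sb]
  d$sig_eff2 <- design$sig_eff2[keep_sb]
  d$amp <- design$amp[keep_sb]
  d$orientations <- design$orientations[shots]
  d$recips <- design$recips[shots]
  d$lgamma_k <- sum(lgamma(d$counts + 1))
  d
}

#' Held-out average per-pixel Poisson deviance
#'
#' Evaluates the trained generator on a design — typically the held-out
#' shots — and returns the mean per-pixel deviance
#' 2 \[k log(k / lambda) - (k - lambda)\]. With `nuisance = "encoder"`
#' (default) the per-shot scales and backgrounds come from the amortized
#' encoder at the posterior means; with `nuisance = "refit"` they are
#' re-solved exactly on the evaluation shots, which isolates the effect of
#' the learned correction from encoder noise when comparing corrected and
#' uncorrected models on the same split.
#'
#' @param model a trained (or in-training) `pvae_model`.
#' @param design design of the evaluation shots.
#' @param nuisance `"encoder"` or `"refit"`.
#' @return mean per-pixel deviance (scalar).
#' @export
pvae_heldout_deviance <- function(model, design,
                                  nuisance = c("encoder", "refit")) {
  nuisance <- match.arg(nuisance)
  if (nuisance == "refit") {
    pr <- model$priors
    md <- design_model(design, pr$shift_sd * model$mD)
    m <- md$m
    if (model$correction) {
      phi <- correction_basis(design$pix_u, design$pix_v)
      m <- exp(as.numeric(phi %*% model$theta)) * m
    }
    nb <- nuisance_refit(m, design, design$g0, design$bg0, sweeps = 40)
    lam <- pmax(nb$g[design$shot_of_pix] * m + nb$b[design$sb_of_pix], 1e-12)
    k <- design$counts
    return(mean(2 * (ifelse(k > 0, k * log(k / lam), 0) - (k - lam))))
  }
  pvae_deviance_encoder(model, design)
}

pvae_deviance_encoder <- function(model, design) {
  # the encoder is amortized, so it applies to unseen shots directly; its
  # feature standardization comes from the training set
  m2 <- model
  raw <- pvae_features_raw(design)
  m2$features <- list(
    x = sweep(sweep(raw, 2, model$features$mu), 2, model$features$sd, "/"),
    mu = model$features$mu, sd = model$features$sd)
  enc <- pvae_encode(m2, design)
  pr <- model$priors
  dE <- pr$shift_sd * model$mD
  g <- design$g0 * exp(pr$scale_sd * enc$shot_m)
  b <- design$bg0 * exp(pr$bg_sd * enc$sb[, 1])
  md <- design_model(design, dE)
  lam <- g[design$shot_of_pix] * md$m + b[design$sb_of_pix]
  if (model$correction) {
    phi <- correction_basis(design$pix_u, design$pix_v)
    lam <- exp(as.numeric(phi %*% model$theta)) * lam
  }
  lam <- pmax(lam, 1e-12)
  k <- design$counts
  dev <- 2 * (ifelse(k > 0, k * log(k / lam), 0) - (k - lam))
  mean(dev)
}

#' Sample the posterior over anomalous curves and edge shifts
#'
#' Draws i.i.d. samples from the dataset-level variational posterior of
#' the edge shift and maps each through the curve parameterization
#' (reference curve translated by the sampled shift).
#'
#' @param fit a trained [train_pvae()] result.
#' @param n number of samples.
#' @param seed RNG seed.
#' @return list: `edge_shift` (n samples, eV), `curves` (list of n
#'   [anomalous_curve()]), `summary` (mean, sd, central 90% interval).
#' @export
sample_posterior <- function(fit, n = 1000, seed = 1) {
  if (!inherits(fit, "pvae_fit") || !fit$model$trained)
    stop("sample_posterior needs a trained pvae_fit")
  set.seed(seed)
  mu <- fit$posterior$edge_shift_mean
  sd <- fit$posterior$edge_shift_sd
  draws <- stats::rnorm(n, mu, sd)
  span <- diff(range(as.numeric(fit$design$curve$grid)))
  draws_c <- pmin(pmax(draws, -span / 2 + 1), span / 2 - 1)
  curves <- lapply(draws_c, function(d) shift_edge(fit$design$curve, d))
  smry <- list(mean = if (n) mean(draws) else mu,
               sd = if (n > 1) stats::sd(draws) else sd,
               q05 = if (n) as.numeric(stats::quantile(draws, 0.05)) else NA,
               q95 = if (n) as.numeric(stats::quantile(draws, 0.95)) else NA)
  list(edge_shift = draws, curves = curves, summary = smry)
}
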