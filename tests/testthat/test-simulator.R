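# Forward simulator: orientations, reflection prediction, the pixel-level
# shoebox model against a brute-force oracle, noise, and model-error
# injections.

test_that("random orientations are proper rotations with Haar statistics", {
  set.seed(1)
  r <- random_orientation()
  expect_equal(crossprod(r), diag(3), tolerance = 1e-12)
  expect_equal(det(r), 1, tolerance = 1e-12)
  set.seed(99); a <- random_orientation()
  set.seed(99); b <- random_orientation()
  expect_identical(a, b)
  set.seed(2)
  draws <- random_orientation(1e4)
  m <- Reduce(`+`, draws) / length(draws)
  expect_true(all(abs(m) < 3 * 0.6 / sqrt(1e4)))
})

test_that("lattice profile has the coherent peak, decay and normalization", {
  cell <- unit_cell(15, 18, 22)
  expect_equal(lattice_profile(0, c(5, 5, 5), cell), 125^2)
  off <- seq(0, 0.01, by = 1e-4)
  prof <- lattice_profile(off, c(8, 8, 8), cell)
  expect_true(all(diff(prof) < 0))
  # 3-D integral of the isotropic profile vs the Gaussian closed form
  sig <- 1 / (2 * pi * 8 * prod(c(15, 18, 22))^(1 / 3))
  integrand <- function(r) 4 * pi * r^2 * lattice_profile(r, c(8, 8, 8), cell)
  num <- stats::integrate(integrand, 0, 20 * sig, rel.tol = 1e-8)$value
  expect_equal(num, 8^6 * (2 * pi)^1.5 * sig^3, tolerance = 0.01)
})

test_that("reflection prediction honors the Bragg condition and nesting", {
  cfg <- default_config()
  scn <- toy_scene(cfg)
  # orientation constructed to put (1,0,0) exactly on the Ewald sphere at
  # the central energy
  lam <- ev_to_angstrom(6550)
  q0 <- as.numeric(scn$crystal$cell$recip %*% c(1, 0, 0))
  qn <- sqrt(sum(q0^2))
  qz <- -qn^2 * lam / 2
  qstar <- c(sqrt(qn^2 - qz^2), 0, qz)
  u <- rotation_between(q0, qstar)
  pred <- predict_reflections(u, scn$crystal, scn$det, scn$spec)
  expect_true(any(pred$h == 1 & pred$k == 0 & pred$l == 0))
  expect_lt(pred$eps_min[pred$h == 1 & pred$k == 0 & pred$l == 0][1], 1e-4)
  # widening the acceptance shell never shrinks the predicted set
  set.seed(3)
  u2 <- random_orientation()
  keys <- function(p) paste(p$h, p$k, p$l)
  prev <- character(0)
  for (mult in c(1, 2, 4)) {
    cur <- keys(predict_reflections(u2, scn$crystal, scn$det, scn$spec,
                                    shell_mult = mult))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  # zero bandwidth + zero mosaic + large coherent blocks: the Bragg
  # condition is nearly measure-zero, so a generic orientation sees at
  # most a stray reflection or two
  mono <- spectrum(6550, 1)
  sharp <- crystal_model(unit_cell(6, 7, 8), scn$crystal$atoms,
                         mosaic_model(1, 0, c(60, 60, 60)))
  n_sharp <- vapply(1:5, function(s) {
    set.seed(s)
    nrow(predict_reflections(random_orientation(), sharp, scn$det, mono))
  }, 0L)
  expect_lt(mean(n_sharp), 1)
})

test_that("vectorized shoebox expectation equals a brute-force triple loop", {
  cfg <- default_config()
  scn <- toy_scene(cfg, shift = 1)
  spec3 <- spectrum(c(6540, 6550, 6560), c(0.3, 0.4, 0.3))
  set.seed(7)
  u <- random_orientation()
  pred <- predict_reflections(u, scn$crystal, scn$det, spec3)
  expect_gt(nrow(pred), 0)
  hkl <- as.integer(pred[1, c("h", "k", "l")])
  doms <- replicate(3, sfxspread:::random_small_rotation(1e-3),
                    simplify = FALSE)
  sb <- simulate_shoebox(hkl, u, scn$crystal, scn$det, spec3, scale = 1.7,
                         flux = 1, background_rate = 2,
                         domain_rotations = doms, noise = FALSE, half = 3,
                         prediction = pred[1, ])
  # independent pixel-by-pixel reference: plain loops, scalar arithmetic
  det <- scn$det; cell <- scn$crystal$cell; mos <- scn$crystal$mosaic
  sig <- 1 / (2 * pi * prod(mos$domain_cells)^(1 / 3) *
                (cell$a * cell$b * cell$c)^(1 / 3))
  f2 <- vapply(spec3$energies, function(e)
    abs(structure_factor(cell, scn$crystal$atoms, hkl, e))^2, 0)
  ref <- matrix(0, 7, 7)
  for (i in 1:7) for (j in 1:7) {
    f <- sb$bbox[1] + i - 1; s <- sb$bbox[3] + j - 1
    x <- (f + 0.5 - det$beam_center[1]) * det$pixel_size
    y <- (s + 0.5 - det$beam_center[2]) * det$pixel_size
    r <- sqrt(x^2 + y^2 + det$distance^2)
    omega <- det$pixel_size^2 * det$distance / r^3
    val <- 0
    for (e in 1:3) {
      il <- 1 / ev_to_angstrom(spec3$energies[e])
      qp <- c(x, y, det$distance) / r * il - c(0, 0, il)
      for (d in 1:3) {
        qd <- as.numeric(doms[[d]] %*% u %*% cell$recip %*% hkl)
        eps2 <- sum((qp - qd)^2)
        val <- val + spec3$weights[e] * f2[e] *
          prod(mos$domain_cells)^2 / 3 * exp(-eps2 / (2 * sig^2))
      }
    }
    ref[i, j] <- 1.7 * omega * val + 2
  }
  expect_equal(unname(sb$counts), ref, tolerance = 1e-10)
  # doubling the scale doubles the expectation above background exactly
  sb2 <- simulate_shoebox(hkl, u, scn$crystal, scn$det, spec3, scale = 3.4,
                          flux = 1, background_rate = 2,
                          domain_rotations = doms, noise = FALSE, half = 3,
                          prediction = pred[1, ])
  expect_equal(sb2$counts - 2, 2 * (sb$counts - 2), tolerance = 1e-10)
})

test_that("zero occupancy leaves pure background and noise is Poisson", {
  cfg <- default_config()
  scn <- toy_scene(cfg)
  ghost <- crystal_model(
    scn$crystal$cell,
    lapply(scn$crystal$atoms, function(a) { a$occupancy <- 0; a }),
    scn$crystal$mosaic)
  set.seed(11)
  u <- random_orientation()
  pred <- predict_reflections(u, scn$crystal, scn$det, scn$spec)
  sb <- simulate_shoebox(as.integer(pred[1, 1:3]), u, ghost, scn$det,
                         scn$spec, noise = FALSE, mosaic_mode = "smooth",
                         background_rate = 1.5, prediction = pred[1, ])
  expect_equal(unname(sb$counts), matrix(1.5, 9, 9), tolerance = 1e-12)
  # replicate Poisson draws of one shoebox: per-pixel mean within 4 SE
  sb0 <- simulate_shoebox(as.integer(pred[1, 1:3]), u, scn$crystal, scn$det,
                          scn$spec, noise = FALSE, mosaic_mode = "smooth",
                          half = 2, prediction = pred[1, ])
  lam <- sb0$counts[3, 3]
  set.seed(21)
  n <- 4000
  draws <- vapply(seq_len(n), function(i)
    simulate_shoebox(as.integer(pred[1, 1:3]), u, scn$crystal, scn$det,
                     scn$spec, noise = TRUE, mosaic_mode = "smooth",
                     half = 2, prediction = pred[1, ])$counts[3, 3], 0)
  expect_lt(abs(mean(draws) - lam), 4 * sqrt(lam / n))
})

test_that("datasets are reproducible and degenerate jitters collapse", {
  cfg <- small_config(6)
  a <- simulate_dataset(cfg, seed = 42)
  b <- simulate_dataset(cfg, seed = 42)
  expect_identical(serialize(a$data, NULL), serialize(b$data, NULL))
  expect_identical(serialize(a$truth, NULL), serialize(b$truth, NULL))
  cfg0 <- cfg
  cfg0$dataset$scale_sdlog <- 0
  cfg0$dataset$cell_jitter <- 0
  d <- simulate_dataset(cfg0, seed = 1)
  gs <- vapply(d$truth$shots, function(s) s$scale, 0)
  expect_true(all(gs == gs[1]))
  cells <- vapply(d$truth$shots, function(s) s$cell$a, 0)
  expect_true(all(cells == cells[1]))
  empty <- simulate_dataset(small_config(0), seed = 1)
  expect_length(empty$data$shots, 0)
})

test_that("model-error injections perturb the generator as stated", {
  expect_error(inject_model_error(default_config(), "sensor_fire", 1),
               "pixel_gain_field")
  base <- small_config(3); base$dataset$noise <- FALSE
  nom <- simulate_dataset(base, seed = 5)
  zero <- simulate_dataset(inject_model_error(base, "pixel_gain_field", 0),
                           seed = 5)
  expect_identical(serialize(nom$data$shots, NULL),
                   serialize(zero$data$shots, NULL))
  gain <- simulate_dataset(inject_model_error(base, "pixel_gain_field", 0.1),
                           seed = 5)
  for (s in 1:3) {
    for (i in seq_along(nom$data$shots[[s]]$shoeboxes)) {
      ratio <- gain$data$shots[[s]]$shoeboxes[[i]]$counts /
        nom$data$shots[[s]]$shoeboxes[[i]]$counts
      expect_true(all(ratio >= 0.9 - 1e-12 & ratio <= 1.1 + 1e-12))
    }
  }
  ramp <- simulate_dataset(
    inject_model_error(base, "background_gradient", 0.5), seed = 5)
  # pure-background rows (along the fast axis) must be strictly monotone;
  # check on a signal-free shoebox built from the ramped config
  cfg0 <- inject_model_error(base, "background_gradient", 0.5)
  cfg0$crystal$atoms <- lapply(cfg0$crystal$atoms, function(a) {
    a$occupancy <- 0; a })
  flat <- simulate_dataset(cfg0, seed = 5)
  sb <- flat$data$shots[[1]]$shoeboxes[[1]]
  expect_true(all(diff(rowMeans(sb$counts)) > 0) ||
                all(diff(rowMeans(sb$counts)) < 0))
  # mosaic misspecification only touches the generating mosaic
  mm <- inject_model_error(base, "mosaic_misspecification", 0.5)
  sim_mm <- simulate_dataset(mm, seed = 5)
  expect_identical(sim_mm$data$mosaic$angular_spread,
                   base$mosaic$angular_spread)
})

test_that("Friedel mates at mirrored orientations match without absorption and split with it", {
  cfg <- default_config()
  scn_plain <- toy_scene(cfg)
  # remove the anomalous curve entirely
  atoms0 <- lapply(scn_plain$crystal$atoms, function(a) {
    a$anomalous_curve <- NULL; a })
  cr0 <- crystal_model(scn_plain$crystal$cell, atoms0,
                       scn_plain$crystal$mosaic)
  mirror <- diag(c(-1, 1, -1))
  set.seed(13)
  found <- FALSE
  for (try in 1:10) {
    u <- random_orientation()
    pred <- predict_reflections(u, cr0, scn_plain$det, scn_plain$spec)
    if (!nrow(pred)) next
    hkl <- as.integer(pred[1, 1:3])
    u2 <- mirror %*% u
    pred2 <- predict_reflections(u2, cr0, scn_plain$det, scn_plain$spec)
    row2 <- pred2[pred2$h == -hkl[1] & pred2$k == -hkl[2] &
                    pred2$l == -hkl[3], ]
    if (!nrow(row2)) next
    found <- TRUE
    mk <- function(cr, h, uu, prow)
      simulate_shoebox(h, uu, cr, scn_plain$det, scn_plain$spec,
                       noise = FALSE, mosaic_mode = "smooth",
                       prediction = prow)
    a <- mk(cr0, hkl, u, pred[1, ])
    b <- mk(cr0, -hkl, u2, row2[1, ])
    expect_equal(sum(a$counts), sum(b$counts), tolerance = 1e-8)
    # same geometry with the Mn-like curve active: Friedel symmetry breaks
    a2 <- mk(scn_plain$crystal, hkl, u, pred[1, ])
    b2 <- mk(scn_plain$crystal, -hkl, u2, row2[1, ])
    expect_gt(abs(sum(a2$counts) - sum(b2$counts)) /
                abs(sum(a2$counts) - 81 * 2), 1e-4)
    break
  }
  expect_true(found)
})
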