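test_that("affine decomposition and matrix composition round-trip", {
  set.seed(31)
  for (i in 1:25) {
    p <- affine_params(rotation = runif(1, -pi / 3, pi / 3),
                       shear = runif(1, -0.3, 0.3),
                       scale_x = runif(1, 0.5, 2), scale_y = runif(1, 0.5, 2),
                       translation = runif(2, -10, 10),
                       center = c(32.5, 32.5), constrained = FALSE)
    q <- decompose_affine(p$matrix, center = p$center)
    expect_equal(q$rotation, p$rotation, tolerance = 1e-9)
    expect_equal(q$shear, p$shear, tolerance = 1e-9)
    expect_equal(c(q$scale_x, q$scale_y), c(p$scale_x, p$scale_y), tolerance = 1e-9)
    expect_equal(q$translation, p$translation, tolerance = 1e-9)
    expect_equal(q$matrix, p$matrix, tolerance = 1e-12)
  }
  # constrained mode refuses scale changes and keeps unit determinant
  expect_error(affine_params(scale_x = 1.1), "constrained")
  pc <- affine_params(rotation = 0.3, shear = 0, translation = c(2, -1),
                      center = c(10, 10))
  expect_equal(det(pc$matrix[, 1:2]), 1, tolerance = 1e-12)
  expect_error(affine_params(rotation = NaN), "non-finite")
})

test_that("warping honours identity, integer shifts and rotation round-trips", {
  set.seed(8)
  img <- image2d(matrix(runif(64 * 64), 64, 64), 41.2)
  id <- affine_params(center = c(32.5, 32.5))
  expect_identical(apply_transform(img, id), img)

  sh <- affine_params(translation = c(3, -2), center = c(32.5, 32.5))
  out <- apply_transform(img, sh)
  # interior of the shifted image: output (r, c) = input (r + 2, c - 3)
  expect_equal(unclass(out)[4:60, 6:60], unclass(img)[6:62, 3:57],
               tolerance = 1e-12)

  smooth <- simulate_synapse_pair(quiet_spec(seed = 2), trans = FALSE)$image$pre
  ctr <- c((ncol(smooth) + 1) / 2, (nrow(smooth) + 1) / 2)
  fwd <- apply_transform(smooth, affine_params(rotation = 0.3, center = ctr))
  back <- apply_transform(fwd, affine_params(rotation = -0.3, center = ctr))
  interior <- 20:108
  err <- mean(abs(unclass(back)[interior, interior] -
                    unclass(smooth)[interior, interior]))
  expect_lt(err, 0.01 * diff(range(smooth)))
})

test_that("constrained alignment recovers known translations and rotations", {
  img <- simulate_synapse_pair(quiet_spec(seed = 4), trans = FALSE)$image$post
  ctr <- c((ncol(img) + 1) / 2, (nrow(img) + 1) / 2)

  self <- estimate_constrained_affine(img, img)
  expect_lt(sqrt(sum(self$shift_vector^2)), 0.1)
  expect_gt(self$pcc_after, 0.999)

  moved <- apply_transform(img, affine_params(translation = c(5, -3), center = ctr))
  aln <- estimate_constrained_affine(img, moved)
  expect_lt(max(abs(aln$shift_vector - c(-5, 3))), 0.5)
  expect_gt(aln$pcc_after, 0.99)

  rot <- apply_transform(img, affine_params(rotation = 10 * pi / 180, center = ctr))
  aln2 <- estimate_constrained_affine(img, rot)
  expect_lt(abs(aln2$transform$rotation + 10 * pi / 180), pi / 180)
  expect_gt(aln2$pcc_after, 0.98)
  # scale stays locked through the optimisation
  expect_equal(c(aln2$transform$scale_x, aln2$transform$scale_y), c(1, 1))
  expect_error(estimate_constrained_affine(img, img, roi = c(1, 1, 3, 3)), "ROI")
})

test_that("alignment never does worse than the identity transform", {
  for (s in 1:6) {
    spec <- sim_spec(seed = s, lateral_jitter = 100, poisson_noise = TRUE)
    sim <- simulate_synapse_pair(spec, applied_misalignment =
                                   list(dx = runif(1, -200, 200),
                                        dy = runif(1, -200, 200),
                                        rot = runif(1, -0.15, 0.15)),
                                 trans = FALSE)
    aln <- estimate_constrained_affine(sim$image$post, sim$image$pre)
    expect_gte(aln$pcc_after, aln$pcc_before - 1e-6)
  }
})

test_that("the distortion field is zero for identity and follows the transform", {
  id <- affine_params(center = c(16.5, 16.5))
  f0 <- transform_distortion(id, c(32, 32))
  expect_true(all(f0$displacement_vectors == 0))
  tr <- affine_params(translation = c(2, 1), center = c(16.5, 16.5))
  f1 <- transform_distortion(tr, c(32, 32))
  expect_true(all(abs(f1$displacement_vectors[, 1] - 2) < 1e-12))
  expect_equal(unname(f1$summary["mean"]), sqrt(5), tolerance = 1e-12)
})

test_that("similarity registration recovers identity and a 2x scene scale", {
  spec <- quiet_spec(image_shape = c(72, 72), pixel_size = 99,
                     domain_sigma = 150, seed = 14)
  pre <- simulate_expansion_pair(spec, scale = 1, n_points = 25)$pre
  self <- estimate_similarity(pre, pre)
  expect_equal(self$params$scale, 1, tolerance = 1e-3)
  expect_gt(self$pcc, 0.999)

  ex2 <- simulate_expansion_pair(spec, scale = 2, n_points = 25,
                                 post_pixel_size = 99)  # same pixel pitch
  sim2 <- estimate_similarity(ex2$post, ex2$pre)
  expect_equal(sim2$params$scale, 2, tolerance = 0.01)
  expect_error(estimate_similarity(image2d(matrix(1, 8, 8), 99), pre),
               "featureless")
})

test_that("affine refinement adds little when the expansion is undistorted", {
  spec <- quiet_spec(image_shape = c(80, 80), pixel_size = 99,
                     domain_sigma = 130, seed = 17)
  ex <- simulate_expansion_pair(spec, scale = 4, n_points = 30)
  sim <- estimate_similarity(ex$post, ex$pre)
  aff <- refine_affine_full(ex$post, ex$pre, sim)
  expect_gte(aff$pcc, sim$pcc - 1e-6)
  expect_lt(aff$pcc - sim$pcc, 0.01)
  expect_lt(unname(aff$distortion$summary["mean"]), 0.5)
})

test_that("structural expansion factor converts pixel scales to physical units", {
  spec <- quiet_spec(image_shape = c(64, 64), pixel_size = 99,
                     domain_sigma = 130, seed = 23)
  pre <- simulate_expansion_pair(spec, scale = 1, n_points = 25)$pre
  est1 <- expansion_factor_structural(pre, pre)
  expect_equal(est1$factor, 1, tolerance = 1e-3)

  # post rendered at a coarser pixel pitch: pixel scale 3, physical factor 8
  ex <- simulate_expansion_pair(spec, scale = 8, n_points = 25,
                                post_pixel_size = 99 * 8 / 3)
  est8 <- expansion_factor_structural(ex$pre, ex$post)
  expect_equal(est8$factor, 8, tolerance = 0.02)
})
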