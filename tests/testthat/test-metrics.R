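test_that("pearson_cc matches the textbook formula and its exact limits", {
  a <- image2d(matrix(c(1, 2, 3, 4), 2, 2), 41.2)
  b <- image2d(matrix(c(2, 4, 6, 9), 2, 2), 41.2)
  expect_equal(pearson_cc(a, b), oracle_pearson(c(1, 2, 3, 4), c(2, 4, 6, 9)),
               tolerance = 1e-12)
  expect_equal(pearson_cc(a, a), 1, tolerance = 1e-12)
  neg <- image2d(-unclass(a) + 10, 41.2)
  expect_equal(pearson_cc(a, neg), -1, tolerance = 1e-12)
  expect_error(pearson_cc(a, image2d(matrix(5, 2, 2), 41.2)), "zero variance")

  # invariance under positive affine intensity rescaling
  set.seed(2)
  x <- image2d(matrix(runif(100), 10, 10), 41.2)
  y <- image2d(matrix(runif(100), 10, 10), 41.2)
  expect_equal(pearson_cc(x, y),
               pearson_cc(image2d(3 * unclass(x) + 7, 41.2), y),
               tolerance = 1e-12)

  mask <- matrix(FALSE, 10, 10); mask[1, 1] <- TRUE
  expect_error(pearson_cc(x, y, mask), "2 pixels")
})

test_that("orientation-shift cosine flags perpendicular shifts as consistent", {
  perp <- orientation_shift_cosine(0, c(0, 5))
  expect_equal(perp$value, 0)
  expect_true(perp$consistent)
  par <- orientation_shift_cosine(0, c(5, 0))
  expect_equal(par$value, 1)
  expect_false(par$consistent)

  # brute-force vector arithmetic for an oblique case
  u <- c(cos(pi / 4), sin(pi / 4)); s <- c(1, 2) / sqrt(5)
  expect_equal(orientation_shift_cosine(pi / 4, c(1, 2))$value, sum(u * s),
               tolerance = 1e-12)

  # antisymmetric under shift negation, bounded in [-1, 1]
  set.seed(3)
  for (i in 1:20) {
    th <- runif(1, -pi / 2, pi / 2); sh <- rnorm(2)
    v1 <- orientation_shift_cosine(th, sh)$value
    v2 <- orientation_shift_cosine(th, -sh)$value
    expect_equal(v1, -v2, tolerance = 1e-12)
    expect_lte(abs(v1), 1)
  }

  zero <- orientation_shift_cosine(1, c(0, 0))
  expect_equal(zero$value, 0)
  expect_equal(zero$flag, "no shift")

  raw <- orientation_shift_cosine(0, c(2, 2), normalized = FALSE)
  expect_equal(raw$value, 2)
})

test_that("coloc map is the AND of per-channel masks with an anchored PCC", {
  spec <- quiet_spec(seed = 19, background = 2)
  img <- simulate_synapse_pair(spec)$image
  same <- coloc_map(img$post, img$post, anchor = "a")
  expect_identical(same$map, unclass(img$post) > same$threshold_a)
  expect_equal(same$pcc, 1, tolerance = 1e-12)

  # disjoint foregrounds produce an empty map
  a <- matrix(1, 20, 20); a[2:5, 2:5] <- 100
  b <- matrix(1, 20, 20); b[14:17, 14:17] <- 100
  dis <- coloc_map(image2d(a, 41.2), image2d(b, 41.2))
  expect_equal(sum(dis$map), 0)
})

test_that("expansion arithmetic reproduces the worked gel and cleft numbers", {
  gel <- macroscopic_expansion_factor(12, 100)
  expect_equal(round(gel$factor, 1), 8.3)
  expect_equal(gel$method, "macroscopic")
  expect_equal(macroscopic_expansion_factor(5, 5)$factor, 1)
  expect_equal(macroscopic_expansion_factor(10, 45)$factor, 4.5)
  expect_error(macroscopic_expansion_factor(0, 10), "positive")

  expect_equal(to_biological_scale(318, 8), 39.75)
  expect_equal(round(to_biological_scale(318, 8), -1), 40)
  expect_equal(to_biological_scale(7, 1), 7)
  expect_equal(to_biological_scale(824, 8.3), 99.27711, tolerance = 1e-6)
  expect_error(to_biological_scale(318, 0), "positive")
})

test_that("group summaries exclude 1.5 SD outliers in a single pass", {
  flat <- summarize_group(rep(0.5, 6))
  expect_equal(flat$mean, 0.5)
  expect_equal(flat$median, 0.5)
  expect_equal(flat$sd, 0)
  expect_length(flat$excluded_indices, 0)

  v <- c(0.5, 0.5, 0.5, 0.5, 0.9)
  su <- summarize_group(v)
  manual_excl <- which(abs(v - mean(v)) > 1.5 * sd(v))
  expect_equal(su$excluded_indices, manual_excl)
  survivors <- v[-manual_excl]
  expect_equal(su$mean, mean(survivors))
  expect_equal(su$n_used, su$n_total - length(manual_excl))
  expect_equal(su$q25, unname(quantile(survivors, 0.25)))

  # survivors stay inside the full-sample band
  set.seed(4)
  w <- rnorm(200, 0.6, 0.15)
  sw <- summarize_group(w)
  expect_true(all(abs(c(sw$min, sw$max) - mean(w)) <= 1.5 * sd(w) + 1e-12))

  expect_error(summarize_group(c(1, 2)), "at least 3")
})

test_that("the exclusion fraction matches the normal tail mass", {
  set.seed(11)
  v <- rnorm(1000, 0.6, 0.1)
  su <- summarize_group(v)
  frac <- length(su$excluded_indices) / 1000
  p <- 2 * pnorm(-1.5)
  se <- sqrt(p * (1 - p) / 1000)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("group comparison gates the t-test on Shapiro-Wilk normality", {
  set.seed(21)
  a <- rnorm(30, 0.5, 0.1)
  same <- compare_groups(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$method, "t-test")

  # pooled-variance t statistic against the hand formula
  x <- c(0.42, 0.55, 0.48, 0.61, 0.50)
  y <- c(0.66, 0.71, 0.59, 0.74, 0.68)
  cmp <- compare_groups(x, y)
  expect_equal(cmp$method, "t-test")
  expect_equal(cmp$statistic, oracle_t_statistic(x, y), tolerance = 1e-12)

  # heavily non-normal data falls back to the rank test, flagged
  set.seed(22)
  u <- c(rep(0.1, 20), rep(0.9, 20)) + rnorm(40, 0, 1e-4)
  w <- rexp(40)
  fb <- compare_groups(u, w)
  expect_match(fb$method, "wilcoxon")

  deg <- compare_groups(rep(1, 5), rep(1, 5))
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)
  expect_error(compare_groups(1:2, 1:5), "n >= 3")
})
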