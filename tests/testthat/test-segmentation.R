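test_that("otsu threshold separates a perfectly bimodal image", {
  img <- image2d(matrix(c(rep(0, 50), rep(100, 50)), 10, 10), 41.2)
  t <- otsu_threshold(img)
  expect_true(t >= 0 && t < 100)
  expect_equal(sum(unclass(img) > t), 50)

  disc <- image2d(matrix(c(rep(10, 90), rep(200, 10)), 10, 10), 41.2)
  td <- otsu_threshold(disc)
  expect_equal(td, oracle_otsu(disc))
  expect_equal(sum(unclass(disc) > td), 10)

  expect_error(otsu_threshold(image2d(matrix(3, 5, 5), 41.2)), "degenerate")
})

test_that("otsu threshold equals the exhaustive brute-force search", {
  set.seed(101)
  for (i in 1:100) {
    v <- switch(1 + i %% 4,
                rnorm(400, 50, 10) + rbinom(400, 1, 0.3) * rnorm(400, 60, 15),
                runif(300, 0, 1),
                round(rgamma(500, 2, 0.1)),
                sample(0:255, 256, replace = TRUE))
    img <- image2d(matrix(v, ncol = 1), 41.2)
    if (max(v) == min(v)) next
    expect_equal(otsu_threshold(img), oracle_otsu(v))
  }
})

test_that("labeling finds size-sorted components whose areas sum to the mask", {
  m <- matrix(0, 20, 20)
  m[2:6, 2:6] <- 1      # 25 px
  m[12:14, 12:14] <- 1  # 9 px
  lab <- regions_from_mask(m)
  expect_length(lab$regions, 2)
  expect_equal(vapply(lab$regions, `[[`, numeric(1), "area_px"), c(25, 9))
  expect_equal(sum(lab$label_map > 0), sum(m))
  expect_equal(sort(unique(as.numeric(lab$label_map))), c(0, 1, 2))

  # diagonal touch merges under 8- but not 4-connectivity
  d <- matrix(0, 5, 5); d[1, 1] <- 1; d[2, 2] <- 1
  expect_length(label_and_sort(image2d(d, 41.2), 0.5, connectivity = 8L)$regions, 1)
  expect_length(label_and_sort(image2d(d, 41.2), 0.5, connectivity = 4L)$regions, 2)

  # empty foreground is not an error
  expect_length(regions_from_mask(matrix(0, 5, 5))$regions, 0)
})

test_that("region moments match a brute-force second-moment oracle", {
  # axis-aligned 30 x 6 rectangle
  m <- matrix(0, 40, 40); m[10:15, 5:34] <- 1
  r <- regions_from_mask(m)$regions[[1]]
  o <- oracle_moments(r$pixels)
  expect_lt(abs(r$orientation), 1e-6)
  expect_equal(r$orientation, o$orientation)
  expect_equal(r$major_axis_px, o$major, tolerance = 1e-12)
  expect_equal(r$minor_axis_px, o$minor, tolerance = 1e-12)
  expect_equal(r$axis_ratio, 5, tolerance = 0.05)
  expect_equal(r$bounding_box, c(10, 5, 16, 35))

  # the same bar rasterized at 45 degrees
  th <- pi / 4
  tpts <- seq(-15, 15, by = 0.25)
  rot <- unique(round(cbind(20 + tpts * sin(th) + rep(c(-1, 0, 1), each = length(tpts)),
                            20 + tpts * cos(th))))
  rot <- rot[rot[, 1] >= 1 & rot[, 2] >= 1 & rot[, 1] <= 40 & rot[, 2] <= 40, ]
  mr <- matrix(0, 40, 40); mr[rot] <- 1
  rr <- regions_from_mask(mr)$regions[[1]]
  expect_equal(rr$orientation, pi / 4, tolerance = 0.05)
  expect_equal(rr$orientation, oracle_moments(rr$pixels)$orientation)
})

test_that("random blobs give moments identical to the oracle", {
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(rbinom(400, 1, 0.3), 20, 20)
    lab <- regions_from_mask(m)
    if (length(lab$regions) == 0) next
    r <- lab$regions[[1]]
    o <- oracle_moments(r$pixels)
    expect_equal(r$orientation, o$orientation)
    expect_equal(r$major_axis_px, o$major, tolerance = 1e-12)
    expect_equal(r$minor_axis_px, o$minor, tolerance = 1e-12)
  }
})

test_that("merging the top clusters pools pixels under one moment ellipse", {
  m <- matrix(0, 20, 44)
  m[9:12, c(2:5, 18:21, 34:37)] <- 1   # three collinear squares along x
  lab <- regions_from_mask(m)
  merged <- merge_top_clusters(lab, 3)
  expect_lt(abs(merged$orientation), 1e-6)
  expect_gt(merged$axis_ratio, max(vapply(lab$regions, `[[`, numeric(1), "axis_ratio")))
  expect_equal(merged$area_px, 48)

  # k = 1 reduces to the largest region
  one <- merge_top_clusters(lab, 1)
  expect_equal(one[names(one) != "pixels"],
               lab$regions[[1]][names(lab$regions[[1]]) != "pixels"])

  # two squares stacked along y merge into a vertical ellipse
  m2 <- matrix(0, 30, 12)
  m2[c(3:6, 24:27), 5:8] <- 1
  lab2 <- regions_from_mask(m2)
  expect_equal(abs(merge_top_clusters(lab2, 2)$orientation), pi / 2,
               tolerance = 1e-6)
})

test_that("the selection rule covers accept, merge-fallback and discard branches", {
  accept_state <- function(mask, ...) {
    cand <- select_synapse(regions_from_mask(mask), ...)
    list(accepted = cand$accepted, stage = cand$stage)
  }
  # large elongated region: accepted outright
  m1 <- matrix(0, 60, 60); m1[20:29, 10:49] <- 1   # 400 px, ratio ~4
  expect_equal(accept_state(m1), list(accepted = TRUE, stage = "primary_region"))

  # three small clusters, individually failing, elongated union: merged accept
  m2 <- matrix(0, 60, 90)
  m2[26:35, c(5:19, 38:52, 71:85)] <- 1            # 3 x 150 px, each ratio 1.5
  r2 <- regions_from_mask(m2)
  expect_lt(r2$regions[[1]]$area_px, 300)          # largest alone fails on area
  expect_equal(accept_state(m2), list(accepted = TRUE, stage = "merged_region"))

  # single small round region: nothing to merge, discarded
  m3 <- matrix(0, 30, 30); m3[10:19, 10:19] <- 1   # 100 px, ratio 1
  expect_equal(accept_state(m3), list(accepted = FALSE, stage = "discarded"))

  # empty mask: discarded with a reason
  cand <- select_synapse(regions_from_mask(matrix(0, 10, 10)))
  expect_false(cand$accepted)
  expect_match(cand$reason, "no foreground")

  # QC plot is written in every case
  qc <- tempfile(fileext = ".png")
  select_synapse(regions_from_mask(m3), qc_path = qc)
  expect_true(file.exists(qc))
})

test_that("selection is invariant under positive intensity rescaling", {
  spec <- quiet_spec(seed = 13)
  img <- simulate_synapse_pair(spec, trans = FALSE)$image$post
  t1 <- otsu_threshold(img)
  scaled <- image2d(unclass(img) * 3.7, pixel_size(img))
  t2 <- otsu_threshold(scaled)
  expect_equal(t2, 3.7 * t1, tolerance = 1e-9)
  expect_identical(unclass(img) > t1, unclass(scaled) > t2)
})

test_that("segmentation recovers the simulated synapse orientation", {
  for (th in c(-1.2, -0.5, 0, pi / 6, 1.1)) {
    spec <- quiet_spec(orientation = th, seed = 3)
    img <- simulate_synapse_pair(spec, trans = FALSE)$image$pre
    lab <- label_and_sort(img, otsu_threshold(img))
    expect_equal(lab$regions[[1]]$orientation, th, tolerance = 0.05)
  }
})

test_that("otsu agrees with EBImage on a continuous image", {
  skip_if_not_installed("EBImage")
  set.seed(5)
  v <- pmin(pmax(c(rnorm(200, 0.3, 0.05), rnorm(56, 0.7, 0.05)), 0), 1)
  img <- matrix(v, 16, 16)
  ours <- otsu_threshold(image2d(img, 41.2))
  ref <- EBImage::otsu(EBImage::Image(img), range = range(img), levels = 256)
  # conventions differ in bin placement; the resulting masks must agree
  expect_gte(mean((img > ours) == (img > ref)), 0.97)
})
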