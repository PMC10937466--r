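# Independent brute-force oracles used across the suite. These are written
# as plain loops over raw pixel values so they share no code path with the
# package implementations they check.

# Exhaustive Otsu search: partition the raw pixels at every candidate
# threshold and maximise the between-class variance directly.
oracle_otsu <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  uv <- sort(unique(v))
  cand <- if (all(v == round(v)) && length(uv) <= n_bins) {
    uv[-length(uv)]
  } else {
    breaks <- seq(min(v), max(v), length.out = n_bins + 1L)
    breaks[2:n_bins]
  }
  best <- -Inf; best_t <- cand[1]
  for (t in cand) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v)
    bcv <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  best_t
}

# Second central moments of a pixel set, computed by explicit loops, with
# closed-form eigen decomposition of the 2x2 covariance.
oracle_moments <- function(pixels) {
  y <- pixels[, 1]; x <- pixels[, 2]
  n <- length(x)
  cx <- sum(x) / n; cy <- sum(y) / n
  mu20 <- 0; mu02 <- 0; mu11 <- 0
  for (i in seq_len(n)) {
    mu20 <- mu20 + (x[i] - cx)^2
    mu02 <- mu02 + (y[i] - cy)^2
    mu11 <- mu11 + (x[i] - cx) * (y[i] - cy)
  }
  mu20 <- mu20 / n; mu02 <- mu02 / n; mu11 <- mu11 / n
  tr <- mu20 + mu02
  disc <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  list(orientation = theta, major = 4 * sqrt(max(l1, 0)),
       minor = 4 * sqrt(max(l2, 0)))
}

# Textbook Pearson coefficient via the covariance / sd formula.
oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  cov <- sum((a - ma) * (b - mb)) / (n - 1)
  cov / (sqrt(sum((a - ma)^2) / (n - 1)) * sqrt(sum((b - mb)^2) / (n - 1)))
}

# Pooled-variance two-sample t statistic.
oracle_t_statistic <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Build a labeled_regions object from a logical mask, through the public
# segmentation surface (threshold 0.5 on a 0/1 image).
regions_from_mask <- function(mask) {
  label_and_sort(image2d(mask * 1.0, 41.2), 0.5)
}

# A noise-free spec small enough for fast tests.
quiet_spec <- function(...) {
  args <- list(...)
  defaults <- list(poisson_noise = FALSE, background = 0)
  do.call(sim_spec, utils::modifyList(defaults, args))
}

# True pre->post transform of a simulated pair with lateral_jitter = 0:
# the post bar is the pre bar shifted by the cleft vector, then rotated by
# mis$rot about the image center and shifted by (mis$dx, mis$dy). In pixel
# units the aligning transform has rotation mis$rot and translation
# R(mis$rot) cleft_v + t_mis.
true_pair_transform <- function(spec, mis) {
  v <- c(-sin(spec$orientation), cos(spec$orientation)) * spec$cleft_offset
  R <- matrix(c(cos(mis$rot), sin(mis$rot), -sin(mis$rot), cos(mis$rot)), 2, 2)
  t_nm <- as.numeric(R %*% v) + c(mis$dx, mis$dy)
  list(rotation = mis$rot, translation_px = t_nm / spec$pixel_size)
}
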