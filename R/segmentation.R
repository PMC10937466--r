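#' Otsu threshold of an intensity image
#'
#' Maximises the between-class variance of the foreground/background split
#' over a 256-bin histogram spanning the intensity range. For integer-valued
#' images with at most 256 distinct levels the native levels are used as
#' candidate thresholds instead of bin edges, so small synthetic label maps
#' threshold exactly. Pixels strictly above the returned value are
#' foreground.
#'
#' @param image an `image2d` (or numeric matrix).
#' @param n_bins histogram bins for continuous images.
#' @return the threshold intensity (scalar).
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- sort(as.numeric(image))
  lo <- v[1]; hi <- v[length(v)]
  if (hi == lo) stop("degenerate histogram: image is constant")
  uv <- unique(v)
  if (all(v == round(v)) && length(uv) <= n_bins) {
    cand <- uv[-length(uv)]          # threshold at each level but the top
  } else {
    breaks <- seq(lo, hi, length.out = n_bins + 1L)
    cand <- breaks[2:n_bins]         # interior bin edges
  }
  n <- length(v)
  cs <- cumsum(v)
  n0 <- findInterval(cand, v)        # pixels with value <= candidate
  ok <- n0 > 0L & n0 < n
  mu0 <- cs[pmax(n0, 1L)] / pmax(n0, 1L)
  mu1 <- (cs[n] - cs[pmax(n0, 1L)]) / pmax(n - n0, 1L)
  w0 <- n0 / n
  bcv <- ifelse(ok, w0 * (1 - w0) * (mu0 - mu1)^2, -Inf)
  cand[which.max(bcv)]
}

# 8- or 4-connected component labeling by iterative min-label propagation.
# Vectorised over the whole mask; converges in O(geodesic diameter) sweeps,
# ample for synapse-sized fields.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(Inf, H, W)
  lab[mask] <- which(mask)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  shift_mat <- function(m, dr, dc) {
    out <- matrix(Inf, H, W)
    r_dst <- max(1, 1 + dr):min(H, H + dr)
    c_dst <- max(1, 1 + dc):min(W, W + dc)
    out[r_dst, c_dst] <- m[r_dst - dr, c_dst - dc]
    out
  }
  repeat {
    new <- lab
    for (s in shifts) new <- pmin(new, shift_mat(lab, s[1], s[2]))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, H, W)
  if (any(mask)) {
    ids <- sort(unique(lab[mask]))
    out[mask] <- match(lab[mask], ids)
  }
  out
}

#' Moment-derived shape of a pixel set
#'
#' Area, centroid, orientation and ellipse axes from the second central
#' moments of the binary pixel set (the normalised-second-moment ellipse:
#' axis length = 4 sqrt(eigenvalue) of the coordinate covariance).
#' Orientation is the major-axis angle in (-pi/2, pi/2], measured from the
#' +x (column) axis with y along increasing row index.
#'
#' @param pixels N x 2 matrix of (row, col) pixel coordinates.
#' @return a `region_shape` list: `area_px`, `centroid` (x, y) px,
#'   `orientation` rad, `major_axis_px`, `minor_axis_px`, `axis_ratio`,
#'   `bounding_box` (row_min, col_min, row_max, col_max; half-open),
#'   `pixels`.
#' @export
region_shape <- function(pixels) {
  pixels <- matrix(as.integer(pixels), ncol = 2)
  n <- nrow(pixels)
  stopifnot(n >= 1L)
  y <- pixels[, 1]; x <- pixels[, 2]
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  cov <- matrix(c(mu20, mu11, mu11, mu02), 2, 2)
  ev <- eigen(cov, symmetric = TRUE)
  major <- 4 * sqrt(max(ev$values[1], 0))
  minor <- 4 * sqrt(max(ev$values[2], 0))
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  structure(list(
    area_px = n,
    centroid = c(x = cx, y = cy),
    orientation = theta,
    major_axis_px = major,
    minor_axis_px = minor,
    axis_ratio = if (minor > 0) major / minor else Inf,
    bounding_box = c(min(y), min(x), max(y) + 1L, max(x) + 1L),
    pixels = pixels
  ), class = "region_shape")
}

#' Threshold, label and sort connected regions
#'
#' Binarises the image at `threshold` (pixels strictly above are
#' foreground), labels connected components (8-connectivity by default) and
#' returns their moment shapes sorted by area, largest first.
#'
#' @param image an `image2d`.
#' @param threshold intensity threshold, e.g. from [otsu_threshold()].
#' @param connectivity 8 (default) or 4.
#' @return a `labeled_regions` list: `label_map` (0 = background, labels
#'   follow the size order), `regions` (list of [region_shape()]),
#'   `source_threshold`.
#' @export
label_and_sort <- function(image, threshold, connectivity = 8L) {
  mask <- unclass(image) > threshold
  lab <- label_components(mask, connectivity)
  k <- max(lab)
  regions <- list()
  if (k > 0) {
    idx <- which(lab > 0, arr.ind = TRUE)
    by_lab <- split(seq_len(nrow(idx)), lab[lab > 0])
    regions <- lapply(by_lab, function(i) region_shape(idx[i, , drop = FALSE]))
    ord <- order(vapply(regions, `[[`, numeric(1), "area_px"), decreasing = TRUE)
    regions <- unname(regions[ord])
    relab <- matrix(0L, nrow(lab), ncol(lab))
    for (new in seq_along(ord))
      relab[lab == as.integer(names(by_lab))[ord[new]]] <- new
    lab <- relab
  }
  structure(list(label_map = lab, regions = regions,
                 source_threshold = threshold),
            class = "labeled_regions")
}

#' Shape of the union of the largest clusters
#'
#' Pools the pixel sets of the `min(k, K)` largest regions and computes the
#' moment shape of the union with the same formulas as a single region —
#' the fallback used when the largest cluster alone is too small or too
#' round to qualify as a synapse.
#'
#' @param regions a [label_and_sort()] result.
#' @param k number of largest clusters to pool (default 3).
#' @return a [region_shape()].
#' @export
merge_top_clusters <- function(regions, k = 3L) {
  if (length(regions$regions) == 0L) stop("no regions to merge")
  take <- regions$regions[seq_len(min(k, length(regions$regions)))]
  region_shape(do.call(rbind, lapply(take, `[[`, "pixels")))
}

#' Select the synaptic region of interest
#'
#' Two-stage rule: the largest connected region qualifies if its area is at
#' least `min_area` pixels and its major/minor axis ratio at least
#' `min_axis_ratio`; if it fails, the union of the three largest regions is
#' re-tested; if that also fails the synapse is discarded. A QC plot of the
#' evaluated region over the label map is written when `qc_path` is given,
#' so decisions can be verified by eye.
#'
#' @param regions a [label_and_sort()] result.
#' @param min_area minimum region area in pixels (default 300).
#' @param min_axis_ratio minimum elongation (default 2).
#' @param channel_name label recorded in the candidate.
#' @param qc_path optional PNG path for the QC image.
#' @return a `synapse_candidate` list: `channel_name`, `accepted`, `stage`
#'   (`primary_region`, `merged_region` or `discarded`), `shape` (NULL when
#'   no foreground), `reason`, `qc_plot_path`.
#' @export
select_synapse <- function(regions, min_area = 300, min_axis_ratio = 2,
                           channel_name = "", qc_path = NULL) {
  passes <- function(s) s$area_px >= min_area && s$axis_ratio >= min_axis_ratio
  out <- list(channel_name = channel_name, accepted = FALSE,
              stage = "discarded", shape = NULL, reason = "",
              qc_plot_path = qc_path)
  if (length(regions$regions) == 0L) {
    out$reason <- "no foreground"
  } else {
    primary <- regions$regions[[1]]
    if (passes(primary)) {
      out$accepted <- TRUE; out$stage <- "primary_region"; out$shape <- primary
    } else {
      merged <- merge_top_clusters(regions, 3L)
      if (passes(merged)) {
        out$accepted <- TRUE; out$stage <- "merged_region"; out$shape <- merged
      } else {
        out$shape <- merged
        out$reason <- sprintf("area %d px, axis ratio %.2f below (%g, %g)",
                              merged$area_px, merged$axis_ratio,
                              min_area, min_axis_ratio)
      }
    }
  }
  if (!is.null(qc_path)) write_qc_plot(regions, out, qc_path)
  structure(out, class = "synapse_candidate")
}

# QC image: grey label map, evaluated region in green (accepted) or red.
write_qc_plot <- function(regions, candidate, path) {
  lab <- regions$label_map
  base <- ifelse(lab > 0, 0.4 + 0.5 * lab / max(max(lab), 1L), 0)
  rgb <- array(rep(base, 3L), dim = c(nrow(lab), ncol(lab), 3L))
  if (!is.null(candidate$shape)) {
    px <- candidate$shape$pixels
    ch <- if (candidate$accepted) 2L else 1L
    rgb[cbind(px[, 1], px[, 2], ch)] <- 1
  }
  png::writePNG(rgb, path)
  invisible(path)
}
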