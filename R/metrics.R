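#' Pearson correlation between two channels over a region
#'
#' The alignment and colocalization statistic: pixel-intensity Pearson
#' correlation of two channels over the masked region. A good correlation
#' over the whole synaptic domain indicates the presence of trans-synaptic
#' nanocolumns.
#'
#' @param a,b `image2d` objects (or matrices) of identical shape.
#' @param mask logical matrix selecting the pixels; default all.
#' @return correlation in [-1, 1].
#' @export
pearson_cc <- function(a, b, mask = NULL) {
  stopifnot(all(dim(a) == dim(b)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(a), ncol(a))
  stopifnot(all(dim(mask) == dim(a)))
  va <- as.numeric(unclass(a)[mask]); vb <- as.numeric(unclass(b)[mask])
  if (length(va) < 2L) stop("mask must cover at least 2 pixels")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance: a channel is constant within the mask")
  stats::cor(va, vb)
}

#' Cosine between the synapse orientation and the alignment shift
#'
#' A nanocolumn-consistent alignment moves the pre-synaptic signal onto
#' its post-synaptic counterpart across the cleft, i.e. perpendicular to
#' the synapse major axis — so the cosine between the unit major-axis
#' vector `(cos theta, sin theta)` and the unit shift vector should be
#' near zero. `|cosine| < threshold` flags the synapse as
#' trans-synaptic-consistent. A raw (unnormalised) dot product is
#' available via `normalized = FALSE`.
#'
#' @param orientation major-axis angle in radians.
#' @param shift c(dx, dy) shift vector in px.
#' @param threshold consistency cut on |cosine| (default 0.3).
#' @param normalized divide by |shift| (cosine) or keep the raw dot.
#' @return list `value` (the cosine, 0 for a zero shift), `consistent`,
#'   `flag` ("ok" or "no shift").
#' @export
orientation_shift_cosine <- function(orientation, shift, threshold = 0.3,
                                     normalized = TRUE) {
  u <- c(cos(orientation), sin(orientation))
  len <- sqrt(sum(shift^2))
  if (len == 0)
    return(list(value = 0, consistent = NA, flag = "no shift"))
  v <- if (normalized) shift / len else shift
  val <- sum(u * v)
  list(value = val, consistent = abs(val) < threshold, flag = "ok")
}

#' Colocalization map and Pearson coefficient of two channels
#'
#' Binarises each channel with its own Otsu threshold and reports the
#' pixelwise AND as the colocalization map, plus the Pearson correlation
#' over the bounding box of the anchor channel's largest connected region
#' (the anchor keeps the synapse orientation stable, e.g. the
#' trans-synaptic LGI1 signal). No alignment transform is applied:
#' colocalization, unlike nanocolumn analysis, is computed on unmoved
#' channels.
#'
#' @param a,b `image2d` channels of identical shape.
#' @param anchor `"a"` or `"b"`: whose largest region fixes the ROI.
#' @return list `map` (logical matrix), `pcc`, `roi` (half-open bbox),
#'   `threshold_a`, `threshold_b`.
#' @export
coloc_map <- function(a, b, anchor = c("a", "b")) {
  anchor <- match.arg(anchor)
  stopifnot(all(dim(a) == dim(b)))
  ta <- otsu_threshold(a); tb <- otsu_threshold(b)
  map <- (unclass(a) > ta) & (unclass(b) > tb)
  anchor_img <- if (anchor == "a") a else b
  anchor_thr <- if (anchor == "a") ta else tb
  lab <- label_and_sort(anchor_img, anchor_thr)
  if (length(lab$regions) == 0L) stop("anchor channel has no foreground")
  roi <- lab$regions[[1]]$bounding_box
  rows <- roi[1]:(roi[3] - 1L); cols <- roi[2]:(roi[4] - 1L)
  roi_mask <- matrix(FALSE, nrow(a), ncol(a)); roi_mask[rows, cols] <- TRUE
  # a channel can be constant inside the ROI (e.g. fully disjoint signals);
  # the map is still meaningful, the correlation is undefined
  pcc <- tryCatch(pearson_cc(a, b, roi_mask), error = function(e) NA_real_)
  list(map = map, pcc = pcc, roi = roi,
       threshold_a = ta, threshold_b = tb)
}

#' Macroscopic expansion factor from gel diameters
#'
#' The simplest expansion readout: the ratio of the gel diameter after and
#' before expansion (e.g. 12 mm to ~10 cm gives ~8.3x).
#'
#' @param pre_diameter,post_diameter gel diameters in the same unit (> 0).
#' @return an `expansion_estimate` with `method = "macroscopic"`.
#' @export
macroscopic_expansion_factor <- function(pre_diameter, post_diameter) {
  if (pre_diameter <= 0 || post_diameter <= 0)
    stop("gel diameters must be positive")
  structure(list(factor = post_diameter / pre_diameter, method = "macroscopic",
                 pcc_similarity = NULL, pcc_affine = NULL,
                 distortion_summary = NULL),
            class = "expansion_estimate")
}

#' Convert an expanded-frame distance to biological scale
#'
#' Divides a distance measured in the expanded specimen by the linear
#' expansion factor, e.g. a ~318 nm expanded cleft distance corresponds to
#' ~40 nm at 8x.
#'
#' @param distance_expanded nm in the expanded frame.
#' @param factor linear expansion factor (> 0).
#' @return nm at biological scale.
#' @export
to_biological_scale <- function(distance_expanded, factor) {
  if (factor <= 0) stop("expansion factor must be positive")
  distance_expanded / factor
}

#' Summarise a group of per-synapse values with outlier exclusion
#'
#' Values deviating from the group mean by more than 1.5 standard
#' deviations (mean and SD over the full sample, applied in a single pass)
#' are excluded; the summary (mean, SD, median, quartiles by linear
#' interpolation, range) describes the survivors, matching the box-plot
#' convention used for per-synapse PCC distributions.
#'
#' @param values numeric vector, length >= 3.
#' @param sd_factor exclusion cut in SD units (default 1.5).
#' @return a `group_summary`: `n_total`, `n_used`, `mean`, `sd`, `median`,
#'   `q25`, `q75`, `min`, `max`, `excluded_indices`.
#' @export
summarize_group <- function(values, sd_factor = 1.5) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 values")
  m <- mean(values); s <- stats::sd(values)
  excluded <- if (s > 0) which(abs(values - m) > sd_factor * s) else integer(0)
  used <- if (length(excluded)) values[-excluded] else values
  q <- stats::quantile(used, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(n_total = length(values), n_used = length(used),
                 mean = mean(used), sd = stats::sd(used),
                 median = q[2], q25 = q[1], q75 = q[3],
                 min = min(used), max = max(used),
                 excluded_indices = excluded),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary n = %d/%d, mean %.3f +/- %.3f, median %.3f [%.3f, %.3f]>\n",
              x$n_used, x$n_total, x$mean, x$sd, x$median, x$q25, x$q75))
  invisible(x)
}

#' Compare two groups of per-synapse values
#'
#' Shapiro-Wilk normality check per group (alpha = 0.05); if both groups
#' are consistent with normality, a two-sided pooled-variance two-sample
#' t-test is applied; otherwise the result is flagged and a Wilcoxon
#' rank-sum test is reported instead as a distribution-free fallback.
#'
#' @param a,b numeric vectors, each length >= 3.
#' @param alpha normality-rejection level.
#' @return list `normal_a`, `normal_b` (logical, NA for constant input),
#'   `shapiro_p_a`, `shapiro_p_b`, `method` ("t-test" or
#'   "wilcoxon (non-normal fallback)"), `statistic`, `p_value`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L) stop("each group needs n >= 3")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    return(list(normal_a = NA, normal_b = NA, shapiro_p_a = NA, shapiro_p_b = NA,
                method = "degenerate", statistic = 0, p_value = 1,
                mean_a = mean(a), mean_b = mean(b),
                n_a = length(a), n_b = length(b)))
  sw <- function(x) {
    if (stats::sd(x) == 0 || length(x) > 5000L) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  pa <- sw(a); pb <- sw(b)
  normal_a <- if (is.na(pa)) NA else pa > alpha
  normal_b <- if (is.na(pb)) NA else pb > alpha
  if (isTRUE(normal_a) && isTRUE(normal_b)) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    method <- "t-test"
  } else {
    ht <- stats::wilcox.test(a, b, exact = FALSE)
    method <- "wilcoxon (non-normal fallback)"
  }
  list(normal_a = normal_a, normal_b = normal_b,
       shapiro_p_a = pa, shapiro_p_b = pb, method = method,
       statistic = unname(ht$statistic), p_value = ht$p.value,
       mean_a = mean(a), mean_b = mean(b), n_a = length(a), n_b = length(b))
}
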