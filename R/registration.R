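#' Constrained 2-D affine transform parameters
#'
#' Decomposed as rotation, shear and per-axis scale about a fixed center
#' (the geometric image center), plus a translation:
#' `p = R(rotation) S(shear) diag(scale) (q - center) + center + translation`
#' with `S(shear) = [[1, shear], [0, 1]]`, coordinates (x, y) = (col, row)
#' in pixels. In constrained (scale-locked) mode both scales are exactly 1,
#' so the linear part has unit determinant whenever shear is 0.
#'
#' @param rotation radians, counter-clockwise in the (col, row-down) frame.
#' @param shear dimensionless x-shear.
#' @param scale_x,scale_y axis scales; must both be 1 when `constrained`.
#' @param translation c(tx, ty) in pixels.
#' @param center c(cx, cy) rotation center in pixels.
#' @param constrained logical; enforce the scale lock.
#' @return an `affine_params` list with the composed 2 x 3 matrix.
#' @export
affine_params <- function(rotation = 0, shear = 0, scale_x = 1, scale_y = 1,
                          translation = c(0, 0), center = c(0, 0),
                          constrained = TRUE) {
  if (!all(is.finite(c(rotation, shear, scale_x, scale_y, translation, center))))
    stop("non-finite transform parameters")
  if (constrained && !(scale_x == 1 && scale_y == 1))
    stop("constrained mode requires scale_x = scale_y = 1")
  L <- rot2(rotation) %*% matrix(c(1, 0, shear, 1), 2, 2) %*% diag(c(scale_x, scale_y))
  structure(list(rotation = rotation, shear = shear,
                 scale_x = scale_x, scale_y = scale_y,
                 translation = as.numeric(translation),
                 center = as.numeric(center), constrained = constrained,
                 matrix = cbind(L, center + translation - L %*% center)),
            class = "affine_params")
}

#' Recover decomposed parameters from a 2 x 3 affine matrix
#'
#' Inverts the rotation-shear-scale factorisation used by
#' [affine_params()]; the round trip matrix -> decomposition -> matrix is
#' exact to numerical precision.
#'
#' @param m 2 x 3 matrix (linear part | offset).
#' @param center rotation center the matrix was composed about.
#' @return an `affine_params` (unconstrained).
#' @export
decompose_affine <- function(m, center = c(0, 0)) {
  L <- m[, 1:2]
  rotation <- atan2(L[2, 1], L[1, 1])
  RL <- t(rot2(rotation)) %*% L          # = S(shear) diag(sx, sy)
  scale_x <- RL[1, 1]; scale_y <- RL[2, 2]
  shear <- RL[1, 2] / scale_y
  translation <- m[, 3] - center + L %*% center
  affine_params(rotation, shear, scale_x, scale_y, as.numeric(translation),
                center, constrained = FALSE)
}

is_identity_params <- function(p) {
  p$rotation == 0 && p$shear == 0 && p$scale_x == 1 && p$scale_y == 1 &&
    all(p$translation == 0)
}

# Bilinear sampling of img at continuous (x = col, y = row) positions;
# positions outside the grid return fill.
bilinear_sample <- function(img, qx, qy, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(qx); y0 <- floor(qy)
  wx <- qx - x0; wy <- qy - y0
  pick <- function(yy, xx) {
    ok <- xx >= 1 & xx <= W & yy >= 1 & yy <= H
    val <- rep(fill, length(xx))
    val[ok] <- img[cbind(yy[ok], xx[ok])]
    val
  }
  pick(y0, x0) * (1 - wx) * (1 - wy) + pick(y0, x0 + 1) * wx * (1 - wy) +
    pick(y0 + 1, x0) * (1 - wx) * wy + pick(y0 + 1, x0 + 1) * wx * wy
}

geometric_center <- function(shape) c((shape[2] + 1) / 2, (shape[1] + 1) / 2)

#' Resample an image under an affine transform
#'
#' Pull-back warping with linear interpolation and zero fill: output pixel
#' `p` takes the value of the input at `T^{-1}(p)`. Identity parameters
#' return the input unchanged, bit for bit.
#'
#' @param image an `image2d` (or matrix).
#' @param params an [affine_params()].
#' @return warped `image2d` with the input's pixel size (if any).
#' @export
apply_transform <- function(image, params) {
  if (!inherits(params, "affine_params")) {
    if (is.list(params) && !is.null(params$scale))  # similarity parameters
      params <- affine_params(rotation = params$rotation,
                              scale_x = params$scale, scale_y = params$scale,
                              translation = params$translation,
                              center = geometric_center(dim(image)),
                              constrained = FALSE)
    else stop("params must be affine_params or similarity parameters")
  }
  if (is_identity_params(params)) return(image)
  H <- nrow(image); W <- ncol(image)
  L <- params$matrix[, 1:2]
  Linv <- solve(L)
  c0 <- params$center; t0 <- params$translation
  grid <- expand.grid(y = seq_len(H), x = seq_len(W))
  dx <- grid$x - c0[1] - t0[1]
  dy <- grid$y - c0[2] - t0[2]
  qx <- Linv[1, 1] * dx + Linv[1, 2] * dy + c0[1]
  qy <- Linv[2, 1] * dx + Linv[2, 2] * dy + c0[2]
  out <- matrix(bilinear_sample(unclass(image), qx, qy), H, W)
  ps <- attr(image, "pixel_size")
  if (is.null(ps)) out else image2d(out, ps)
}

# Displacement of transform map_fun (px -> px) on a regular grid.
displacement_grid <- function(shape, map_fun, step = 8L) {
  gx <- seq(1, shape[2], by = step)
  gy <- seq(1, shape[1], by = step)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  mapped <- map_fun(pts)
  d <- mapped - pts
  mag <- sqrt(rowSums(d^2))
  structure(list(grid_points = pts, displacement_vectors = d,
                 summary = c(mean = mean(mag), max = max(mag))),
            class = "distortion_field")
}

#' Distortion field of an affine transform
#'
#' Displacement vectors `T(p) - p` on a regular grid: the "vector map"
#' showing how far each part of the image moved between the unaligned and
#' aligned states.
#'
#' @param params an [affine_params()].
#' @param shape image (H, W).
#' @param step grid spacing in pixels.
#' @return `distortion_field`: grid points, vectors, mean/max magnitude.
#' @export
transform_distortion <- function(params, shape, step = 8L) {
  m <- params$matrix
  displacement_grid(shape, function(p) {
    cbind(m[1, 1] * p[, 1] + m[1, 2] * p[, 2] + m[1, 3],
          m[2, 1] * p[, 1] + m[2, 2] * p[, 2] + m[2, 3])
  }, step)
}

# Pearson/NCC objective machinery for the constrained estimate: fixed ROI
# values against moving samples pulled back under candidate parameters.
make_constrained_objective <- function(fixed, moving, roi) {
  rows <- roi[1]:(roi[3] - 1L); cols <- roi[2]:(roi[4] - 1L)
  grid <- expand.grid(y = rows, x = cols)
  f <- as.numeric(unclass(fixed)[cbind(grid$y, grid$x)])
  if (stats::sd(f) == 0) stop("fixed image constant within ROI")
  c0 <- geometric_center(dim(fixed))
  mv <- unclass(moving)
  function(theta, shear, tx, ty) {
    L <- rot2(theta) %*% matrix(c(1, 0, shear, 1), 2, 2)
    Linv <- solve(L)
    dx <- grid$x - c0[1] - tx; dy <- grid$y - c0[2] - ty
    qx <- Linv[1, 1] * dx + Linv[1, 2] * dy + c0[1]
    qy <- Linv[2, 1] * dx + Linv[2, 2] * dy + c0[2]
    s <- bilinear_sample(mv, qx, qy)
    if (stats::sd(s) == 0) return(-Inf)
    stats::cor(f, s)
  }
}

#' Scale-locked affine alignment of the pre- onto the post-synaptic channel
#'
#' Maximises the Pearson correlation within the synapse ROI under an
#' affine transform whose scale is locked to 1, optimised in stages with
#' decreasing weight: translation first (seeded by a coarse grid search
#' over +/- 25% of the image size), then translation + rotation, then
#' translation + rotation + shear. Rotation and shear act about the
#' geometric image center. The identity is always a candidate, so the
#' aligned correlation can never fall below the unaligned one.
#'
#' @param fixed reference `image2d` (post-synaptic channel).
#' @param moving `image2d` to align (pre-synaptic channel).
#' @param roi half-open bounding box (row_min, col_min, row_max, col_max)
#'   from segmentation; default whole image.
#' @param max_eval optimiser evaluation budget per stage.
#' @param grid_step coarse translation grid spacing (px).
#' @param distortion_step grid spacing of the output distortion field.
#' @return an `alignment_result`: `transform` ([affine_params()]),
#'   `pcc_before`, `pcc_after`, `shift_vector` (tx, ty px),
#'   `orientation_dot` (NA here; filled by the pipeline), `distortion`,
#'   `converged`.
#' @export
estimate_constrained_affine <- function(fixed, moving, roi = NULL,
                                        max_eval = 500L, grid_step = NULL,
                                        distortion_step = 8L) {
  stopifnot(all(dim(fixed) == dim(moving)))
  shape <- dim(fixed)
  if (is.null(roi)) roi <- c(1L, 1L, shape[1] + 1L, shape[2] + 1L)
  roi <- clip_bbox(round(roi), shape)
  if (roi[3] - roi[1] < 3L || roi[4] - roi[2] < 3L)
    stop("ROI smaller than 3 x 3 px")
  obj <- make_constrained_objective(fixed, moving, roi)
  pcc_before <- obj(0, 0, 0, 0)

  if (is.null(grid_step)) grid_step <- max(2L, round(min(shape) / 16))
  span <- 0.25 * min(shape)
  offsets <- unique(c(rev(-seq(0, span, by = grid_step)), seq(0, span, by = grid_step)))
  cand <- as.matrix(expand.grid(tx = offsets, ty = offsets))
  scores <- apply(cand, 1L, function(t) obj(0, 0, t[1], t[2]))
  best <- list(par = c(0, 0, 0, 0), value = pcc_before)  # theta, shear, tx, ty
  top <- cand[which.max(scores), ]
  if (max(scores) > best$value) best <- list(par = c(0, 0, top), value = max(scores))

  converged <- TRUE
  run_stage <- function(par0, active) {
    # active: indices of c(theta, shear, tx, ty) optimised in this stage
    fn <- function(p) {
      full <- par0; full[active] <- p
      -obj(full[1], full[2], full[3], full[4])
    }
    scales <- c(0.05, 0.05, 1, 1)[active]
    fit <- stats::optim(par0[active], fn, method = "Nelder-Mead",
                        control = list(maxit = max_eval, reltol = 1e-8,
                                       parscale = scales))
    if (fit$convergence != 0L) converged <<- FALSE
    full <- par0; full[active] <- fit$par
    list(par = full, value = -fit$value)
  }
  for (active in list(3:4, c(1L, 3L, 4L), c(1L, 2L, 3L, 4L))) {
    st <- run_stage(best$par, active)
    if (st$value > best$value) best <- st
  }

  params <- affine_params(rotation = best$par[1], shear = best$par[2],
                          translation = best$par[3:4],
                          center = geometric_center(shape), constrained = TRUE)
  structure(list(transform = params,
                 pcc_before = pcc_before, pcc_after = best$value,
                 shift_vector = params$translation,
                 orientation_dot = NA_real_,
                 distortion = transform_distortion(params, shape, distortion_step),
                 roi = roi, converged = converged),
            class = "alignment_result")
}

# Masked NCC of moving sampled under a similarity/affine map onto the
# fixed canvas; only in-bounds pull-backs enter the correlation.
cross_canvas_ncc <- function(fixed, moving, map_inv, min_frac = 0.2) {
  H <- nrow(fixed); W <- ncol(fixed)
  grid <- expand.grid(y = seq_len(H), x = seq_len(W))
  q <- map_inv(cbind(grid$x, grid$y))
  ok <- q[, 1] >= 1 & q[, 1] <= ncol(moving) & q[, 2] >= 1 & q[, 2] <= nrow(moving)
  if (mean(ok) < min_frac) return(-Inf)
  s <- bilinear_sample(unclass(moving), q[ok, 1], q[ok, 2])
  f <- as.numeric(unclass(fixed))[ok]
  if (stats::sd(s) == 0 || stats::sd(f) == 0) return(-Inf)
  stats::cor(f, s)
}

similarity_inverse_map <- function(par, c_fixed, c_moving) {
  # par = c(scale, theta, tx, ty); forward: p = s R (q - c_m) + c_f + t
  Rinv <- t(rot2(par[2]))
  function(p) {
    d <- cbind(p[, 1] - c_fixed[1] - par[3], p[, 2] - c_fixed[2] - par[4]) / par[1]
    cbind(Rinv[1, 1] * d[, 1] + Rinv[1, 2] * d[, 2] + c_moving[1],
          Rinv[2, 1] * d[, 1] + Rinv[2, 2] * d[, 2] + c_moving[2])
  }
}

#' Similarity registration (rotation, uniform scale, translation)
#'
#' The four-degree-of-freedom transform used to match pre- and
#' post-expansion images: a coarse geometric grid over candidate scales
#' seeds local Nelder-Mead refinement of (scale, rotation, translation),
#' maximising the Pearson correlation of the overlapping area.
#'
#' @param fixed reference `image2d` (typically the post-expansion image).
#' @param moving `image2d` to map onto `fixed` (pre-expansion image).
#' @param scale_grid candidate scales for the multi-start; default a
#'   geometric grid over 0.5-10 plus exactly 1.
#' @param max_eval refinement evaluation budget.
#' @return list `params` (rotation, scale, translation), `pcc`.
#' @export
estimate_similarity <- function(fixed, moving, scale_grid = NULL,
                                max_eval = 400L) {
  if (stats::sd(as.numeric(fixed)) == 0 || stats::sd(as.numeric(moving)) == 0)
    stop("featureless (constant) image")
  if (is.null(scale_grid))
    scale_grid <- sort(unique(c(1, exp(seq(log(0.5), log(10), length.out = 18)))))
  c_f <- geometric_center(dim(fixed)); c_m <- geometric_center(dim(moving))
  score <- function(par) cross_canvas_ncc(fixed, moving,
                                          similarity_inverse_map(par, c_f, c_m))
  coarse <- vapply(scale_grid, function(s) score(c(s, 0, 0, 0)), numeric(1))
  starts <- scale_grid[order(coarse, decreasing = TRUE)[1:3]]
  best <- list(par = c(starts[1], 0, 0, 0), value = max(coarse))
  for (s0 in starts) {
    fit <- stats::optim(c(s0, 0, 0, 0), function(p) -score(p),
                        method = "Nelder-Mead",
                        control = list(maxit = max_eval, reltol = 1e-9,
                                       parscale = c(0.05 * s0, 0.05, 1, 1)))
    if (-fit$value > best$value) best <- list(par = fit$par, value = -fit$value)
  }
  list(params = list(rotation = best$par[2], scale = best$par[1],
                     translation = best$par[3:4]),
       pcc = best$value)
}

affine_inverse_map <- function(A, t, c_fixed, c_moving) {
  Ainv <- solve(A)
  function(p) {
    d <- cbind(p[, 1] - c_fixed[1] - t[1], p[, 2] - c_fixed[2] - t[2])
    cbind(Ainv[1, 1] * d[, 1] + Ainv[1, 2] * d[, 2] + c_moving[1],
          Ainv[2, 1] * d[, 1] + Ainv[2, 2] * d[, 2] + c_moving[2])
  }
}

#' Full affine refinement from a similarity initialisation
#'
#' Frees all six affine degrees of freedom (the scale lock is for synapse
#' channel alignment only — expansion estimation needs the scale) and
#' refines from the similarity solution. The distortion field is the
#' displacement of the affine map relative to the similarity map on a
#' regular grid: the residual, non-uniform part of the gel expansion.
#'
#' @param fixed,moving as in [estimate_similarity()].
#' @param init result of [estimate_similarity()].
#' @param max_eval evaluation budget.
#' @param distortion_step grid spacing (px of the moving image).
#' @return list `params` (unconstrained [affine_params()]), `pcc`,
#'   `distortion` (`distortion_field`).
#' @export
refine_affine_full <- function(fixed, moving, init, max_eval = 600L,
                               distortion_step = 8L) {
  c_f <- geometric_center(dim(fixed)); c_m <- geometric_center(dim(moving))
  s <- init$params$scale
  A0 <- s * rot2(init$params$rotation)
  par0 <- c(as.numeric(A0), init$params$translation)
  score <- function(p) {
    A <- matrix(p[1:4], 2, 2)
    if (abs(det(A)) < 1e-9) return(-Inf)
    cross_canvas_ncc(fixed, moving, affine_inverse_map(A, p[5:6], c_f, c_m))
  }
  fit <- stats::optim(par0, function(p) -score(p), method = "Nelder-Mead",
                      control = list(maxit = max_eval, reltol = 1e-9,
                                     parscale = c(rep(0.02 * s, 4), 1, 1)))
  par <- if (-fit$value >= init$pcc) fit$par else par0
  pcc <- max(-fit$value, init$pcc)
  A <- matrix(par[1:4], 2, 2); t_a <- par[5:6]
  fwd_aff <- function(p) {
    d <- cbind(p[, 1] - c_m[1], p[, 2] - c_m[2])
    cbind(A[1, 1] * d[, 1] + A[1, 2] * d[, 2] + c_f[1] + t_a[1],
          A[2, 1] * d[, 1] + A[2, 2] * d[, 2] + c_f[2] + t_a[2])
  }
  S <- s * rot2(init$params$rotation); t_s <- init$params$translation
  fwd_sim <- function(p) {
    d <- cbind(p[, 1] - c_m[1], p[, 2] - c_m[2])
    cbind(S[1, 1] * d[, 1] + S[1, 2] * d[, 2] + c_f[1] + t_s[1],
          S[2, 1] * d[, 1] + S[2, 2] * d[, 2] + c_f[2] + t_s[2])
  }
  gx <- seq(1, ncol(moving), by = distortion_step)
  gy <- seq(1, nrow(moving), by = distortion_step)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  d <- fwd_aff(pts) - fwd_sim(pts)
  mag <- sqrt(rowSums(d^2))
  params <- decompose_affine(cbind(A, c_f + t_a - A %*% c_m), center = c_m)
  list(params = params, pcc = pcc,
       distortion = structure(list(grid_points = pts, displacement_vectors = d,
                                   summary = c(mean = mean(mag), max = max(mag))),
                              class = "distortion_field"))
}

#' Structural expansion factor from an image pair
#'
#' Registers the pre-expansion onto the post-expansion image with a
#' similarity transform, converts the recovered pixel-space scale to a
#' physical linear expansion factor via the two pixel sizes, then refines
#' with a full affine to quantify residual distortion:
#' `ExF = scale_px * post_pixel_size / pre_pixel_size`.
#'
#' @param pre,post `image2d` objects carrying `pixel_size`.
#' @return an `expansion_estimate`: `factor`, `method = "structural"`,
#'   `pcc_similarity`, `pcc_affine`, `distortion_summary`, `similarity`.
#' @export
expansion_factor_structural <- function(pre, post) {
  sim <- estimate_similarity(post, pre)
  aff <- refine_affine_full(post, pre, sim)
  factor <- sim$params$scale * pixel_size(post) / pixel_size(pre)
  structure(list(factor = factor, method = "structural",
                 pcc_similarity = sim$pcc, pcc_affine = aff$pcc,
                 distortion_summary = aff$distortion$summary,
                 similarity = sim$params, affine = aff$params,
                 distortion = aff$distortion),
            class = "expansion_estimate")
}

#' @export
print.expansion_estimate <- function(x, ...) {
  cat(sprintf("<expansion_estimate %s: factor %.3f", x$method, x$factor))
  if (!is.null(x$pcc_similarity))
    cat(sprintf(", PCC sim %.3f / affine %.3f", x$pcc_similarity, x$pcc_affine))
  cat(">\n")
  invisible(x)
}

#' Write a distortion field as TSV and a quiver-style overlay PNG
#'
#' @param field a `distortion_field`.
#' @param tsv_path output TSV (x, y, dx, dy); NULL to skip.
#' @param png_path output quiver PNG; NULL to skip.
#' @param background optional `image2d` drawn under the arrows.
#' @return invisibly, the summary magnitudes.
#' @export
write_distortion_field <- function(field, tsv_path = NULL, png_path = NULL,
                                   background = NULL) {
  if (!is.null(tsv_path)) {
    df <- data.frame(x = field$grid_points[, 1], y = field$grid_points[, 2],
                     dx = field$displacement_vectors[, 1],
                     dy = field$displacement_vectors[, 2])
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 640, height = 640, type = "cairo")
    on.exit(grDevices::dev.off(), add = TRUE)
    p <- field$grid_points; d <- field$displacement_vectors
    if (!is.null(background)) {
      graphics::image(t(unclass(background))[, rev(seq_len(nrow(background)))],
                      col = grDevices::gray.colors(64, 0, 1), axes = FALSE,
                      x = seq_len(ncol(background)),
                      y = seq_len(nrow(background)), ylim = c(nrow(background), 1))
    } else {
      graphics::plot(NULL, xlim = range(p[, 1]), ylim = rev(range(p[, 2])),
                     xlab = "x [px]", ylab = "y [px]", asp = 1)
    }
    nz <- sqrt(rowSums(d^2)) > 1e-6
    if (any(nz))
      graphics::arrows(p[nz, 1], p[nz, 2], p[nz, 1] + d[nz, 1], p[nz, 2] + d[nz, 2],
                       length = 0.04, col = "red")
  }
  invisible(field$summary)
}
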