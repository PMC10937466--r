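#' Simulation parameters for a synthetic synapse or expansion scene
#'
#' Defaults describe a typical ~8x-expanded synapse imaged by Airyscan:
#' 41.2 nm pixels, a bar of Gaussian nanodomains along the synapse major
#' axis, a post-synaptic bar mirrored across a 318 nm (expanded) cleft, a
#' ~120 nm FWHM optical PSF (sigma ~51 nm), constant camera background and
#' Poisson shot noise. All geometry is specified in nm and converted to
#' pixels only at render time; sub-pixel centers are rendered analytically.
#'
#' @param image_shape integer (H, W) in pixels.
#' @param pixel_size nm per pixel.
#' @param orientation synapse major-axis angle in radians, measured from the
#'   +x (column) axis with y increasing down the rows.
#' @param n_domains number of nanodomains per synaptic side.
#' @param domain_sigma Gaussian width (sigma, nm) of one nanodomain.
#' @param domain_spacing center-to-center spacing (nm) along the axis.
#' @param cleft_offset perpendicular pre-to-post offset (nm); 318 nm is the
#'   expanded cleft distance, ~40 nm at biological scale for an 8x gel.
#' @param lateral_jitter RMS per-axis misregistration (nm) between matched
#'   pre/post nanodomains; 0 gives perfectly formed nanocolumns.
#' @param psf_sigma Gaussian PSF sigma in nm (120 nm FWHM / 2.355 ~ 51 nm).
#' @param background constant offset in counts.
#' @param peak_amplitude peak counts of one nanodomain after PSF blur.
#' @param poisson_noise logical; apply Poisson shot noise.
#' @param seed integer RNG seed; identical spec (incl. seed) gives
#'   bit-identical images.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(image_shape = c(128L, 128L),
                     pixel_size = 41.2,
                     orientation = pi / 6,
                     n_domains = 4L,
                     domain_sigma = 160,
                     domain_spacing = 500,
                     cleft_offset = 318,
                     lateral_jitter = 0,
                     psf_sigma = 51,
                     background = 10,
                     peak_amplitude = 1000,
                     poisson_noise = TRUE,
                     seed = 1L) {
  spec <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
               orientation = orientation, n_domains = as.integer(n_domains),
               domain_sigma = domain_sigma, domain_spacing = domain_spacing,
               cleft_offset = cleft_offset, lateral_jitter = lateral_jitter,
               psf_sigma = psf_sigma, background = background,
               peak_amplitude = peak_amplitude, poisson_noise = poisson_noise,
               seed = as.integer(seed))
  validate_sim_spec(spec)
  structure(spec, class = "sim_spec")
}

validate_sim_spec <- function(spec) {
  with(spec, {
    if (length(image_shape) != 2L || any(image_shape <= 0))
      stop("image_shape must be two positive integers")
    if (pixel_size <= 0) stop("pixel_size must be > 0")
    if (n_domains < 1L) stop("n_domains must be >= 1")
    if (cleft_offset < 0) stop("cleft_offset must be >= 0")
    if (psf_sigma < 0 || domain_sigma <= 0) stop("invalid sigma")
    if (lateral_jitter < 0) stop("lateral_jitter must be >= 0")
  })
  invisible(spec)
}

field_extent_nm <- function(spec) {
  c(x = spec$image_shape[2] * spec$pixel_size,
    y = spec$image_shape[1] * spec$pixel_size)
}

# nm coordinates of pixel centers along one axis (n pixels)
pixel_centers_nm <- function(n, pixel_size) (seq_len(n) - 0.5) * pixel_size

#' Render Gaussian nanodomains into an image
#'
#' Sums isotropic Gaussian blobs evaluated analytically at pixel centers.
#' A Gaussian domain convolved with a Gaussian PSF is again Gaussian with
#' sigma_total^2 = domain_sigma^2 + psf_sigma^2, so the blur is applied in
#' closed form rather than by discrete convolution; amplitudes are the
#' post-blur peak counts. A constant background is added; no noise here.
#'
#' @param centers N x 2 matrix of (x, y) nm positions (may be empty).
#' @param amplitudes peak counts, scalar or length N.
#' @param spec a [sim_spec()].
#' @param domain_sigma override of `spec$domain_sigma` (nm), used for the
#'   wider pan-proteome channel.
#' @return an `image2d` in counts.
#' @export
render_nanodomains <- function(centers, amplitudes, spec,
                               domain_sigma = spec$domain_sigma) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  ext <- field_extent_nm(spec)
  img <- matrix(spec$background, H, W)
  if (nrow(centers) > 0) {
    bad <- centers[, 1] < 0 | centers[, 1] > ext["x"] |
           centers[, 2] < 0 | centers[, 2] > ext["y"]
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("domain center (%.1f, %.1f) nm outside image bounds (%.0f x %.0f nm)",
                   centers[i, 1], centers[i, 2], ext["x"], ext["y"]))
    }
    amplitudes <- rep_len(amplitudes, nrow(centers))
    s2 <- domain_sigma^2 + spec$psf_sigma^2
    xs <- pixel_centers_nm(W, spec$pixel_size)
    ys <- pixel_centers_nm(H, spec$pixel_size)
    for (i in seq_len(nrow(centers))) {
      ex <- exp(-(xs - centers[i, 1])^2 / (2 * s2))
      ey <- exp(-(ys - centers[i, 2])^2 / (2 * s2))
      img <- img + amplitudes[i] * (ey %o% ex)
    }
  }
  image2d(img, spec$pixel_size)
}

rot2 <- function(theta) matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

apply_poisson <- function(img) {
  px <- stats::rpois(length(img), lambda = pmax(unclass(img), 0))
  image2d(matrix(as.numeric(px), nrow(img), ncol(img)), pixel_size(img))
}

#' Simulate a pre/post synapse image pair with known ground truth
#'
#' Builds a bar of `n_domains` nanodomains centered in the field along
#' `spec$orientation` (the pre-synaptic channel), mirrors it across the
#' cleft by `cleft_offset` perpendicular to the axis (the post-synaptic
#' channel), optionally jitters each matched post domain and displaces or
#' rotates the whole post side by `applied_misalignment`. A pan-proteome
#' channel (both sides plus cleft-band density, rendered with a wider
#' kernel) and an optional trans-synaptic channel of mid-cleft blobs are
#' added. Poisson noise is applied per channel when `spec$poisson_noise`.
#'
#' @param spec a [sim_spec()].
#' @param applied_misalignment list with `dx`, `dy` (nm) and `rot`
#'   (radians, about the image center) applied to the post channel; this is
#'   the misregistration the alignment stage should recover.
#' @param trans logical; include the trans-synaptic channel.
#' @return list with `image` (a `multichannel_image` with channels pre,
#'   post, pan and optionally trans) and `truth` (ground-truth list: domain
#'   centers in nm, true orientation, cleft offset and the applied
#'   misalignment).
#' @export
simulate_synapse_pair <- function(spec,
                                  applied_misalignment = list(dx = 0, dy = 0, rot = 0),
                                  trans = TRUE) {
  validate_sim_spec(spec)
  set.seed(spec$seed)
  ext <- field_extent_nm(spec)
  c0 <- unname(c(ext["x"], ext["y"])) / 2
  u <- c(cos(spec$orientation), sin(spec$orientation))
  v <- c(-sin(spec$orientation), cos(spec$orientation))

  offs <- (seq_len(spec$n_domains) - (spec$n_domains + 1) / 2) * spec$domain_spacing
  pre <- t(vapply(offs, function(o) c0 + o * u, numeric(2)))
  jit <- if (spec$lateral_jitter > 0)
    matrix(stats::rnorm(2 * spec$n_domains, sd = spec$lateral_jitter), ncol = 2)
  else matrix(0, spec$n_domains, 2)
  post <- sweep(pre, 2, spec$cleft_offset * v, "+") + jit

  mis <- applied_misalignment
  if (mis$rot != 0)
    post <- t(rot2(mis$rot) %*% (t(post) - c0) + c0)
  post <- sweep(post, 2, c(mis$dx, mis$dy), "+")

  amp <- spec$peak_amplitude
  pre_img <- render_nanodomains(pre, amp, spec)
  post_img <- render_nanodomains(post, amp, spec)

  # pan-proteome context: both sides with a 2x wider kernel plus extra
  # density in the cleft band (midpoints between matched domains)
  mid <- (pre + post) / 2
  pan_img <- render_nanodomains(rbind(pre, post, mid),
                                c(rep(0.5 * amp, 2 * spec$n_domains),
                                  rep(0.35 * amp, spec$n_domains)),
                                spec, domain_sigma = 2 * spec$domain_sigma)

  chans <- list(pre = pre_img, post = post_img, pan = pan_img)
  if (trans)
    chans$trans <- render_nanodomains(mid, 0.8 * amp, spec,
                                      domain_sigma = 0.75 * spec$domain_sigma)
  if (spec$poisson_noise) chans <- lapply(chans, apply_poisson)

  truth <- list(pre_domain_centers = pre, post_domain_centers = post,
                true_orientation = spec$orientation,
                true_cleft_offset = spec$cleft_offset,
                applied_misalignment = mis)
  list(image = multichannel_image(chans, spec$pixel_size), truth = truth)
}

#' Smooth random displacement field
#'
#' A coarse grid of iid Gaussian control vectors over the given extent,
#' bilinearly interpolated, then rescaled so the RMS vector magnitude over
#' a dense sampling of the field equals `amplitude` exactly. Models the
#' smooth, low-order distortions of non-isotropic gel expansion.
#'
#' @param extent c(x, y) nm extent of the field.
#' @param amplitude target RMS displacement magnitude in nm; 0 gives the
#'   zero field.
#' @param n_ctrl control points per axis.
#' @return function mapping an N x 2 matrix of (x, y) nm to N x 2
#'   displacements (nm).
#' @export
make_displacement_field <- function(extent, amplitude, n_ctrl = 4L) {
  if (amplitude == 0) return(function(p) matrix(0, nrow(p), 2))
  gx <- seq(0, extent[1], length.out = n_ctrl)
  gy <- seq(0, extent[2], length.out = n_ctrl)
  ctrl <- array(stats::rnorm(2 * n_ctrl^2), dim = c(n_ctrl, n_ctrl, 2))
  interp <- function(p) {
    fx <- pmin(pmax((p[, 1] - gx[1]) / (gx[2] - gx[1]), 0), n_ctrl - 1 - 1e-9)
    fy <- pmin(pmax((p[, 2] - gy[1]) / (gy[2] - gy[1]), 0), n_ctrl - 1 - 1e-9)
    i0 <- floor(fx); j0 <- floor(fy); wx <- fx - i0; wy <- fy - j0
    val <- function(k) {
      g <- ctrl[, , k]
      g[cbind(j0 + 1, i0 + 1)] * (1 - wx) * (1 - wy) +
        g[cbind(j0 + 1, i0 + 2)] * wx * (1 - wy) +
        g[cbind(j0 + 2, i0 + 1)] * (1 - wx) * wy +
        g[cbind(j0 + 2, i0 + 2)] * wx * wy
    }
    cbind(val(1), val(2))
  }
  dense <- as.matrix(expand.grid(x = seq(0, extent[1], length.out = 64),
                                 y = seq(0, extent[2], length.out = 64)))
  d <- interp(dense)
  rms <- sqrt(mean(rowSums(d^2)))
  scale_f <- amplitude / rms
  function(p) interp(matrix(as.numeric(p), ncol = 2)) * scale_f
}

#' Simulate a pre/post-expansion image pair
#'
#' Scatters point-like structures (e.g. neurofilament puncta) over the
#' pre-expansion field, then re-renders the same scene with all nm
#' coordinates multiplied by `scale` plus a smooth random displacement
#' field of RMS `distortion_amplitude`, emulating near-isotropic gel
#' expansion. Structure sizes expand with the gel while the PSF does not.
#'
#' @param spec a [sim_spec()] describing the pre-expansion image.
#' @param scale linear expansion factor (>= 1; < 1 is an error).
#' @param distortion_amplitude RMS displacement (nm, post-expansion frame).
#' @param n_points number of puncta in the scene.
#' @param post_pixel_size nm/px of the post image; defaults to
#'   `spec$pixel_size * scale` so both rasters have the same pixel grid.
#' @param post_shape (H, W) of the post image; defaults to cover the scaled
#'   scene at `post_pixel_size`.
#' @return list `pre` (`image2d`), `post` (`image2d`), `truth` (centers in
#'   nm for both frames, `true_scale`, the displacement RMS used).
#' @export
simulate_expansion_pair <- function(spec, scale, distortion_amplitude = 0,
                                    n_points = 50L, post_pixel_size = NULL,
                                    post_shape = NULL) {
  validate_sim_spec(spec)
  if (scale < 1) stop("expansion scale must be >= 1")
  set.seed(spec$seed)
  ext <- field_extent_nm(spec)
  centers <- cbind(stats::runif(n_points, 0.1 * ext["x"], 0.9 * ext["x"]),
                   stats::runif(n_points, 0.1 * ext["y"], 0.9 * ext["y"]))
  amps <- spec$peak_amplitude * stats::runif(n_points, 0.5, 1)
  pre_img <- render_nanodomains(centers, amps, spec)
  if (spec$poisson_noise) pre_img <- apply_poisson(pre_img)

  if (is.null(post_pixel_size)) post_pixel_size <- spec$pixel_size * scale
  if (is.null(post_shape))
    post_shape <- as.integer(round(spec$image_shape * scale * spec$pixel_size /
                                     post_pixel_size))
  post_centers <- centers * scale
  field <- make_displacement_field(ext * scale, distortion_amplitude)
  post_centers <- post_centers + field(post_centers)

  post_spec <- spec
  post_spec$image_shape <- post_shape
  post_spec$pixel_size <- post_pixel_size
  post_img <- render_nanodomains(post_centers, amps, post_spec,
                                 domain_sigma = spec$domain_sigma * scale)
  if (spec$poisson_noise) post_img <- apply_poisson(post_img)

  truth <- list(pre_domain_centers = centers, post_domain_centers = post_centers,
                true_scale = scale, distortion_amplitude = distortion_amplitude)
  list(pre = pre_img, post = post_img, truth = truth)
}
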