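#' Intensity image with a physical pixel size
#'
#' The elementary data carrier of the package: a numeric matrix of
#' non-negative intensities (rows = y, columns = x, origin at the top-left
#' pixel) together with the physical pixel pitch in nanometres. Expanded
#' Airyscan data are typically sampled at 41.2 nm/px and non-expanded
#' confocal data at 99 nm/px.
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param pixel_size physical pixel size in nm/px (scalar, > 0).
#' @return An object of class `image2d`: the matrix with a `pixel_size`
#'   attribute.
#' @export
image2d <- function(pixels, pixel_size) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!all(is.finite(pixels))) stop("image contains non-finite values")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (nm/px)")
  structure(pixels, pixel_size = as.numeric(pixel_size), class = c("image2d", "matrix"))
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d %d x %d px, %.4g nm/px, range [%.4g, %.4g]>\n",
              nrow(x), ncol(x), pixel_size(x), min(x), max(x)))
  invisible(x)
}

#' Physical pixel size of an image
#' @param x an `image2d` or `multichannel_image`.
#' @return pixel size in nm/px.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size")
  if (is.null(ps)) stop("object carries no pixel_size attribute")
  ps
}

as_image2d <- function(x, pixel_size = NULL) {
  if (inherits(x, "image2d")) return(x)
  if (is.null(pixel_size)) stop("pixel_size required for a bare matrix")
  image2d(x, pixel_size)
}

#' Multi-channel image container
#'
#' A named list of equally sized channel matrices sharing one pixel size.
#' Conventional channel names are `pre` (pre-synaptic marker), `post`
#' (post-synaptic marker), `pan` (pan-proteome NHS density) and `trans`
#' (trans-synaptic protein, e.g. LGI1).
#'
#' @param channels named list of numeric matrices with identical dimensions.
#' @param pixel_size nm/px shared by all channels.
#' @return `multichannel_image` object.
#' @export
multichannel_image <- function(channels, pixel_size) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named list")
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channels must share the same dimensions")
  channels <- lapply(channels, function(ch) image2d(unclass(ch), pixel_size))
  structure(channels, pixel_size = as.numeric(pixel_size),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  cat(sprintf("<multichannel_image [%s] %d x %d px, %.4g nm/px>\n",
              paste(names(x), collapse = ", "),
              nrow(x[[1]]), ncol(x[[1]]), pixel_size(x)))
  invisible(x)
}

#' Write a multi-channel image to TIFF with a JSON sidecar
#'
#' One 16-bit TIFF page per channel. Because baseline TIFF stores
#' normalised integers, intensities are rescaled to the joint maximum and
#' the scale factor, channel names and pixel size are recorded in a JSON
#' sidecar with the same basename (`<path>.json`), from which
#' [read_multichannel_tiff()] restores the original counts.
#'
#' @param img a `multichannel_image`.
#' @param path output TIFF path.
#' @param extra optional named list merged into the sidecar (e.g. ground
#'   truth from the simulator).
#' @return `path`, invisibly.
#' @export
write_multichannel_tiff <- function(img, path, extra = NULL) {
  stopifnot(inherits(img, "multichannel_image"))
  hi <- max(vapply(img, max, numeric(1)), 1e-12)
  pages <- lapply(img, function(ch) unclass(ch) / hi)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(channels = names(img), pixel_size_nm = pixel_size(img),
               intensity_scale = hi)
  if (!is.null(extra)) meta <- c(meta, extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a multi-channel TIFF written by [write_multichannel_tiff()]
#'
#' @param path TIFF path; the `<path>.json` sidecar must exist.
#' @return a `multichannel_image`; the sidecar metadata (including any
#'   ground truth) is attached as attribute `meta`.
#' @export
read_multichannel_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(meta$channels))
    stop("TIFF page count does not match sidecar channel list")
  chans <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # grey pages only
    p * meta$intensity_scale
  })
  names(chans) <- meta$channels
  out <- multichannel_image(chans, meta$pixel_size_nm)
  attr(out, "meta") <- meta
  out
}

# Half-open bounding box helpers: c(row_min, col_min, row_max, col_max),
# rows/cols 1-based, the max edge is exclusive.
clip_bbox <- function(bbox, shape) {
  c(max(1L, bbox[1]), max(1L, bbox[2]),
    min(shape[1] + 1L, bbox[3]), min(shape[2] + 1L, bbox[4]))
}

bbox_union <- function(a, b) {
  c(min(a[1], b[1]), min(a[2], b[2]), max(a[3], b[3]), max(a[4], b[4]))
}
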