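#' Pipeline configuration
#'
#' Collects the tunable parameters of the per-synapse analysis. Defaults
#' follow the published selection rule (300 px minimum area, axis ratio of
#' at least 2) and the expanded Airyscan pixel pitch of 41.2 nm.
#'
#' @param channels named character vector mapping roles to channel names in
#'   the input images, e.g. `c(pre = "pre", post = "post", trans = "trans")`.
#' @param pixel_size nm/px, used when inputs are bare matrices.
#' @param min_area_px minimum region area (default 300).
#' @param min_axis_ratio minimum major/minor axis ratio (default 2).
#' @param cosine_threshold consistency cut on the orientation-shift cosine.
#' @param require_both accept a synapse only when both the pre and post
#'   channel pass the selection rule (otherwise the post channel decides).
#' @param roi_margin px added around the union bounding box before
#'   alignment.
#' @param max_eval optimiser budget per registration stage.
#' @param seed RNG seed recorded for provenance.
#' @param out_dir output directory for QC plots, overlays, distortion maps
#'   and data.txt; NULL disables file output.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(channels = c(pre = "pre", post = "post",
                                         pan = "pan", trans = "trans"),
                            pixel_size = 41.2,
                            min_area_px = 300,
                            min_axis_ratio = 2,
                            cosine_threshold = 0.3,
                            require_both = TRUE,
                            roi_margin = 10L,
                            max_eval = 500L,
                            seed = 1L,
                            out_dir = NULL) {
  if (anyDuplicated(channels)) stop("channel names must be distinct")
  structure(list(channels = channels, pixel_size = pixel_size,
                 min_area_px = min_area_px, min_axis_ratio = min_axis_ratio,
                 cosine_threshold = cosine_threshold,
                 require_both = require_both, roi_margin = as.integer(roi_margin),
                 max_eval = as.integer(max_eval), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

resolve_input <- function(x) {
  if (is.character(x)) read_multichannel_tiff(x) else x
}

input_name <- function(x, i) {
  if (is.character(x)) basename(x) else sprintf("image_%03d", i)
}

segment_channel <- function(img, config, name, qc_path = NULL) {
  thr <- otsu_threshold(img)
  regions <- label_and_sort(img, thr)
  select_synapse(regions, min_area = config$min_area_px,
                 min_axis_ratio = config$min_axis_ratio,
                 channel_name = name, qc_path = qc_path)
}

empty_record <- function(filename, config) {
  data.frame(filename = filename, pcc = NA_real_,
             channel_pre = unname(config$channels["pre"]),
             channel_post = unname(config$channels["post"]),
             pcc_before = NA_real_, shift_dx = NA_real_, shift_dy = NA_real_,
             orientation_dot = NA_real_, accepted = FALSE,
             stage = "discarded", note = "", stringsAsFactors = FALSE)
}

# Overlay PNG: fixed (post) in magenta, aligned moving (pre) in green.
write_overlay <- function(fixed, moving_aligned, path) {
  norm01 <- function(m) { m <- unclass(m); r <- range(m); if (diff(r) == 0) m * 0 else (m - r[1]) / diff(r) }
  f <- norm01(fixed); g <- norm01(moving_aligned)
  rgb <- array(0, dim = c(nrow(f), ncol(f), 3))
  rgb[, , 1] <- f; rgb[, , 3] <- f   # magenta
  rgb[, , 2] <- g                    # green
  png::writePNG(rgb, path)
  invisible(path)
}

#' Run the nanocolumn alignment pipeline
#'
#' Per input image: segment the pre and post channels (Otsu threshold,
#' connected components, the area/elongation selection rule with the
#' top-3-merge fallback), align the pre channel onto the post channel with
#' the scale-locked affine transform inside the synapse ROI, compute the
#' Pearson correlation before and after alignment and the
#' orientation-shift cosine, and — when `config$out_dir` is set — write QC
#' plots, an aligned overlay, the distortion map and a tab-separated
#' `data.txt` with one row per input (discards included, with a reason).
#'
#' @param inputs list of `multichannel_image` objects or TIFF paths.
#' @param config a [pipeline_config()].
#' @return invisible list `records` (the data.txt data frame) and
#'   `results` (per-image detail: candidates and `alignment_result`).
#' @export
run_align_pipeline <- function(inputs, config = pipeline_config()) {
  if (length(inputs) == 0L) stop("empty input set")
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- list(); details <- list()
  for (i in seq_along(inputs)) {
    fname <- input_name(inputs[[i]], i)
    rec <- empty_record(fname, config)
    detail <- list()
    res <- try({
      img <- resolve_input(inputs[[i]])
      pre <- img[[config$channels[["pre"]]]]
      post <- img[[config$channels[["post"]]]]
      if (is.null(pre) || is.null(post)) stop("configured channels missing")
      qc <- function(role) if (is.null(out_dir)) NULL else
        file.path(out_dir, sprintf("%s_qc_%s.png", tools::file_path_sans_ext(fname), role))
      cand_pre <- segment_channel(pre, config, "pre", qc("pre"))
      cand_post <- segment_channel(post, config, "post", qc("post"))
      detail$candidates <- list(pre = cand_pre, post = cand_post)
      ok <- if (config$require_both) cand_pre$accepted && cand_post$accepted
            else cand_post$accepted
      if (!ok) {
        rec$stage <- "discarded"
        rec$note <- paste("selection failed:",
                          if (!cand_post$accepted) cand_post$reason else cand_pre$reason)
      } else {
        roi <- bbox_union(cand_pre$shape$bounding_box, cand_post$shape$bounding_box)
        roi <- roi + c(-config$roi_margin, -config$roi_margin,
                       config$roi_margin, config$roi_margin)
        aln <- estimate_constrained_affine(post, pre, roi = roi,
                                           max_eval = config$max_eval)
        osc <- orientation_shift_cosine(cand_post$shape$orientation,
                                        aln$shift_vector,
                                        threshold = config$cosine_threshold)
        aln$orientation_dot <- osc$value
        detail$alignment <- aln
        rec$pcc <- aln$pcc_after; rec$pcc_before <- aln$pcc_before
        rec$shift_dx <- aln$shift_vector[1]; rec$shift_dy <- aln$shift_vector[2]
        rec$orientation_dot <- osc$value
        rec$accepted <- TRUE
        rec$stage <- cand_post$stage
        if (!is.null(out_dir)) {
          base <- tools::file_path_sans_ext(fname)
          write_overlay(post, apply_transform(pre, aln$transform),
                        file.path(out_dir, paste0(base, "_overlay.png")))
          write_overlay(post, pre,
                        file.path(out_dir, paste0(base, "_before.png")))
          write_distortion_field(aln$distortion,
                                 tsv_path = file.path(out_dir, paste0(base, "_distortion.tsv")))
        }
      }
      NULL
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      rec$note <- paste("error:", conditionMessage(attr(res, "condition")))
    records[[i]] <- rec
    details[[i]] <- detail
  }
  records <- do.call(rbind, records)
  if (!is.null(out_dir)) write_data_txt(records, file.path(out_dir, "data.txt"))
  invisible(list(records = records, results = details))
}

#' Write the per-synapse record table
#'
#' Tab-separated with header; canonical columns `filename`, `pcc`,
#' `channel_pre`, `channel_post` plus extension columns (pcc_before,
#' shift components, orientation cosine, accept decision and stage).
#'
#' @param records data frame from [run_align_pipeline()].
#' @param path output path (conventionally `data.txt`).
#' @return `path`, invisibly.
#' @export
write_data_txt <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the trans-synaptic colocalization pipeline
#'
#' Per input image, computes [coloc_map()] of the trans channel against the
#' post channel and against the pre channel, both anchored on the trans
#' channel (which keeps the synapse orientation stable), then summarises
#' the two PCC groups with 1.5 SD outlier exclusion and compares them
#' (Shapiro-Wilk gated t-test).
#'
#' @param inputs list of `multichannel_image` objects or TIFF paths; each
#'   must contain the configured trans channel.
#' @param config a [pipeline_config()].
#' @return list `records` (per-image PCCs and notes), `summary_post`,
#'   `summary_pre` ([summarize_group()] over usable synapses),
#'   `comparison` ([compare_groups()]).
#' @export
run_coloc_pipeline <- function(inputs, config = pipeline_config()) {
  if (length(inputs) == 0L) stop("empty input set")
  tr_name <- unname(config$channels["trans"])
  if (is.null(tr_name) || is.na(tr_name)) stop("no trans channel configured")
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(inputs), function(i) {
    fname <- input_name(inputs[[i]], i)
    row <- data.frame(filename = fname, pcc_trans_post = NA_real_,
                      pcc_trans_pre = NA_real_, note = "",
                      stringsAsFactors = FALSE)
    res <- try({
      img <- resolve_input(inputs[[i]])
      tr <- img[[tr_name]]
      if (is.null(tr)) stop("trans channel missing from image")
      cm_post <- coloc_map(tr, img[[config$channels[["post"]]]], anchor = "a")
      cm_pre <- coloc_map(tr, img[[config$channels[["pre"]]]], anchor = "a")
      row$pcc_trans_post <- cm_post$pcc
      row$pcc_trans_pre <- cm_pre$pcc
      if (!is.null(out_dir)) {
        base <- tools::file_path_sans_ext(fname)
        png::writePNG(cm_post$map * 1,
                      file.path(out_dir, paste0(base, "_coloc_post.png")))
        png::writePNG(cm_pre$map * 1,
                      file.path(out_dir, paste0(base, "_coloc_pre.png")))
      }
      NULL
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      row$note <- paste("error:", conditionMessage(attr(res, "condition")))
    row
  })
  records <- do.call(rbind, rows)
  usable <- stats::complete.cases(records[, c("pcc_trans_post", "pcc_trans_pre")])
  if (!any(usable))
    stop("no usable synapses: every colocalization computation failed")
  su_post <- summarize_group(records$pcc_trans_post[usable])
  su_pre <- summarize_group(records$pcc_trans_pre[usable])
  cmp <- compare_groups(records$pcc_trans_post[usable],
                        records$pcc_trans_pre[usable])
  if (!is.null(out_dir))
    utils::write.table(records, file.path(out_dir, "coloc.txt"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  list(records = records, summary_post = su_post, summary_pre = su_pre,
       comparison = cmp)
}

#' Expansion-factor report
#'
#' Computes the structural estimate from a pre/post-expansion image pair
#' (similarity registration, affine refinement, distortion map) and/or the
#' macroscopic estimate from gel diameters; at least one input form must be
#' supplied.
#'
#' @param pre,post pre-/post-expansion `image2d` objects (optional).
#' @param pre_diameter,post_diameter gel diameters (optional, same unit).
#' @param out_dir optional directory for the distortion map TSV/PNG.
#' @return list with `structural` and/or `macroscopic`
#'   `expansion_estimate` entries.
#' @export
run_exfactor <- function(pre = NULL, post = NULL,
                         pre_diameter = NULL, post_diameter = NULL,
                         out_dir = NULL) {
  if ((is.null(pre) || is.null(post)) &&
      (is.null(pre_diameter) || is.null(post_diameter)))
    stop("supply an image pair and/or a gel-diameter pair")
  out <- list()
  if (!is.null(pre) && !is.null(post)) {
    out$structural <- expansion_factor_structural(pre, post)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_distortion_field(out$structural$distortion,
                             tsv_path = file.path(out_dir, "expansion_distortion.tsv"),
                             png_path = file.path(out_dir, "expansion_distortion.png"))
    }
  }
  if (!is.null(pre_diameter) && !is.null(post_diameter))
    out$macroscopic <- macroscopic_expansion_factor(pre_diameter, post_diameter)
  out
}
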