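#' Registration parameter-recovery study
#'
#' Simulates seeded synapse pairs with random known misalignments of the
#' post channel (shift magnitude up to `max_shift_px` pixels, rotation up
#' to `max_rot_deg` degrees), runs segmentation and the scale-locked
#' alignment, and measures the translation and rotation errors against the
#' ground-truth transform. For a jitter-free pair the true aligning
#' transform has rotation equal to the applied rotation and translation
#' `R(rot) %*% cleft_vector + shift`.
#'
#' @param n_pairs number of simulated pairs.
#' @param seed base seed; pair i uses `seed + i`.
#' @param max_shift_px,max_rot_deg misalignment ranges.
#' @param config a [pipeline_config()].
#' @return data frame with one row per pair: recovered and true transform
#'   components, `translation_error_px`, `rotation_error_deg`,
#'   `pcc_before`, `pcc_after`, `accepted`.
#' @export
study_recovery <- function(n_pairs = 50L, seed = 1L, max_shift_px = 10,
                           max_rot_deg = 15, config = pipeline_config()) {
  rows <- lapply(seq_len(n_pairs), function(i) {
    set.seed(seed + i)
    spec <- sim_spec(seed = seed + i, lateral_jitter = 0,
                     orientation = stats::runif(1, -pi / 3, pi / 3))
    mag <- stats::runif(1, 0, max_shift_px) * spec$pixel_size
    ang <- stats::runif(1, 0, 2 * pi)
    mis <- list(dx = mag * cos(ang), dy = mag * sin(ang),
                rot = stats::runif(1, -1, 1) * max_rot_deg * pi / 180)
    sim <- simulate_synapse_pair(spec, applied_misalignment = mis, trans = FALSE)
    out <- run_align_pipeline(list(sim$image), config)
    rec <- out$records
    v <- c(-sin(spec$orientation), cos(spec$orientation)) * spec$cleft_offset
    t_true <- (as.numeric(rot2(mis$rot) %*% v) + c(mis$dx, mis$dy)) / spec$pixel_size
    rot_rec <- if (rec$accepted) out$results[[1]]$alignment$transform$rotation else NA
    data.frame(pair = i, accepted = rec$accepted,
               shift_dx = rec$shift_dx, shift_dy = rec$shift_dy,
               rot_rec = rot_rec, true_dx = t_true[1], true_dy = t_true[2],
               true_rot = mis$rot,
               translation_error_px = sqrt(sum((c(rec$shift_dx, rec$shift_dy) - t_true)^2)),
               rotation_error_deg = abs(rot_rec - mis$rot) * 180 / pi,
               pcc_before = rec$pcc_before, pcc_after = rec$pcc)
  })
  do.call(rbind, rows)
}

#' Expansion-scale recovery study
#'
#' Simulates a pre/post-expansion pair at a known linear scale, with an
#' optional smooth distortion field, and recovers the structural expansion
#' factor by similarity + affine registration.
#'
#' @param scale true linear expansion factor.
#' @param distortion_amplitude RMS distortion in nm (post-expansion frame).
#' @param seed RNG seed.
#' @param n_points puncta in the scene.
#' @return the `expansion_estimate` with the true scale attached as
#'   attribute `true_scale`.
#' @export
study_expansion_recovery <- function(scale = 8, distortion_amplitude = 0,
                                     seed = 1L, n_points = 50L) {
  spec <- sim_spec(image_shape = c(96L, 96L), pixel_size = 99,
                   domain_sigma = 120, seed = seed)
  pair <- simulate_expansion_pair(spec, scale = scale,
                                  distortion_amplitude = distortion_amplitude,
                                  n_points = n_points)
  est <- expansion_factor_structural(pair$pre, pair$post)
  attr(est, "true_scale") <- scale
  est
}

#' Nanocolumn disassembly study: aligned PCC versus nanodomain jitter
#'
#' Runs the full pipeline over batches of simulated synapses at increasing
#' lateral jitter between matched pre/post nanodomains. As jitter destroys
#' the columnar correspondence, the aligned Pearson correlation must fall:
#' the study reports the per-synapse PCCs and the Spearman correlation of
#' PCC against jitter level.
#'
#' @param jitter_levels nm RMS jitter values.
#' @param n_per_level synapses per level.
#' @param seed base seed.
#' @param config a [pipeline_config()].
#' @return list `table` (jitter, pcc per accepted synapse), `rho`
#'   (Spearman), `level_means`.
#' @export
study_jitter_monotonicity <- function(jitter_levels = c(0, 100, 200, 300, 400),
                                      n_per_level = 20L, seed = 1L,
                                      config = pipeline_config()) {
  rows <- list()
  for (j in seq_along(jitter_levels)) {
    for (i in seq_len(n_per_level)) {
      s <- seed + 1000L * j + i
      set.seed(s)
      spec <- sim_spec(seed = s, lateral_jitter = jitter_levels[j],
                       orientation = stats::runif(1, -pi / 3, pi / 3))
      mis <- list(dx = stats::runif(1, -80, 80), dy = stats::runif(1, -80, 80),
                  rot = stats::runif(1, -0.05, 0.05))
      sim <- simulate_synapse_pair(spec, applied_misalignment = mis, trans = FALSE)
      rec <- run_align_pipeline(list(sim$image), config)$records
      if (rec$accepted)
        rows[[length(rows) + 1L]] <- data.frame(jitter = jitter_levels[j],
                                                pcc = rec$pcc)
    }
  }
  tab <- do.call(rbind, rows)
  rho <- stats::cor(tab$jitter, tab$pcc, method = "spearman")
  list(table = tab, rho = rho,
       level_means = tapply(tab$pcc, tab$jitter, mean))
}

#' Trans-synaptic colocalization asymmetry study
#'
#' The simulated trans channel sits mid-cleft between the pre and post
#' bars. Per synapse the study compares its colocalization PCC with the
#' post channel against the PCC with a displaced pre-like channel rendered
#' one full cleft farther away, and applies a one-sided sign test for the
#' trans channel colocalizing more strongly with the nearer structure.
#'
#' @param n_synapses number of simulated synapses.
#' @param seed base seed.
#' @return list `table` (per-synapse PCC pairs), `n_wins`, `p_value`
#'   (binomial sign test), `summary_near`, `summary_far`.
#' @export
study_coloc_asymmetry <- function(n_synapses = 25L, seed = 1L) {
  rows <- lapply(seq_len(n_synapses), function(i) {
    s <- seed + i
    set.seed(s)
    spec <- sim_spec(seed = s, orientation = stats::runif(1, -pi / 3, pi / 3))
    sim <- simulate_synapse_pair(spec, trans = TRUE)
    v <- c(-sin(spec$orientation), cos(spec$orientation)) * spec$cleft_offset
    far_pre <- render_nanodomains(sweep(sim$truth$pre_domain_centers, 2, v, "-"),
                                  spec$peak_amplitude, spec)
    if (spec$poisson_noise) far_pre <- apply_poisson(far_pre)
    data.frame(synapse = i,
               pcc_near = coloc_map(sim$image$trans, sim$image$post, anchor = "a")$pcc,
               pcc_far = coloc_map(sim$image$trans, far_pre, anchor = "a")$pcc)
  })
  tab <- do.call(rbind, rows)
  ok <- stats::complete.cases(tab[, c("pcc_near", "pcc_far")])
  wins <- sum(tab$pcc_near[ok] > tab$pcc_far[ok])
  bt <- stats::binom.test(wins, sum(ok), alternative = "greater")
  list(table = tab, n_wins = wins, n = sum(ok), p_value = bt$p.value,
       summary_near = summarize_group(tab$pcc_near[ok]),
       summary_far = summarize_group(tab$pcc_far[ok]))
}

#' Power check of the two-group comparison at published group moments
#'
#' Draws normal samples at the reported group means, SDs and sizes of the
#' two nanocolumn PCC groups (0.51 +/- 0.15 with n = 42 versus
#' 0.67 +/- 0.11 with n = 49) and counts how often the gated t-test
#' reaches p < `p_cut` over `n_rep` replicates.
#'
#' @param n_rep replicates.
#' @param seed RNG seed.
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group moments.
#' @param p_cut significance level counted as success.
#' @return list `fraction` (replicates with p < p_cut), `n_rep`, `p_values`.
#' @export
study_power_check <- function(n_rep = 200L, seed = 1L,
                              mean_a = 0.51, sd_a = 0.15, n_a = 42L,
                              mean_b = 0.67, sd_b = 0.11, n_b = 49L,
                              p_cut = 0.001) {
  set.seed(seed)
  p_values <- vapply(seq_len(n_rep), function(i) {
    a <- stats::rnorm(n_a, mean_a, sd_a)
    b <- stats::rnorm(n_b, mean_b, sd_b)
    compare_groups(a, b)$p_value
  }, numeric(1))
  list(fraction = mean(p_values < p_cut), n_rep = n_rep, p_values = p_values)
}
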