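#!/usr/bin/env Rscript
# Simulate the study inputs: a batch of four-channel synapse images
# (pre / post / pan / trans) with known ground truth, plus one
# pre/post-expansion image pair. Writes TIFFs with JSON sidecars under
# results/sim/.

library(nanocolumn)

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
n_synapses <- 30L
base_seed <- 1L

cat("Simulating", n_synapses, "synapses at 41.2 nm/px, cleft 318 nm ...\n")
for (i in seq_len(n_synapses)) {
  set.seed(base_seed + i)
  spec <- sim_spec(seed = base_seed + i,
                   orientation = runif(1, -pi / 3, pi / 3))
  mis <- list(dx = runif(1, -150, 150), dy = runif(1, -150, 150),
              rot = runif(1, -0.05, 0.05))
  sim <- simulate_synapse_pair(spec, applied_misalignment = mis)
  write_multichannel_tiff(sim$image,
                          file.path(out_dir, sprintf("synapse_%03d.tif", i)),
                          extra = list(truth = sim$truth))
}

cat("Simulating an 8x expansion pair (99 nm/px pre-expansion) ...\n")
spec <- sim_spec(image_shape = c(96L, 96L), pixel_size = 99,
                 domain_sigma = 120, seed = base_seed)
pair <- simulate_expansion_pair(spec, scale = 8, distortion_amplitude = 100,
                                n_points = 50)
write_multichannel_tiff(multichannel_image(list(pre = pair$pre), pixel_size(pair$pre)),
                        file.path(out_dir, "expansion_pre.tif"),
                        extra = list(truth = pair$truth["true_scale"]))
write_multichannel_tiff(multichannel_image(list(post = pair$post), pixel_size(pair$post)),
                        file.path(out_dir, "expansion_post.tif"))

cat("Wrote", n_synapses, "synapse images and one expansion pair to", out_dir, "\n")
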