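#!/usr/bin/env Rscript
# Simulation studies behind the statistical claims: registration
# parameter recovery, aligned-PCC decay with nanodomain jitter, and the
# power of the gated t-test at the published group moments. Writes
# results/stats/.

library(nanocolumn)

dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)

rec <- study_recovery(n_pairs = 50L, seed = 1L)
cat(sprintf("Recovery over %d pairs: median translation error %.3f px, median rotation error %.3f deg\n",
            nrow(rec), median(rec$translation_error_px, na.rm = TRUE),
            median(rec$rotation_error_deg, na.rm = TRUE)))
write.table(rec, "results/stats/recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

jm <- study_jitter_monotonicity(seed = 1L)
cat("Aligned PCC by jitter level (nm):\n")
print(round(jm$level_means, 3))
cat(sprintf("Spearman rho(jitter, PCC) = %.3f over %d accepted synapses\n",
            jm$rho, nrow(jm$table)))
write.table(jm$table, "results/stats/jitter_pcc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pw <- study_power_check(n_rep = 200L, seed = 1L)
cat(sprintf("Power check at published moments (0.51+/-0.15 n=42 vs 0.67+/-0.11 n=49): %.1f%% of %d replicates reach p < 0.001\n",
            100 * pw$fraction, pw$n_rep))
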