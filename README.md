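# nanocolumn

Quantification of trans-synaptic nanocolumn alignment in expansion
microscopy images.

Chemical synapses organise their release machinery and receptor fields
into *trans-synaptic nanocolumns*: presynaptic active-zone proteins (RIM,
Munc13-1, Bassoon) sit in nanodomains that align, across the synaptic
cleft, with postsynaptic scaffold and receptor clusters (PSD95, Homer1,
GluA1). In ~8×-expanded specimens imaged with Airyscan microscopy
(expanded pixel pitch ≈ 41.2 nm), this alignment becomes measurable with
ordinary image statistics. `nanocolumn` implements the full analysis as a
tested R package:

- **Segmentation** — Otsu thresholding (256-bin between-class-variance
  maximisation), 8-connected component labelling, and moment-derived
  region shapes (orientation θ = ½·atan2(2µ₁₁, µ₂₀ − µ₀₂), axis lengths
  4√λ of the second-central-moment ellipse). A synapse qualifies when its
  largest cluster has area ≥ 300 px and major/minor axis ratio ≥ 2; if it
  fails, the union of the three largest clusters is re-tested, otherwise
  the synapse is discarded (QC plots are always written).
- **Alignment** — a scale-locked affine transform (translation, rotation,
  shear about the geometric image centre; scale fixed at 1) maps the
  pre- onto the post-synaptic channel, optimised in stages
  (translation → rotation → shear) on the Pearson correlation inside the
  synapse ROI. The result records the PCC before and after alignment, the
  shift vector, and the cosine between the synapse major axis and the
  shift — a value near 0 means the signal moved straight across the
  cleft, as a nanocolumn should.
- **Colocalization** — per-channel Otsu masks are intersected into a
  coloc map and a PCC is computed over the ROI anchored on the
  trans-synaptic channel (e.g. LGI1), with no alignment applied.
- **Expansion factor** — macroscopic (gel-diameter ratio) and structural
  (similarity registration of pre-/post-expansion images, refined by a
  full affine whose residual displacement field is the distortion map):
  ExF = s_px · (post px size / pre px size).
- **Group statistics** — per-synapse PCC summaries with single-pass
  1.5 SD outlier exclusion, and Shapiro–Wilk-gated two-sample t-tests
  (rank-sum fallback, flagged).
- **Synthetic data** — a generator of synapse image pairs (Gaussian
  nanodomain bars, mirrored across a 318 nm expanded cleft, ~120 nm FWHM
  PSF, Poisson noise) and expansion pairs with smooth random distortion,
  all with exact ground truth, so every stage is testable without
  microscopy data.

## Worked example

```r
library(nanocolumn)

spec <- sim_spec(seed = 3, poisson_noise = FALSE)     # 128x128 px @ 41.2 nm
sim  <- simulate_synapse_pair(spec,
          applied_misalignment = list(dx = 120, dy = -80, rot = 0.05))

thr  <- otsu_threshold(sim$image$post)
cand <- select_synapse(label_and_sort(sim$image$post, thr))
cand$accepted                        # TRUE (stage "primary_region")
cand$shape$orientation               # 0.575 rad (axis + applied 0.05 rotation)

aln <- estimate_constrained_affine(sim$image$post, sim$image$pre,
                                   roi = cand$shape$bounding_box + c(-10, -10, 10, 10))
round(c(aln$pcc_before, aln$pcc_after), 3)   # 0.650  1.000
round(aln$shift_vector, 2)                   # -1.28  4.54  (px)
round(aln$transform$rotation, 3)             # 0.050  (the applied rotation)
```

The recovered shift is the cleft vector plus the applied misalignment,
and the aligned PCC rises to ~1 because the two bars are perfectly
columnar in this simulation. Running the workflow scripts
(`analysis/01_simulate.R` … `05_group_statistics.R`) over 30 simulated
synapses prints, among others:

```
Aligned PCC: mean 0.998 +/- 0.000, median 0.998 [0.998, 0.998] (29/30 after 1.5 SD exclusion)
Structural ExF: 8.000 (similarity PCC 0.992, affine PCC 0.992, residual distortion mean 0.03 px)
Macroscopic ExF from gel diameters 12 mm -> 100 mm: 8.3
Cleft distance: 318 nm expanded -> 39.75 nm biological at 8x (~40 nm)
Aligned PCC by jitter level (nm):   0 0.998 | 100 0.902 | 200 0.804 | 300 0.697 | 400 0.668
```

i.e. the aligned correlation degrades monotonically as the simulated
nanocolumns are disassembled by lateral jitter.

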