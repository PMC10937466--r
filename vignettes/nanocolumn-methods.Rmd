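---
title: "Methods: quantifying trans-synaptic nanocolumn alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying trans-synaptic nanocolumn alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanocolumn)
```

## The measurement problem

In ~8×-expanded neuronal specimens imaged at super-resolution, pre- and
post-synaptic proteins appear as bars of discrete nanodomains facing each
other across the synaptic cleft (~318 nm in the expanded frame, ~40 nm
biological at 8×). The question the pipeline answers per synapse is: *how
well do the two sides correspond, nanodomain for nanodomain?* The
operational definition used throughout is the Pearson correlation
coefficient (PCC) of the two channels over the synaptic region after an
alignment that is allowed to translate, rotate and shear — but not to
scale — the pre-synaptic channel onto the post-synaptic one. Scale is
locked because a scale degree of freedom could "cheat" by shrinking one
channel onto the other; translation is the physically expected motion (a
shift across the cleft), so it is optimised first and most freely.

## Segmentation and the selection rule

Each channel is binarised at its Otsu threshold: the intensity that
maximises the between-class variance, searched over 256 histogram bins
spanning the intensity range (for integer images with ≤ 256 distinct
levels the native levels are the candidates, so exact masks are
reproducible). Class statistics are computed from the raw pixel values at
each candidate split, which keeps the implementation exactly equivalent
to an exhaustive search — the property the test suite asserts on random
images.

Connected components (8-connectivity by default; 4 is available because
the convention is a genuine choice) are sorted by area and described by
the normalised-second-central-moment ellipse: orientation
θ = ½·atan2(2µ₁₁, µ₂₀ − µ₀₂) in (−π/2, π/2] measured from the +x (column)
axis with y running down the rows, axis lengths 4√λ of the covariance
eigenvalues. This convention is stated explicitly because the 300 px /
ratio-2 thresholds below are only reproducible relative to it.

A synapse is **accepted** when its largest region has area ≥ 300 px *and*
axis ratio ≥ 2; when the largest region fails, the union of the three
largest regions is re-tested with the same moment formulas; when that
also fails the synapse is discarded. The rule is deliberately read as a
failure condition with a merge-and-retest fallback — the only reading
under which the fallback does anything. "Connecting" the three clusters
is implemented as a plain pixel-set union (no morphological bridging):
the moments of the union are what the ellipse test needs, and bridging
would add an arbitrary structuring-element parameter. A QC plot is
written for every decision so a scientist can audit it, mirroring how
such selections are verified by hand in practice. Both the pre and the
post channel must pass for the synapse to be analysed (configurable);
requiring both is the conservative choice since the alignment uses both.

## Constrained affine alignment

The transform is parameterised as rotation R(θ), shear S = [[1, s], [0, 1]]
and translation t about the geometric image centre, with both scales
locked to exactly 1 — a hard lock rather than a soft penalty, since a
disabled degree of freedom should not be reachable at any cost. The
objective is the Pearson correlation of the fixed (post) channel and the
pulled-back moving (pre) channel inside the ROI (the union of both
accepted bounding boxes plus a 10 px margin), under bilinear
interpolation with zero fill.

"Translation is the most adjustable parameter" is realised structurally:
a coarse translation grid (±25 % of the image size) seeds Nelder–Mead
refinement of translation alone, then translation + rotation, then
translation + rotation + shear, with per-parameter scaling (1 px ≈ 0.05
rad steps). The identity is always among the evaluated candidates and the
best iterate is kept, so `pcc_after ≥ pcc_before` holds by construction —
an invariant the tests check on noisy, jittered inputs. Optimiser
tolerances: relative 1e−8 on the correlation, 500 evaluations per stage
(configurable); non-convergence is flagged and the best iterate returned.

The per-synapse outputs are the PCC before/after, the shift vector (the
translation component), the distortion field T(p) − p on an 8 px grid,
and the orientation–shift cosine: the cosine between the unit major-axis
vector and the unit shift vector. The cosine (rather than a raw dot
product) makes the "close to zero means trans-synaptic" criterion
scale-free; |cos| < 0.3 is the default consistency flag, a deliberately
loose cut since no published number exists, and the raw-dot mode remains
available.

## Expansion factors

The macroscopic factor is the gel-diameter ratio. The structural factor
registers the pre-expansion image onto the post-expansion image with a
4-DOF similarity transform (coarse geometric scale grid, 0.5–10, then
Nelder–Mead refinement of scale, rotation and translation on the
overlapping-area PCC), then frees all six affine degrees of freedom. The
physical factor is `scale_px · post_pixel_size / pre_pixel_size`, so
images acquired at different pixel pitches (99 nm non-expanded vs 41.2 nm
expanded Airyscan) are handled by construction — a unit-handling case the
tests exercise. The displacement of the affine map relative to the
similarity map on a regular grid is the distortion map: the residual,
non-uniform part of the expansion. On undistorted synthetic pairs the
affine refinement adds almost nothing (< 0.01 PCC, mean residual
< 0.5 px), which is itself a test.

## Group statistics

Per-synapse PCCs are summarised after a **single-pass** exclusion of
values deviating more than 1.5 SD from the full-sample mean (no
iteration — an iterated rule would need a stopping criterion nobody
specified), with quartiles by linear interpolation. Significance uses a
Shapiro–Wilk gate (α = 0.05) in front of a pooled-variance two-sample
t-test; if either group looks non-normal the result is flagged and a
Wilcoxon rank-sum test is reported instead — the fallback is an extension
beyond the t-test-only convention and is always labelled in the output.
Tests are applied to the post-exclusion samples and both sample sizes are
recorded.

## The synthetic-data generator

The generator is the package's stand-in for microscopy data, and its
defaults are the study conditions, chosen once:

| parameter | default | why |
|---|---|---|
| image | 128×128 px @ 41.2 nm | expanded Airyscan pixel pitch; ~5.3 µm field |
| nanodomains | 4 per side, σ = 160 nm, spacing 500 nm | ~20 nm biological domains, discrete but overlapping after blur |
| cleft offset | 318 nm | the expanded cleft distance |
| PSF | σ = 51 nm | 120 nm FWHM optics (FWHM/2.355), not expanded by the gel |
| counts | peak 1000, background 10, Poisson on | high-SNR Airyscan-like statistics |

Pre-synaptic nanodomains sit on a bar through the image centre along the
specified orientation; post-synaptic domains mirror them across the cleft
(perpendicular offset), optionally jittered per domain
(iid N(0, jitter²) per coordinate axis — jitter is RMS per axis) and
displaced/rotated as a whole by a known misalignment. The pan-proteome
channel is both bars plus mid-cleft density rendered with a 2× wider
kernel: it is qualitative context only, since no quantitative pan claim
is made anywhere. The trans channel is mid-cleft blobs. Because a
Gaussian domain blurred by a Gaussian PSF is again Gaussian
(σ² = σ_dom² + σ_psf²), rendering is analytic at pixel centres —
sub-pixel geometry is exact, never a shifted raster. Identical spec and
seed give bit-identical images.

Expansion pairs re-render a random punctum scene at coordinates × scale
plus a smooth displacement field (4×4 grid of Gaussian control vectors,
bilinearly interpolated, rescaled so the field's RMS over the image grid
equals the requested amplitude exactly). Structure sizes expand with the
gel; the PSF does not. A scale of exactly 1 is allowed (it must reproduce
the input identically, a useful degenerate check); scales below 1 are
errors. By default the post image is rendered at
`pre_pixel_size × scale`, keeping both rasters the same size so
registration cost stays flat; the caller can choose any post pixel size.

What the generator does **not** emulate: 3-D structure, vesicle pools,
chromatic aberration, labelling stochasticity, linkage error, background
structure from neighbouring synapses. Passing tests therefore show the
pipeline is correct *given* the forward model, not that real data meet
the model; the acceptance of real images still rests on the QC plots.

## Problem sizes and numerical choices

The simulation studies use 50 pairs for registration recovery
(|t| ≤ 10 px, |θ| ≤ 15°), 5 jitter levels × 20 synapses for the
monotonicity study, 25 synapses for the colocalization asymmetry sign
test, and 200 replicates for the power check at group moments
(0.51 ± 0.15, n = 42 vs 0.67 ± 0.11, n = 49) — sizes chosen so the whole
battery runs in a few minutes on one CPU while keeping the Monte-Carlo
error well below the decision margins. TIFF output is 16-bit with the
intensity scale, channel names and pixel size recorded in a JSON sidecar
(baseline TIFF writers do not round-trip float counts or custom tags);
the sidecar also carries the ground truth for simulated images.

## Known limitations

- Strictly 2-D; z-stacks must be sliced or projected upstream.
- One synapse per field: only the largest candidate (or top-3 union) is
  evaluated.
- The registration objective is correlation, which assumes roughly
  monotone intensity correspondence between channels; mutual information
  is not implemented.
- The colocalization map is Otsu-AND; Manders/Costes coefficients are out
  of scope.
- The similarity multi-start covers scales 0.5–10; factors far outside
  need a custom `scale_grid`.
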