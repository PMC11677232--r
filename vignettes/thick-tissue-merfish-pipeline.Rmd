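---
title: "Decoding thick-tissue 3D MERFISH: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding thick-tissue 3D MERFISH: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

merfish3d turns per-bit confocal z-stacks of a thick tissue section into a
quality-controlled cell-by-gene matrix and nearest-neighbor spatial
statistics. This vignette is the package's own account of the science it
implements: the imaging and decoding model, the parameters that matter and
their defaults, the numerical choices behind each stage, and what the
synthetic benchmarks do and do not establish.

## The measurement model

A MERFISH experiment encodes each gene as a fixed-length binary barcode
read out over sequential hybridization rounds, two color channels per
round (~650 nm and ~560 nm), so bit *b* of a B-bit codebook is one
(round, channel) pair. In thick tissue the readout is acquired as a
z-stack at a 1 µm step, so an RNA molecule is a diffraction-limited 3D
spot present in exactly the ON bits of its gene's barcode. Codebooks also
carry *blank* barcodes — valid codewords assigned to no gene — whose
decoded abundance measures the false-identification rate.

The simulator (`plant_truth()`, `render_stacks()`) renders this model
explicitly: molecules are uniform in the volume with genes uniform over
coding entries, each contributing a separable 3D Gaussian (peak
`brightness` photons) to its ON bits; channel-B bits are shifted along z
by the axial chromatic offset; each round is translated by that round's
stage drift; flat cellular background (optionally plus a wide out-of-focus
blob) is added; Poisson shot noise and Gaussian read noise come last.
Fiducial beads at the coverslip are rendered per round with the same
drift. Blank entries never receive signal, so any decoded blank is by
construction an error — the basis of every calibration test in the suite.

What the simulator deliberately does *not* model: diffraction (the PSF is
Gaussian), tissue scattering and depth-dependent aberration, hybridization
chemistry and probe kinetics, and realistic cell morphology (toy cells are
non-overlapping ellipsoids). Passing tests therefore demonstrate the
*algorithmic* correctness and calibration behaviour of the pipeline, not
instrument-level performance on real tissue.

## Preprocessing

`preprocess_stacks()` runs, in order: drift registration → chromatic
alignment → per-bit median normalization → high-pass → Lucy–Richardson
deconvolution → low-pass.

* **Drift** is modelled as one 2D translation per imaging round, shared by
  all z planes of a FOV, because beads are imaged only at the coverslip.
  `estimate_drift()` uses phase correlation for the integer peak and a
  matrix-DFT evaluation of the *unwhitened* cross-spectrum on a 1/20-pixel
  grid for subpixel refinement — whitening is what makes the integer peak
  sharp, but under noise the matched-filter (unwhitened) surface is the
  more accurate subpixel objective. Ties between equal peaks break toward
  the smallest shift. A weak peak sets a low-confidence flag rather than
  failing, so one bad bead image cannot abort a run.
* **Chromatic z offset** (`calibrate_chromatic_z()`) is the mean over
  detected beads of the difference in background-subtracted axial
  intensity centroids between the channels. Registration applies the
  inverse drift (bilinear) and inverse z offset (linear along z);
  uncovered voxels are zero-filled and masked, and the decoder ignores
  masked pixels, so borders never fabricate signal.
* **Median normalization** divides every stack of a bit by that bit's
  median intensity pooled over FOVs, equalizing rounds and channels. It
  runs *before* the high-pass: the pooled median of a background-subtracted,
  zero-clipped image is ~0, which would make the scale undefined — placing
  normalization first is the only self-consistent ordering, and it also
  fixes the intensity scale on which the decoder's magnitude gate operates.
  The operation is idempotent and records its scale per bit.
* **High-pass** (default σ = 3 px) subtracts a Gaussian blur and clips at
  zero, removing cellular background. **Lucy–Richardson** (default 20
  iterations, PSF = the per-channel Gaussian of the optics) tightens
  spots; the implementation is the standard multiplicative update with
  replicate boundaries and conserves interior flux to better than 1%.
  **Low-pass** (default σ = 1 px) absorbs residual sub-pixel centroid
  motion between rounds. All blurs use truncated-renormalized Gaussian
  operators (dense banded matrices) rather than FFT wrap-around, because
  circular boundaries leak flux and break the deconvolution fixed point at
  image edges. The paper-level operations fix *what* is done; the kernel
  scales are not dictated by the protocol and are exposed as configuration.

## Decoding and filtering

`decode_plane()` forms each pixel's B-vector, gates on magnitude
(`min_intensity`, default 10, on the median-normalized scale — the L2 norm
of the pixel vector is the only scalar intensity defined at this point, and
the gate is a configuration knob for pipelines that normalize differently),
unit-normalizes, and assigns the nearest entry by Euclidean distance among
*all* entries including blanks (`max_distance`, default 0.65). Ties break
to the lowest entry index, deterministically. Aggregation is per z-plane
with 4-connectivity by default; 3D merging is deliberately left to the
separate z-deduplication step (`dedup_across_z()`), which links molecules
of the same barcode in *adjacent* planes within 1.5 px laterally and keeps
one per chain (largest area, then brightest, then lowest z). A z gap of two
or more planes is treated as two molecules — adjacency is the definition of
redundancy here.

`adaptive_filter()` calibrates the list to a target misidentification rate
(default 5%) using the per-entry-normalized blank rate
(N_blank/B_blank)/(N_total/B_total), which is dimensionless and independent
of codebook size. Features are (log₁₀ mean intensity, mean distance, area
capped at its 99th percentile) on a 20×20×10 grid; bins are accepted in
order of ascending blank fraction (empty bins last among zero-fraction
bins, by index, for determinism) while the cumulative rate stays at or
below target. If even the best bin exceeds the target the filter keeps that
single bin and flags the model instead of silently passing. Single-pixel
molecules are removed before the filter, and z-deduplication runs after it,
mirroring the order in which the corrections are defined.

## Cells and the expression matrix

Segmentation is consumed, not produced: label volumes (or the simulator's
toy cells) enter `cell_set_from_labels()`, which records volume
(voxel count × voxel volume, µm³), centroid, z extent and the occupied
voxel set on the global grid. `dedup_cells()` examines each cell's 10
nearest neighbors by centroid, computes pairwise overlap ÷ min(volume) on
the voxel grid, and resolves ratios above 0.40 in descending order by
removing the smaller cell (volume ties keep the lower id) — a deterministic
sweep that is idempotent. The quality filter keeps cells with volume ≥ 100,
total counts ≥ 30 and z extent within 5–40 one-micrometer sections; the
volume threshold is implemented as a plain threshold on the stored volume
value (the printed criterion mixes area and volume units; the stored
quantity here is µm³ and the knob is unitless). Normalization scales each
cell to 10,000 total counts and applies log(1 + x) with a natural log — the
ubiquitous convention for this transform; the base is configurable.

## Spatial statistics

`nn_pairs()` computes, per focal cell, the nearest cell in 3D by centroid
distance (surface-to-surface distance is out of scope) and classifies
to-self vs to-other by subclass label. Whether the candidate set is all
cells or only the focal subclasses is an explicit `neighbor_scope`
parameter, because the two published analyses use both conventions.
`self_other_test()` gates subclasses at ≥ 20 self-self pairs, runs the
one-sided Wilcoxon rank-sum test (exact for small samples without ties via
`stats::wilcox.test`, normal approximation with tie correction otherwise)
and adjusts by Benjamini–Hochberg. `fit_two_gaussians()` is an in-package
EM for a two-component univariate Gaussian mixture: seeded restarts (median
split plus random quantile splits), a variance floor of (10⁻³·sd)² against
degenerate collapse, components ordered by mean, and a recorded
log-likelihood trace that tests assert to be non-decreasing. mclust serves
as an independent cross-check in the test suite, never as the
implementation.

## Restoration (optional, off by default)

The SNR-enhancement stage is a *contract*: paired 128×128 patches from
co-registered low/high-SNR images (default stride 64 — "overlapping" with
no stated stride), an 80/20 seeded split, training under the mean absolute
difference loss with kernel 3 / batch 10 / 50 steps per epoch, one model
per color channel. The network itself is pluggable; the reference model is
a single linear convolution plus bias trained by coordinate-wise exact L1
line search (weighted medians) with epoch-level rollback, which makes the
train-loss history provably non-increasing for this convex model. Two
properties of L1-optimal denoising are worth knowing: on images whose
background is featureless the global optimum is a near-constant predictor
(structured background is what forces input-dependence), and the fitted
affine map rescales absolute intensities, so enhanced stacks should be
compared on direction (barcode distance), not raw magnitude. Decoding is
correct without this stage, which is why it defaults off.

## Problem sizes and reproducibility

All randomness flows from a single seed through named substreams
(`stage_seed()`), making every pipeline rerun byte-identical; artifacts are
plain text or TIFF with a JSON manifest. The package's own benchmark scales
were chosen to keep a full calibration run in minutes on one CPU: the
misidentification benchmark uses a 16-bit, weight-4, minimum-Hamming-
distance-4 codebook with 40 coding + 10 blank entries and ~2,000 molecules
in a 320×320×10 voxel volume at peak SNR 8 (0.167 µm pixels, 1 µm z step);
the recovery benchmark uses ~400 molecules at SNR 12 in 256×256×8. The
barcode length, weight and distance properties of published panels are not
printed in the protocol this models, so the generator's defaults are a
conventional constant-weight, minimum-distance-4 design; the generator is a
seeded greedy search, adequate at these scales but not an optimal code
designer.

## Known limitations

* Pure-R image processing: comfortable at benchmark scales (minutes per
  ~10⁶-voxel FOV), not tuned for full-instrument datasets.
* Drift is translation-only and global per round; rotation, scaling and
  depth-dependent gel deformation are not corrected (the simulator can
  inject a linear-in-z shear to demonstrate sensitivity, but the corrector
  does not model it).
* Lateral chromatic offsets are not fitted (the axial term dominates at a
  1 µm z step); stitching transforms are consumed, never estimated.
* The misidentification rate is a codebook-level calibration, not a
  per-gene FDR; genes with few counts inherit the global rate.
* Toy segmentation means molecule-to-cell assignment is exercised on
  idealized geometry; real segmentation errors (merges, splits) only enter
  through the duplicate-cell and QC rules.
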