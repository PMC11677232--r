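# merfish3d

Pixel-based decoding and spatial analysis for thick-tissue 3D MERFISH.

MERFISH (multiplexed error-robust fluorescence in situ hybridization)
identifies hundreds of RNA species in intact tissue by reading out a binary
barcode per gene across sequential two-color hybridization rounds. Imaging
thick (100–200 µm) sections as confocal z-stacks at a 1 µm step turns every
analysis step 3D: spots span several z planes, the two color channels are
offset axially by chromatic aberration, the stage drifts between rounds, and
segmented cells duplicate across overlapping fields of view (FOVs). This
package implements the full computational path from raw per-bit z-stacks to
a quality-controlled cell-by-gene matrix and juxtaposed-cell spatial
statistics, for people building or validating MERFISH-style pipelines
without access to a microscope: a seeded synthetic imaging model with
complete ground truth stands in for the instrument, so every stage is
testable end to end.

## The method

**Decoding.** After registration and filtering, each pixel carries an
intensity vector *v* ∈ ℝ^B over the B imaging bits. With barcodes
*w* ∈ {0,1}^B unit-normalized as *ŵ* = w/‖w‖₂ and pixels as *v̂* = v/‖v‖₂,
a pixel is assigned to the entry minimizing ‖v̂ − ŵ‖₂ over all entries —
coding *and* blank — and left unassigned when the minimum distance exceeds
0.65 or the magnitude ‖v‖₂ (on the median-normalized intensity scale) is
below 10. Adjacent same-barcode pixels aggregate into putative molecules;
single-pixel molecules are removed; molecules repeated in adjacent z planes
are collapsed to one.

**Misidentification calibration.** Blank barcodes are valid codewords
assigned to no gene, so decoded blanks measure the false-identification
rate:

    misid rate = (N_blank / B_blank) / (N_total / B_total)

with N molecule counts and B entry counts. The adaptive filter histograms
molecules in (log₁₀ intensity, barcode distance, area) space, ranks bins by
blank fraction, and accepts bins greedily while the cumulative rate stays at
or below the 5% target.

**Cells.** Segmentation label volumes are consumed as input; duplicate
cells across FOV overlaps are removed when the pairwise overlap volume
exceeds 40% of the smaller cell (the smaller cell is dropped); molecules are
assigned by voxel lookup; cells with volume < 100, total counts < 30, or a
z extent outside 5–40 one-micrometer sections are excluded; counts are
scaled to 10,000 per cell and log-transformed.

**Spatial statistics.** For focal cell subclasses, each cell's 3D
nearest neighbor is classified to-self/to-other; subclasses with ≥ 20
self-self pairs are tested (one-sided Wilcoxon rank-sum, BH-adjusted FDR)
for to-self distances being shorter, and nearest-neighbor distance
distributions are fitted with a two-component Gaussian mixture by EM to
expose a short-distance juxtaposed mode.

## Worked example

```r
library(merfish3d)

cb <- synth_codebook(n_bits = 16, weight = 4, min_hd = 4,
                     n_coding = 12, n_blank = 4, seed = 1)
cb
#> MERFISH codebook: 16 entries (12 coding, 4 blank), 16 bits

optics <- optics_config(n_bits = 16)
truth  <- plant_truth(cb, density_per_100um2_per_plane = 280,
                      volume_px = c(128, 128, 8), optics,
                      drift_mag_px = 3, seed = 5,
                      brightness = brightness_for_snr(12, 1, 1))
nrow(truth$molecules)
#> [1] 110

stacks <- render_stacks(truth, cb, optics, seed = 6)   # Poisson + read noise
stacks <- preprocess_stacks(stacks)   # drift registration, median
                                      # normalization, high-pass, 20x
                                      # Lucy-Richardson, low-pass
mols  <- drop_single_pixel(decode_stacks(stacks, cb))
filt  <- adaptive_filter(mols, cb, target_rate = 0.05)
final <- dedup_across_z(filt$molecules)

filt$model
#> adaptive filter model: 4000/4000 bins accepted, achieved misid rate 0.0000 (target 0.05)
nrow(final)
#> [1] 102
match_molecules(final, truth$molecules)[c("recall", "precision")]
#> $recall    [1] 0.9272727
#> $precision [1] 1
```

102 of 110 planted molecules are recovered within one pixel of their true
positions with no false identifications; the blank-based misidentification
rate of the final list is 0, well under the 5% calibration target (all
feature-space bins are accepted because the decoded list is already clean
at this signal-to-noise ratio).

`run_pipeline(default_config())` chains the full simulate → preprocess →
decode → filter → cells → matrix → spatial pipeline and writes all
artifacts (TIFF stacks + JSON manifest, molecule CSVs, MatrixMarket
cell-by-gene matrix, spatial statistics, a JSON run report) to the
configured output directory; `inst/scripts/merfish3d.R` is a thin
command-line wrapper over the same stages.

## Documentation

The methods vignette (`vignettes/thick-tissue-merfish-pipeline.Rmd`)
describes the imaging model, every tunable parameter with units and
defaults, the numerical choices, and what the synthetic simulations do and
do not establish about real data.
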