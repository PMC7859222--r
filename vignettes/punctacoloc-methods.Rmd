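---
title: "Methods: object-based miRNA/MVE co-localization and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: object-based miRNA/MVE co-localization and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

When fluorescently labeled miRNA duplexes are introduced into resealed
cells, part of the signal accumulates as diffraction-limited puncta in the
cytoplasm, and the scientific question is what fraction of those puncta
sits inside CD63-positive multivesicular endosomes (MVEs). Both structures
are small — MVE puncta around 500 nm, miRNA accumulations around 200 nm —
so the readout is object-based: detect the puncta in each channel, reduce
each channel to a binary object mask, intersect the masks (an AND gate),
and count, per cell, how many objects of one channel share pixels with the
other channel's mask. `punctacoloc` implements that measurement, the
single-cell segmentation it needs, the qPCR-side statistics that accompany
it (ΔΔCt fold changes, copies-per-cell, group tests), and a synthetic
microscopy generator that makes every stage testable against known truth.

## Pipeline model

The pipeline operates on multi-channel z-stacks with channel roles
`nucleus` (Hoechst-like stain), `cytoplasm` (an evenly distributed
cytosolic marker such as Ago2), `mve` (CD63), `mirna_guide` and
`mirna_passenger` (Cy3/Cy5-labeled strands). The stages are:

1. **Maximum-intensity projection.** Analysis is 2D after a per-pixel
   maximum over z. Image stacks are thin (9 slices by default) relative to
   the lateral extent of a cell, and the downstream counting is 2D, so
   projecting first is both faithful to common practice and cheap.
2. **Nucleus segmentation.** Gaussian smoothing (σ = 2 px), a global
   threshold (Otsu by default; `fixed` and `percentile` are options), hole
   filling, and a distance-transform watershed that splits touching
   nuclei. Components below `min_area_px` (default 50 px) are dropped.
3. **Cell segmentation.** A foreground mask thresholded from the smoothed
   cytoplasm channel is unioned with the nuclei; a seeded propagation
   (EBImage's Voronoi-style region growing on image intensity, seeded at
   the nuclei) partitions the foreground into one cell per nucleus. Cells
   touching the image border are flagged and excluded from every per-cell
   statistic, since truncated cells bias counts.
4. **Puncta detection.** Each puncta channel is filtered with a
   scale-normalized Laplacian of Gaussian at σ = d_px / (2√2), where d_px
   is the expected physical diameter converted to pixels (floored at 1 px
   so sub-resolution spots stay representable). This puts the LoG
   zero-crossing at the spot radius, the standard blob-scale relation. The
   threshold is computed on the *positive response values only* (Otsu by
   default), retained pixels are labeled with 8-connectivity, and an area
   filter removes fragments and aggregates. Intensity statistics are
   measured on the original image, not the response.
5. **Assignment and counting.** Each object belongs to the cell under its
   centroid (so every object belongs to at most one cell). For each
   retained cell the pipeline reports, in both directions, how many
   objects of one channel overlap the other channel's mask by at least
   `min_overlap_px` pixels (default 1 — the pure AND-gate criterion),
   together with the per-cell rates. `guide_in_mve_rate` (fraction of
   guide-strand objects on MVEs) is the estimator validated against
   simulation truth; `mve_with_guide_rate` is the complementary view.
6. **MVE classification.** Per cell, up to `sample_n` (default 20) MVE
   objects are sampled without replacement from a seeded per-cell stream
   and classified into the exclusive classes single / guide-only /
   passenger-only / both. Because a three-class summary (single, guide+,
   passenger+) does not say how a double-positive MVE is tallied, the
   output carries both the 4-way exclusive counts and the inclusive
   marginals (guide+ = guide-only + both), with the projection convention
   recorded in the result's metadata.
7. **Nuclear accumulation.** A cell is scored "accumulated" when the mean
   miRNA intensity over its nucleus is at least `ratio_threshold` (default
   1.5) times the mean over its cytoplasm. The underlying assay judged
   accumulation visually; the ratio criterion is this package's
   operationalization and the threshold is a configuration parameter.
8. **Pixelwise Pearson r** over a mask (no Costes-style thresholding), for
   the channel-correlation summaries that complement object counts.

Per-cell rates are summarized as mean ± SD over retained cells (cells with
zero objects of the query channel contribute a missing rate, excluded from
the mean — not a zero).

## qPCR statistics

* **ΔΔCt.** ΔCt = Ct(target) − Ct(reference, 18S rRNA); ΔΔCt subtracts the
  mean ΔCt of the control group within the same (target, compartment)
  stratum; log2FC = −ΔΔCt. The control baseline is the group *mean*
  because control groups have replicates.
* **Outlier rule.** Within each (target, compartment, group), samples with
  |log2FC − group mean| > 2 × group SD are flagged in a single pass and
  excluded from the reported group statistics. The centered form is the
  default reading of a bare "greater than two times SD" rule. A structural
  caveat documented here because it shapes the tests: in a group of n
  samples the standardized deviation is bounded by (n − 1)/√n, so this
  rule cannot flag anything in groups of n ≤ 5; it becomes effective at
  the replication the assay actually used (n ≈ 10–14), and the package's
  checks exercise it at that size.
* **Copies per cell.** copies = c · N_A · V, with V in liters (1 µm³ =
  1e−15 L). At 1.5 µM in a 2.6 × 10³ µm³ cell this gives ≈ 2.35 × 10⁶
  copies, about 23.5 times an endogenous upper bound of 1 × 10⁵ copies per
  cell.
* **Standard curve.** ct = m · log10(amount) + b by least squares;
  unknowns are mapped back through the line; amplification efficiency =
  10^(−1/m) − 1.
* **Group tests.** Welch's t (via `stats::t.test`), Cohen's d with
  df-weighted pooled SD, Dunnett many-to-one comparisons (single-step
  multivariate-t adjustment via `multcomp::glht`; the quasi-random
  integration is seeded for reproducibility and the method is recorded in
  the output), and Steel–Dwass all-pairs comparisons (pairwise rank sums
  with midranks, tie-corrected variance, studentized-range reference with
  infinite df — implemented here because no installed package provides
  it). OLS regression reports pointwise t-based confidence bands for the
  mean response.

## The synthetic generator

`simulation_params()` holds the generator's defaults, which are the
conditions the validation studies run under:

| parameter | default | rationale |
|---|---|---|
| n_z | 9 | matches the 9-slice acquisition the assay used |
| pixel_size_nm | 80 | typical confocal sampling; acquisition pixel size is not published, so it is a config option |
| mve_diameter_nm | 500 | reported MVE punctum size |
| mirna_spot_diameter_nm | 200 | reported miRNA accumulation size |
| cell_radius_um | 8–10 | HeLa-sized rounded cells |
| nucleus_radius_um | 2.5–4 | proportionate nuclei; the upper bound stays below the cell minimum so nuclei always fit |
| mve_per_cell_mean, guide_spots_per_cell_mean | 12, 12 | sparse punctate field; at this density the chance that a random cytoplasmic spot touches an MVE mask is ~3% of the cytoplasm area, keeping congestion bias in object co-localization small |
| psf_sigma_nm | 100 | diffraction-scale blur for visible-light confocal |
| background 20, spot amplitude 300, read noise 2 | — | peak SNR ≈ 17, a clean but noisy-enough acquisition |

Cells are random ellipses (nuclei concentric ellipses), placed without
overlap and wholly inside the field so that every simulated cell is usable
as ground truth; per-cell sub-streams are derived from the master seed so
adding cells never perturbs earlier cells. MVE centers are uniform over
the cytoplasm. Each miRNA spot is either nuclear (guide strand only, with
probability `nuclear_fraction_guide`), co-localized (probability
`coloc_fraction_*`: placed within a quarter MVE diameter of an MVE center,
which guarantees pixel-level mask overlap after rendering), or uniform in
the cytoplasm. Co-localized spots draw their MVE without replacement
(reshuffling when exhausted): the marginal choice stays uniform, but spots
spread across distinct MVEs. With replacement, birthday collisions put
several spots on one MVE, the rendered spots fuse into a single detected
object, and — because (c−1)/(n−1) < c/n — the object-level rate
systematically underestimates the spot-level fraction (by ~0.07 at a true
fraction of 0.75 in our measurements); the generator's purpose is
parameter recovery, so the truth it encodes must be recoverable by an
object-based reader.

Rendering: region channels are filled at their amplitude; each punctum is
an isotropic Gaussian with σ = diameter/(2√(2 ln 2)) combined in
quadrature with the PSF σ, at its peak amplitude, in its own z slice;
per-pixel Poisson shot noise (optional, `shot_noise = FALSE` for
noise-free renders) then additive Gaussian read noise; clipping at zero.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: realistic PSFs (Airy rings, axial
elongation), spectral bleed-through, photobleaching, intensity
heterogeneity within a cell, non-elliptical cell shapes, clustered (non-
uniform) MVE spatial statistics, and 3D structure beyond slice assignment
(z-attenuation is deliberately omitted since analysis happens after
projection).

## Numerical choices and degenerate inputs

* Coordinates are 1-based (row, column), the R convention; areas are in
  pixels with nm conversions available through `pixel_size_nm`.
* Otsu thresholds are computed by EBImage on 256-bin histograms; the mask
  test uses `>=`, so bin-edge ties resolve toward the lower threshold.
* A constant image has no threshold: nucleus segmentation warns and
  returns zero nuclei rather than erroring. A global threshold on a field
  *without* nuclei splits the noise distribution near its middle; a
  foreground covering more than `max_foreground_fraction` (default 0.4)
  of the field is therefore rejected as "no nuclei", with a warning.
* Connected components use 8-connectivity via an iterative minimum-label
  propagation (EBImage's labeler is 4-connected); the test suite checks it
  against an independent flood-fill oracle.
* Detection-count monotonicity in the threshold holds for the retained
  pixel count always, and for the object count only where components are
  unimodal (well-separated spots): raising a threshold can split merged
  spot pairs or shatter the sub-threshold noise sea, which *increases*
  counts.
* TIFF storage: 32-bit samples in [0, 1]; intensities are scaled by the
  smallest power of two at or above the data maximum, recorded in a JSON
  sidecar with the channel roles and pixel size. Round trips are exact to
  the 32-bit sample quantization (relative error < 1e−9 of full scale);
  identical stacks produce byte-identical files.
* All randomness flows from explicit seeds; stage and per-cell sub-seeds
  are derived with a 32-bit-safe mixing function, and seeded package
  functions restore the caller's RNG state.

## Validation studies and their sizes

The acceptance checks (also runnable via `scripts/acceptance.R`) use these
problem sizes, chosen to exercise the estimators at meaningful replication
while staying desk-scale:

* **Parameter recovery:** true guide co-localization fractions
  {0, 0.25, 0.5, 0.75, 1}; per fraction, 7 fields of 8 cells (56 cells) at
  512×512 px, 160 nm/px, 9 z-slices, peak SNR ≈ 17, passenger channel
  disabled. The mean per-cell `guide_in_mve_rate` must sit within ±0.05 of
  truth and be monotone. The residual at fraction 0 (~0.02–0.03) is
  chance overlap, consistent with the analytic congestion estimate.
* **Oracle equivalence:** 20 random 128×128 blob fields; per-object
  overlap flags must equal a brute-force pixel-set intersection exactly.
* **Detection recovery:** noise-free fields whose spots satisfy the
  > 4σ separation condition; exact count recovery, centroids within 1 px.
* **Statistical calibration:** familywise type-I error of Dunnett and
  Steel–Dwass over 1000 null simulations (3 groups × 10) must lie in
  [0.03, 0.07] at α = 0.05; the 95% regression band must cover the true
  mean response at x̄ in 93–97% of 1000 replicates.

## Known limitations

* Object-based counting cannot distinguish one bright miRNA accumulation
  from several fused ones; rates are object-level, not molecule-level.
* Chance co-localization is not subtracted; at high object densities the
  rate estimator is biased upward by the congestion fraction, which users
  can gauge with `coloc_fraction = 0` simulations at their own densities.
* The Pearson coefficient is computed without Costes thresholding and is
  sensitive to background inclusion; use masks restricted to cells.
* The nuclear-accumulation score depends on a single ratio threshold; it
  is a reproducible surrogate for a visual call, not a calibrated measure.
* Steel–Dwass uses the large-sample studentized-range approximation; for
  very small groups (n < 5) exact permutation would be preferable.
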