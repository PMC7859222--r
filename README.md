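# punctacoloc

Per-cell, object-based quantification of the co-localization of
fluorescently labeled miRNA puncta with CD63-positive multivesicular
endosomes (MVEs) in multi-channel fluorescence z-stacks, plus the qPCR
statistics that accompany such experiments. It is written for cell
biologists measuring where introduced miRNA ends up in resealed (or
ordinary) cultured cells: how much of it accumulates as ~200 nm spots
inside ~500 nm CD63-positive puncta, cell by cell.

## What it computes

Given a stack with channel roles {nucleus, cytoplasm, mve, mirna_guide,
mirna_passenger}, the pipeline performs

1. maximum-intensity projection over z;
2. single-cell segmentation: Otsu-thresholded nuclei split by a
   distance-transform watershed, then a nucleus-seeded propagation that
   partitions the cytoplasm foreground into one cell per nucleus
   (border-touching cells are excluded from statistics);
3. puncta detection per channel with a scale-normalized Laplacian of
   Gaussian at σ = d/(2√2) (d = expected diameter in px), thresholding of
   the positive response, 8-connected labeling and an area filter;
4. AND-gated object co-localization: an object counts as co-localized when
   it shares ≥ `min_overlap_px` pixels (default 1) with the partner
   channel's mask; per-cell counts and rates are reported in both
   directions (`guide_in_mve_rate`, `mve_with_guide_rate`);
5. classification of up to 20 randomly sampled MVEs per cell into
   single / guide-only / passenger-only / both;
6. nuclear-accumulation scoring (nuclear/cytoplasmic mean intensity ratio)
   and pixelwise Pearson r.

The statistics module implements ΔΔCt log2 fold changes normalized to 18S
rRNA with a single-pass 2×SD outlier exclusion, standard-curve
quantification with efficiency reporting, copies-per-cell (c·N_A·V),
Welch's t, Cohen's d, Dunnett and Steel–Dwass multiple comparisons, and
OLS regression with pointwise confidence bands.

A synthetic-microscopy generator (`simulation_params()`,
`simulate_field()`) produces 9-slice multi-channel fields of elliptical
cells with known per-spot ground truth — including a controllable true
co-localization fraction — so every stage is testable without any external
data. See `vignettes/punctacoloc-methods.Rmd` for the full model and its
assumptions.

## Worked example

Simulate a field of 8 cells with a true guide-strand co-localization
fraction of 0.5 (passenger 0.2) and run the full pipeline:

```r
library(punctacoloc)

params <- simulation_params(field_size_px = c(512, 512), pixel_size_nm = 160,
                            n_cells = 8, coloc_fraction_guide = 0.5,
                            coloc_fraction_passenger = 0.2, seed = 42)
cfg <- pipeline_config(simulate = params, seed = 42)
res <- run_pipeline(cfg)
print(res$summary, digits = 3)
#>                  metric  mean    sd n_cells
#> 1     guide_in_mve_rate 0.507 0.124       8
#> 2   mve_with_guide_rate 0.608 0.232       8
#> 3 passenger_in_mve_rate 0.259 0.135       8
```

The mean per-cell fraction of guide-strand objects overlapping the MVE
mask (0.507 ± 0.124) recovers the simulated truth of 0.5; the passenger
rate (0.259) sits near its truth of 0.2 plus a small chance-overlap
contribution. Per-cell detail and the sampled-MVE classification:

```r
head(res$per_cell, 2)
#>   cell_id n_mve n_guide guide_in_mve_rate mve_with_guide_rate ...
#> 1       1    13      13             0.692               0.615
#> 2       2    12      12             0.500               0.500
head(res$classification, 2)
#>   cell_id n_mve n_evaluated n_single n_guide_only n_passenger_only n_both
#> 1       1    13          13        5            6                0      2
#> 2       2    12          12        6            4                0      2
```

On the qPCR side, the copy number introduced by resealing cells in a
1.5 µM mimic, for a 2.6 × 10³ µm³ cell volume:

```r
est <- copies_per_cell(1.5e-6, 2.6e3)
est$copies_per_cell            # 2348635 — about 2.35 million copies
excess_ratio(est$copies_per_cell, 1e5)   # 23.5-fold over endogenous levels
```

Results can be written as CSV tables with a JSON run manifest
(`run_pipeline(cfg, out_dir = ...)`), stacks round-trip through
multi-page TIFF with a JSON channel-map sidecar (`write_stack()` /
`read_stack()`), and a thin command-line wrapper lives at
`inst/scripts/punctacoloc` (verbs `simulate` and `run`).

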