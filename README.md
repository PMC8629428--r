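# sheetclust

Quantification of membrane protein cluster organization on glass-adhered
plasma membrane sheets.

Proteins like the SNAREs syntaxin 1A and SNAP25 organize the plasma
membrane at the mesoscale: syntaxin-like species form tight ~80 nm clusters
at ~11 per µm², SNAP25-like species form diffuse ~160 nm "crowds", and the
clusters can recruit and thereby reorganize the crowds. `sheetclust`
implements the image-analysis and spatial-statistics chain with which such
reorganization is measured on two-channel microscopy of unroofed membrane
sheets, plus a ground-truth synthetic scene generator so the whole chain is
testable end to end without microscope data.

The package is aimed at quantitative microscopists: it works on plain
numeric matrices (`image2d`, with a physical pixel size in nm), reads and
writes grayscale TIFF, and emits per-sheet CSV/JSON tables.

## What it computes

* **Sheet segmentation** — Gaussian blur (σ = 3 px) + Otsu threshold +
  connected components; intensities are always measured on the raw image
  under the mask (`segment_sheets()`, `sheet_intensity_table()`), and the
  confocal plasma-membrane fraction `pm / (pm + cyto)` from three nested
  ROIs (`plasma_membrane_fraction()`).
* **Clustering degree** — rSDM = sd/mean of background-corrected ROI
  pixels (`roi_mean_intensity()`); a coefficient of variation that grows as
  staining becomes punctate.
* **Colocalization** — Pearson correlation of paired pixels with a
  180°-flipped chance control (`pcc()`, `pcc_flipped_control()`).
* **Spot detection and sizing** — prominence-based maxima detection
  (exact saddle/persistence semantics, plateau centroids) and per-maximum
  FWHM from dual-orientation 31 × 3 px linescan Gaussian fits with QC
  (R² ≥ 0.8, centre in the middle third) (`find_maxima()`,
  `fit_linescan()`, `maxima_size()`, `maxima_density()`).
* **Distance statistics vs the ideal gas** — nearest-neighbour
  distributions, radial cross-counts, pair distribution g(r), all with
  minus-sampling border correction, against the CSR closed forms
  (`p(r) = 2πλr e^{−πλr²}`) and seeded matched-count Monte-Carlo envelopes
  (`nn_distances()`, `pair_distribution()`, `csr_reference()`).
* **Regression and ratio arithmetic** — per-sheet OLS with Welch-style
  slope comparison, the saturating decay `y = (a − b)e^{−dx} + b`, and
  copy-number/staining ratio propagation (`linear_fit()`,
  `compare_slopes()`, `exp_decay_fit()`, `relative_staining_increase()`,
  `expression_ratio()`).
* **Synthetic scenes** — Thomas-type cluster processes, recruitment-coupled
  crowds, Gaussian-PSF rendering with photon/read noise, and the
  self-quenching / epitope-shielding intensity distortions
  (`scene_spec()`, `simulate_scene()`, `apply_quenching()`,
  `apply_shielding()`).

## Worked example

Simulate two-channel scenes at increasing recruitment coupling and push
them through the full measurement chain:

```r
library(sheetclust)

tab <- do.call(rbind, lapply(c(0, 0.5, 1), function(cp) {
  sc <- simulate_scene(scene_spec(coupling_p = cp, seed = 42))
  fields <- list(list(id = sprintf("coupling_%g", cp),
                      image_a = sc$cluster_image,   # syntaxin-like
                      image_b = sc$crowd_image))    # SNAP25-like
  cbind(coupling_p = cp,
        run_analysis(fields, analysis_params(seed = 42))$summary)
}))
tab[, c("coupling_p", "density_per_um2_a", "mean_size_nm_a",
        "rsdm_b", "pcc", "pcc_flipped", "median_cross_nn_nm")]
```

```
 coupling_p density_per_um2_a mean_size_nm_a rsdm_b     pcc pcc_flipped median_cross_nn_nm
        0.0              9.72           84.5   1.53 -0.0147     0.00797              127.5
        0.5              9.72           84.5   1.59  0.1600     0.00367              100.0
        1.0              9.72           84.5   1.69  0.3201    -0.00592               79.1
```

Reading the table: the cluster channel is identical across conditions
(~10 detected clusters per µm², ~85 nm apparent size). As more crowds are
recruited to clusters (`coupling_p` 0 → 1), the crowd channel becomes less
uniform (rSDM rises 1.53 → 1.69), the channels colocalize (PCC −0.01 →
0.32 while the flipped chance control stays at ~0), and the median
crowd-to-cluster nearest-neighbour distance falls from ~128 nm (the CSR
expectation at this cluster density) to ~79 nm, the binding distance of the
generator. That is exactly the signature used to argue that clusters
recruit crowds.

The numbered scripts under `analysis/` run the shipped studies end to end
and write their tables under `results/`: scene generation
(`01_simulate_scenes.R`), this coupling sweep (`02_coupling_sweep.R`), the
epitope-shielding regression-slope experiment (`03_shielding_regression.R`,
slope 1.00 → 0.29 as shielding rises 0 → 0.8), distance statistics with CSR
envelopes (`04_spatial_statistics.R`), and the ratio arithmetic
(`05_ratio_arithmetic.R`).

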