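---
title: "Quantifying membrane protein cluster organization on membrane sheets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane protein cluster organization on membrane sheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheetclust)
```

## The measurement problem

Many plasma-membrane proteins are not uniformly distributed but organized at
the mesoscale (100 nm – 1 µm): some, like syntaxin 1A, concentrate in tight,
bright clusters of roughly 80 nm apparent diameter at densities around
11 per µm²; others, like SNAP25, form larger, more diffuse "crowds" of
roughly 160 nm. Whether and how one species reorganizes the other is read
out from two-channel super-resolution (STED-like, 25 nm pixels) and
epifluorescence (≈267 nm pixels) images of unroofed, glass-adhered membrane
sheets. `sheetclust` implements that entire measurement chain on ordinary R
matrices, and pairs it with a ground-truth scene generator so every stage
can be validated without microscope data.

The chain is: segment sheets → detect intensity maxima → size them by
linescan Gaussian fits → summarize staining (mean intensity, clustering
degree, colocalization) → compare point patterns against an ideal-gas null
→ regress and propagate ratios.

## Intensity metrics

**rSDM (relative standard deviation of the mean).** For the
background-corrected pixels of an ROI, `rsdm = sd / mean` (sample SD, n − 1
denominator). A uniform stain gives a small rSDM; a punctate stain a large
one, so the rSDM acts as a clustering degree. Whether the background is
subtracted before the ratio is a convention; `roi_mean_intensity()`
subtracts by default and exposes `subtract_background_for_rsdm = FALSE`.
Negative corrected pixels are retained so means stay unbiased; if the
corrected mean is not positive, the rSDM is reported as undefined (`NA`
with a flag), never silently as zero.

**PCC and the flipped control.** Colocalization between channels is the
Pearson correlation of paired pixels inside the ROI. Chance overlap is
estimated by rotating the second channel by 180° ("flipped vertically and
horizontally") before correlating; the ROI mask itself is not rotated.
Which channel is flipped is immaterial for the expectation; the second
argument is flipped by convention. Zero variance in either channel is an
error, not a zero.

```{r pcc-example}
a <- image2d(matrix(c(1, 2, 3, 4), 2, 2), pixel_size_nm = 25)
b <- image2d(matrix(c(2, 1, 4, 3), 2, 2), pixel_size_nm = 25)
pcc(a, b, roi_full(a))
```

## Sheet segmentation and the membrane fraction

Epifluorescence frames are smoothed with a Gaussian blur (σ = 3 px), which
defines sheet outlines better than raw pixels, thresholded (Otsu by
default — parameter-free and scale-invariant; a fixed threshold can be
forced), and connected-component labelled. Components below `min_area_um2`
(default 4 µm²) are treated as debris. Intensities are then always measured
on the **raw** image under the mask. Sheets touching the frame edge are
kept but flagged, since no exclusion rule is part of the protocol.

The confocal plasma-membrane fraction uses three nested hand-drawn ROIs
(cell outline, cytoplasm, nucleus) reduced to integrated densities:
`pm = outer − inner`, `cyto = inner − nucleus`,
`fraction = pm / (pm + cyto)`.

## Maxima detection and sizing

`find_maxima()` implements prominence-based ("noise tolerance") spot
detection: a local maximum (or connected equal-valued plateau, reduced to
its centroid) is reported iff every path to a strictly higher pixel
descends at least `prominence` below its peak. The implementation is a
persistence sweep (union-find over pixels in decreasing order) and is
tested for exact agreement with an exhaustive reference scan. Two
conventions matter and are fixed deliberately:

* plateaus yield one point at the plateau centroid (deterministic
  tie-break);
* two peaks of exactly *equal* height are never suppressed against each
  other, because neither is a "higher region" for the other — suppression
  happens only against strictly higher terrain.

The default prominence is `5 * robust_noise(image, roi)`, where the noise
floor is 1.4826 × MAD of the residual between the image and its 3 × 3
median filter — the standard robust noise estimator, insensitive to the
structured signal itself. Diffuse channels are pre-smoothed with σ = 0.5 px
before detection to curb pixel-noise maxima; sizing is still done on the
raw image so sizes are not blur-inflated (switchable).

**Sizing.** At each maximum a horizontal and a vertical 31 × 3 px linescan
is averaged across its width and fitted with
`A exp(−(x − µ)² / 2σ²) + offset` by Levenberg–Marquardt. The fit starts at
the scan centre (A = max − min, µ = 15, σ = 3 px, offset = min) and, when
the profile argmax sits away from the centre, also from the argmax; the
better R² wins. This multi-start guards against the local optimum the
centred start finds on off-centre peaks. The FWHM (2√(2 ln 2) σ, in nm) of
the better-fitting orientation is the maximum's size. Quality control
rejects fits with R² < 0.8 on the averaged 31-sample profile (not the raw
93 pixels) or a centre outside the middle third, made exact as
µ ∈ [10, 20] on the 0–30 axis. Scans leaving the image fail QC rather than
erroring. Per ROI, surviving FWHM values are averaged; zero survivors give
a flagged `NA`.

```{r sizing-example}
rs <- render_spec(psf_fwhm_nm = 80, photons_per_unit = 0, read_noise_sd = 0)
img <- render_image(point_pattern(500, 500, c(1000, 1000)), rs,
                    intensity = 1000, noise = FALSE)
pat <- find_maxima(img, prominence = max(img) / 2)
maxima_size(img, pat)$mean_size_nm   # recovers 80 nm
```

## Point-pattern statistics against the ideal gas

Maxima coordinates are treated as planar point patterns in nm. All distance
statistics use **minus-sampling**: only reference points farther than
`margin_nm` from every window edge contribute, while neighbours may lie
anywhere, which keeps annulus counts unbiased up to the margin. The margin
defaults to the largest analyzed distance (the top bin edge). Bins are
half-open `[lo, hi)` with a default width of 25 nm (one pixel). Patterns
from multiple sheets are analyzed per sheet and pooled at the histogram
level (weighting sheets by their reference-point counts), never merged into
one fictitious pattern.

The null model is the ideal gas — complete spatial randomness at the same
density. Closed forms: NN distance density `p(r) = 2πλr exp(−πλr²)` with
mode `1/sqrt(2πλ)` (≈120 nm at λ = 11 µm⁻²) and mean `1/(2 sqrt(λ))`
(≈151 nm). `csr_reference()` complements them with seeded Monte-Carlo
envelopes: uniform patterns with *exactly* the observed count (binomial
matching — "same density" with less variance than a Poisson draw), same
margin and bins, pointwise 2.5/97.5 percentiles. The pair distribution
`g(r)` divides observed mean annulus counts by `λπ(hi² − lo²)`; for
same-pattern analysis the target intensity uses (n − 1)/area, matching the
exclusion of self-pairs.

Because histogram argmaxes are noisy and binning biases them low,
`nn_mode_estimate()` estimates the most likely NN distance by fitting a
two-parameter Weibull (the exact CSR family, but with the shape left free)
and reporting the fitted mode.

## Regression and ratio arithmetic

Per-sheet mean-vs-mean intensities are fitted by ordinary least squares
with a free intercept (forcing the origin is not part of the protocol).
Two slopes are compared with a Welch-style test,
`t = (b₁ − b₂)/sqrt(se₁² + se₂²)` with Welch–Satterthwaite degrees of
freedom from the per-fit residual dofs — no equal-variance assumption
across conditions. The clustering-vs-intensity relation is fitted by
unweighted nonlinear least squares of `y = (a − b) e^(−dx) + b`, with
`a` initialized at the smallest-x observation, `b` at the largest-x
observation and `d` from a log-linearized first pass; constant data return
`a = b` with the rate flagged unidentifiable.

Ratio propagation is plain arithmetic kept out of the measurement code:
`relative_staining_increase()` subtracts a common offset (typically the
100% endogenous contribution) before taking a fold ratio, and
`expression_ratio()` propagates a baseline copy-number ratio through
expression folds and membrane-localized fractions. Rounding ("7-fold",
"2.4") is a presentation concern; stored values are never rounded.

## The synthetic scene generator

`scene_spec()` defaults encode the study conditions the package is meant to
measure: cluster centres as CSR parents at 11 µm⁻² with 40 molecules spread
σ = 20 nm (so the rendered spot measures ≈80 nm through a 65 nm FWHM PSF,
via `sqrt(psf² + (2.355σ)²)`), and crowds at 8 µm⁻² rendered as Gaussian
blobs of σ = 62 nm (≈160 nm apparent). Crowd brightness carries the
~12-fold copy-number excess of the crowd species
(`12 · cluster_density · molecules_per_cluster / crowd_density` molecules
per crowd). Recruitment coupling places each crowd, with probability
`coupling_p`, at `binding_distance_nm` (default 80 nm, clusters touching
their recruits) from a uniformly chosen cluster centre. Rendering samples a
normalized Gaussian PSF at pixel centres (25 nm STED-like by default),
applies Poisson photon noise (100 photons per intensity unit) and Gaussian
read noise (SD 2) — chosen so the signal-to-noise resembles published STED
imagery; this is documented, not asserted. Offspring and recruited crowds
falling outside the window are discarded, like structures outside an imaged
sub-field; realized densities are therefore slightly below nominal near
borders.

Two distortions model why staining intensity can misreport protein amount:
`apply_quenching()` multiplies the intensity of any fluorophore with a
neighbour within 5 nm by (1 − q), and `apply_shielding()` removes labels
within `shield_radius_nm` of a cluster centre with probability `shield_p`
(probe accessibility lost under the cluster roof). Both can only decrease
intensity or label count. Their magnitudes are free parameters used for
property tests — synthetic results are not presented as reproducing any
measured slope.

What the generator does **not** emulate: fluorophore blinking and
bleaching, vectorial or 3-D PSFs, membrane curvature, internal crowd
substructure (blobs by default; a molecule-resolved path exists via
`gen_clustered()` + `render_image()`), and non-uniform backgrounds. Tests
passing on these scenes therefore validate the measurement chain's
correctness and calibration, not the biology of any particular real
dataset.

## Numerical choices

* Gaussian blur: separable sampled kernel truncated at 4σ, normalized to
  sum 1, with half-sample reflective padding — the operator is self-adjoint,
  so total intensity is conserved exactly; σ = 0 is the identity.
* All statistics are computed in double precision regardless of input
  depth.
* Nearest-neighbour search is exact (block-wise distance evaluation, no
  approximate index) and matches an O(n²) double loop bit-for-bit.
* Degenerate inputs error loudly (empty ROI, zero-variance PCC, zero-area
  density, empty target pattern) or return flagged `NA`s (rSDM with
  non-positive mean, sizes with zero QC survivors); nothing degrades to a
  silent 0.
* Determinism: every stochastic routine takes a seed and restores the
  caller's RNG state; `csr_reference()` records seed and replicate count in
  its output and sidecars.

## Problem sizes used in the shipped analyses

The packaged scripts and tests run at sizes chosen to make every check
sharp on a laptop-class machine: 6.4 × 6.4 µm scenes (256 × 256 px at
25 nm) for the end-to-end coupling sweep, ~10⁴-point CSR samples for the
distance-law checks, 199 CSR replicates for envelopes, 2000 null
replicates for the slope-test calibration, and 150 noisy replicates for
decay-fit bias. All are package choices, adjustable through the exported
parameters.

## Known limitations

* Detection at high spot density undercounts by merging sub-resolution
  neighbours (visible as g(r) → 0 below ~100 nm on detected patterns and a
  measured density below the planted one); this mirrors the physical
  resolution limit rather than a bug, and is why the shipped spacing
  analysis reports the detected mode, not the molecular one.
* The flipped-channel control estimates chance overlap only where the
  ROI's structure is roughly stationary; a strong intensity gradient leaks
  into the control for both real and synthetic data.
* `segment_sheets()` assumes sheets are bright on a dark background; it is
  not a general cell segmenter.
* The pipeline is strictly 2-D, matching the glass-adhered geometry.
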