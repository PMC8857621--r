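---
title: "Binarizing the choroid in OCT B-scans: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binarizing the choroid in OCT B-scans: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choroseg)
```

## The problem

Enhanced-depth-imaging OCT resolves the choroid, the vascular layer between
the retinal pigment epithelium (RPE) and the sclera. Separating its dark
vessel lumina (hypo-reflective) from the bright interstitial stroma
(hyper-reflective) — *binarization* — yields the choroidal vascularity index

$$\mathrm{CVI} = 100 \cdot \frac{\#\,\text{lumen pixels}}{\#\,\text{choroidal pixels}},$$

a widely used summary of choroidal vascular status. `choroseg` implements the
full analysis chain: flattening the curved choroid into a rectangular strip,
Niblack local thresholding with an explicit window-size analysis, assembly of
three-category ground truth (interstitial / lumen / sclera) for semantic
segmentation, a compact U-Net (and a SegNet-style variant) trained with the
reference regime, and the evaluation statistics: per-class accuracy, IoU,
between-repeat repeatability, ICC and Bland–Altman limits of agreement.
Because clinical OCT datasets of this kind are rarely shareable, the package
includes a synthetic phantom generator with known per-pixel truth; every
claim the test suite makes is evaluated against that known truth.

## Flattening

Local thresholding operates on rectangular regions, but the posterior eye is
curved. Each A-scan (column) is therefore shifted up by its inner choroidal
boundary (ICB) row so the ICB lies on row 0, and the image is cropped to a
fixed height. Shifts are whole pixels — no interpolation — so 8-bit values
are preserved exactly and flattening is invertible on in-range pixels. The
crop height is computed once per dataset as the maximum flattened OCB depth
over all images plus a scleral margin, then applied identically to every
image so the whole corpus shares one geometry.

Two points the interface makes explicit rather than leaving implicit:

* **Scleral margin** (default 15 rows). "Maximum scleral height" can be read
  as the deepest OCB position or as the thickness of visible sclera below
  it; a margin parameter covers both readings and makes the retained slab of
  sclera configurable and testable.
* **Coordinates.** All row/column indices in boundary files and in the
  flattening arithmetic are 0-based from the top of the image, with
  half-open crops, so the shift algebra has no off-by-one ambiguity.

The 6 mm subfoveal strip is extracted with the lateral pixel scale
(e.g. 14 µm/px gives `round(6000/14) = 429` columns), centred on the foveal
A-scan.

## Niblack local thresholding

The per-pixel threshold is

$$T(i,j) = m(i,j) + k\,\sigma(i,j),$$

with $m$ and $\sigma$ the mean and **population** standard deviation inside
the square window centred at $(i,j)$, and $k = -0.05$ by default. Numerical
choices that are pinned so results are bit-for-bit reproducible:

* population SD (divide by $N$), the standard Niblack formulation;
* symmetric-reflection border padding, so every window is full — Niblack is
  notoriously noisy where a window sees a single class, and reflection is the
  least surprising mitigation;
* even windows centre at offset $\lfloor w/2 \rfloor$;
* tie rule: a pixel exactly at its threshold is interstitial; strictly below
  is lumen (low reflectivity → vessel);
* local sums via summed-area tables, so cost is independent of window size;
  the implementation is verified against a naive double-loop oracle to
  $10^{-9}$.

A pixel below threshold is lumen; at or above, interstitium; rows at or below
the flattened outer choroidal boundary (OCB) are painted sclera. Masking
before or after classification commutes, which the tests assert.

### Window size

The window must straddle both tissue classes yet preserve local detail, and
the resulting CVI depends on it appreciably. `window_sweep_cvi()` computes
CVI across a window range (default 20–75 px), reproducing that analysis
surface. Manual window selection by an observer is replaced by
`select_window()`: with a known true luminal fraction it returns the
nearest-CVI window; without one it returns the first window at which the
CVI-vs-window curve flattens (absolute local slope below 0.05 percentage
points/px, falling back to the minimum-slope location when the curve never
gets that flat). The rule mirrors what an observer does — stop enlarging the
window once the binarization stops changing — and on phantoms the selected
window rank-correlates with the programmed vessel diameter (ρ ≈ 0.8 over 20
phantoms in the test suite). A fixed window of 51 px is kept as the
conventional baseline.

The sweep-vs-region question (full flattened strip or only the 6 mm
subfoveal strip) is left to the caller: both are plain function arguments;
the pipeline sweeps the subfoveal strip.

## Ground truth and dataset assembly

Label maps use the exact byte encoding interstitial (0,0,0), lumen
(255,255,255), sclera (127,0,0); the codec is bijective and label images are
stored as lossless PNG only, since any lossy format would corrupt the
reserved mask colour. Network inputs replicate the grayscale into three
channels and paint the scleral region with the same (127,0,0) colour — a
"highlighted region" that lets the network learn the sclera near-perfectly
and concentrate capacity on the choroid. Training without the painted mask
is supported (`mask_input = FALSE`) to quantify that effect.

Flattened crops are resampled to a fixed 224 × 896 grid — bilinear for
intensities, nearest-neighbour for labels and the OCB trace (a hard edge
must stay hard). The mapping of the native crop height onto the 224-row grid
is not uniquely determined by the source material, so the resampling kernel
is simply pinned and documented here. Each 224 × 896 image splits into four
non-overlapping 224 × 224 tiles at offsets {0, 224, 448, 672}; tiling is a
partition, and evaluation is always performed on reassembled full-width
scans, never on tiles. Splits are subject-grouped (60/20/20 by default):
every scan of a subject — all visits, repeats and orientations — lands in one
partition, so no anatomy leaks from training into testing. CVI for an image
with no choroidal pixels is reported as missing, never 0, to avoid biasing
partition means.

## Networks

No deep-learning framework is assumed: the encoder–decoder, Adam and
cross-entropy are implemented directly in C++ (RcppArmadillo), with 3 × 3
convolutions evaluated as im2col + BLAS GEMM in single precision.

* **U-Net**: encoder of depth 4, one 3 × 3 conv + ReLU per stage followed by
  2 × 2 max pooling, filters doubling per stage (base × {1,2,4,8}, bottleneck
  base × 16); decoder with nearest-neighbour upsampling and a skip
  concatenation from the matching encoder stage; final 1 × 1 conv + softmax
  over the 3 categories. One convolution per stage (rather than the classic
  two) satisfies the stated depth/filter contract while keeping CPU training
  tractable; it is a capacity choice, not a structural one.
* **SegNet-style**: same encoder; the decoder upsamples by max-unpooling with
  the pooling argmax indices, no skip concatenation, trained from random
  initialization.

Argmax ties resolve to the lowest class code, pinned for determinism.
Training is deterministic given the seed under single-threaded BLAS.

Two profiles exist: the reference regime (base 64 filters, constant learning
rate 1e-4, 15 epochs, batch 10, shuffle every epoch) and a desk profile
(base 16, 5 epochs, learning rate 1e-3). The desk rate is deliberately
warmer: 200 tiles × 5 epochs is only ~100 Adam steps, for which 1e-4 barely
moves a randomly initialized network. The desk profile is the one exercised
by the tests; the reference profile is the faithful configuration for real
hardware.

## Evaluation statistics

* Per-class accuracy $T_P/(T_P+F_N)$; total accuracy over all pixels; IoU
  $T_P/(T_P+F_P+F_N)$ per class and averaged. Empty denominators yield
  missing values, excluded from means.
* Repeatability $R = |P_1 - P_2| / p \times 100$ between the two same-visit
  scans, per category, with $p$ the total pixel count; 0 means perfect
  agreement. $R$ is a pseudometric (non-negative, symmetric, zero on
  identical maps), which the tests assert.
* ICC: two-way random effects, absolute agreement, single measures —
  ICC(2,1) — computed from the two-way ANOVA mean squares. The form is pinned
  because test–retest of one instrument is exactly its use case; the mean
  squares are cross-checked against `aov()` in the tests.
* Bland–Altman: mean difference and 95 % limits of agreement
  $\bar d \pm 1.96\,s_d$ with the sample (n−1) SD.

## The phantom generator

The phantom emulates the image features the pipeline actually exercises: a
parabolically curved ICB (so flattening is non-trivial), a bright stromal
band of configurable thickness, dark elliptical vessel lumina placed by
rejection sampling until a programmed luminal area fraction is reached
(default 0.60, the scale reported for healthy choroid; overlaps are handled
by union so the achieved fraction is exact by pixel count), a duller scleral
band below the OCB, a thin bright RPE-like band above, and multiplicative
gamma speckle (unit mean, dispersion 0.15 by default) — the standard
first-order surrogate for coherent-imaging noise on averaged B-scans.
Repeat pairs share one anatomy rendered on a widened canvas and cropped at a
small lateral offset (default 2 px) with fresh speckle, emulating follow-up
scans registered to almost the same location. Corpora persist per-subject
anatomy across visits and carry full provenance (subject, visit, repeat,
orientation) so subject-grouped splitting and repeatability pairing can be
tested end to end.

Default intensities (stroma 180, lumen 60, sclera 110 on the 8-bit scale)
give the strong lumen/stroma contrast of EDI imaging. What the phantom does
**not** model: retinal layers above the ICB, depth-dependent signal decay,
shadowing under large vessels, motion artefacts, or anatomically realistic
vessel networks (vessels are independent ellipses). Passing tests therefore
demonstrate that the algorithms recover known structure under OCT-like
statistics — not clinical-grade performance on real scans.

## Problem sizes used by the tests

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each claim is meaningful: 20 phantoms
for CVI recovery (window 32 ≈ 2 × the mean programmed vessel diameter);
56-window sweeps on one subfoveal strip; n = 400 pairs for ICC recovery
(between-subject SD 3, within-subject SD 1, closed-form ICC = 0.9) and
n = 5000 for Bland–Altman; a 14-subject corpus giving 200 training tiles for
the desk U-Net (5 epochs), evaluated on a held-out subject; and a 6-subject
corpus (3 epochs) for the masked-vs-unmasked comparison. Network unit tests
run on 32 × 32 tiles.

## Known limitations

* The networks here are desk-scale; reproducing clinical accuracy figures
  requires the reference profile, a real dataset and GPU-scale training.
* DeepLab-style pretrained backbones are out of scope (they would require
  external weights); the SegNet-style variant trains from scratch.
* Niblack is the only local method implemented; Sauvola/Bernsen/Otsu are
  deliberate non-goals.
* Proprietary scanner containers are not parsed; images enter as 8-bit
  PNG/TIFF with boundary traces as CSV/JSON.
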