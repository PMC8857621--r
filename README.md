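# choroseg

Binarization and vascularity analysis of the choroid in OCT B-scans.

The choroid — the vascular layer between retina and sclera — is imaged well
by enhanced-depth OCT, and its vascular status is commonly summarized by the
**choroidal vascularity index**,

```
CVI = 100 · lumen pixels / (lumen + interstitial pixels),
```

obtained by *binarizing* the choroid into dark vessel lumina and bright
interstitial stroma. `choroseg` implements the complete analysis chain in R:

* **Flattening** — per-A-scan shifting of the curved inner choroidal boundary
  (ICB) to the top row, dataset-wide crop height, 6 mm subfoveal extraction.
* **Niblack local binarization** — per-pixel threshold `T = m + k·σ`
  (population SD, reflective padding, `k = −0.05`), a CVI-vs-window-size
  sweep (20–75 px) and an explicit window-selection rule; fixed window 51 as
  the conventional baseline.
* **Ground truth & dataset assembly** — three-category label maps
  (interstitial 0, lumen 255, sclera (127,0,0) byte-exact), sclera-painted
  3-channel inputs, 224×896 → four 224×224 tiles, subject-grouped 60/20/20
  splits, class-proportion summaries.
* **Networks** — a compact U-Net (encoder depth 4, filters doubling to a
  16× bottleneck, skip connections) and a SegNet-style variant with
  max-unpooling, trained with Adam + cross-entropy. Implemented from scratch
  in RcppArmadillo (im2col + BLAS GEMM); no deep-learning framework needed.
* **Evaluation** — total/per-class accuracy, IoU, repeatability
  `R = |P₁−P₂|/p × 100`, ICC(2,1) and Bland–Altman limits of agreement.
* **Phantoms** — a synthetic OCT generator (curved boundaries, elliptical
  vessels with a programmed luminal fraction, multiplicative speckle, repeat
  pairs with lateral jitter, multi-subject corpora) so the whole pipeline is
  testable without clinical data.

## Worked example

```r
library(choroseg)

# a synthetic B-scan with known anatomy: 200x896 px, programmed luminal
# fraction 0.60, speckled
ph <- generate_phantom(phantom_spec(seed = 7))
ph$truth$lumen_fraction
#> [1] 0.596503

# flatten on the ICB, keep a 15-row scleral slab, cut the 6 mm strip
crop <- compute_crop_height(ph$boundaries, scleral_margin = 15)  # 64 rows
fl   <- flatten_bscan(ph$scan, ph$boundaries, crop)
sub  <- extract_subfoveal(fl, width_mm = 6)                      # 429 columns

# Niblack binarization with a window of ~2x the mean vessel diameter
tm  <- niblack_threshold_map(sub, window = 32, k = -0.05)
lab <- classify_choroid(sub, tm)
cvi(lab)
#> [1] 59.65921        # vs. ground truth 59.65 — the programmed fraction

# how the CVI depends on the analysis window
sw <- window_sweep_cvi(sub, windows = 20:75)
head(sw, 3)
#> # A tibble: 3 x 2
#>   window cvi_percent
#>    <int>       <dbl>
#> 1     20        58.2
#> 2     21        58.4
#> 3     22        58.6
select_window(sw)        # first window where the curve flattens
autoplot(sw)             # the CVI-vs-window curve
```

The CVI printed by the Niblack route (59.66 %) recovers the phantom's true
luminal fraction (59.65 %) to within a tenth of a percentage point; across 20
phantoms the mean recovered CVI sits within 3 points of the programmed 60 %.

Desk-scale training and evaluation of the U-Net run through the same
functions (`build_unet()`, `train_segmodel()`, `predict_full()`,
`metrics_report()`), or in one call via `run_pipeline(pipeline_config())`.
A thin command-line wrapper with `simulate/flatten/binarize/sweep/run`
subcommands is installed at `inst/cli/choroseg.R`.

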