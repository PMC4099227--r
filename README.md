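# lyticgray

Quantitative characterization of lytic bone lesions on digitized skeletal
radiographs, for researchers comparing multiple myeloma (MM) against
osteolytic metastases (OL). Both pathologies produce radiolucent "holes"
in bone that are hard to distinguish by eye; this package implements the
full analysis pipeline that turns a rectangular region of interest (ROI)
on a 12-bit radiograph into first-order gray-level statistics and a
per-bone-class assessment of their diagnostic ability.

## What it computes

For each ROI (after Perona–Malik anisotropic diffusion denoising,
`u' = u + λ Σ g(Δu)·Δu` with `g(s) = exp(−(s/K)²)` or `1/(1+(s/K)²)`):

- **MGL** — mean gray level of the ROI pixels;
- **SDGL** — standard deviation of gray level (sample, n−1);
- **CVGL** — percent coefficient of variation, `(SDGL/MGL)·100`.

For each bone-class stratum (flat: MM2 vs OL2; nonflat: MM1 vs OL1), per
parameter:

- unpaired two-sample t-test (pooled Student or Welch);
- nonparametric ROC analysis: the tie-corrected Mann–Whitney estimator
  `AUC = (Σ 1{x⁺ > x⁻} + ½·1{x⁺ = x⁻}) / (n⁺ n⁻)` with OL as the
  positive class, Hanley–McNeil standard error, and a two-sided normal
  test of the null AUC = 0.5.

A calibrated synthetic-data module (`groupPresets()`,
`generateGroupCases()`, `renderROIImage()`, `generateRadiographScene()`,
`simulateStudy()`) reproduces the statistical structure of the published
study groups — per-case MGL/SDGL normals at group sizes 31/35/36/41 — so
the entire pipeline is testable without patient data; `binormalAUC()`
gives the closed form `Φ(Δμ/√(σ₊²+σ₋²))` that the simulations are checked
against.

## Worked example

Simulate a full study from the calibrated presets (143 synthetic
radiographs with ground truth), then run the five-stage pipeline on it:

```r
library(lyticgray)

sim <- simulateStudy("synthetic_study", seed = 3)
report <- runStudy(StudyConfig(
  manifestPath = sim$manifest,
  diffusion = DiffusionParams(iterations = 3)))
report
#> StudyReport: 143 ROIs, 12 group descriptives, 6 ROC rows
#> AUC (positive class OL):
#>     pair parameter       auc      p_value
#>  MM2-OL2       MGL 0.7649051 6.555301e-05
#>  MM2-OL2      SDGL 0.8956640 2.487294e-09
#>  MM2-OL2      CVGL 0.4769648 7.285015e-01
#>  MM1-OL1       MGL 0.4055300 1.878626e-01
#>  MM1-OL1      SDGL 0.4460829 4.522839e-01
#>  MM1-OL1      CVGL 0.5751152 2.950448e-01
```

Reading the output: in **flat** bones, MGL and SDGL separate the two
pathologies well (AUC 0.76 and 0.90, both strongly significant against
AUC = 0.5 — OL lesions show higher and more dispersed gray levels),
while CVGL carries no signal; in **nonflat** bones no parameter
discriminates. That is exactly the qualitative structure of the study the
calibration presets come from.

Single-image use, and report files:

```r
img <- readImage("radiograph.tif")                 # 12-bit grayscale
roi <- extractROI(img, ROISpec(x0 = 120, y0 = 340, width = 40, height = 50))
computeGrayFeatures(anisotropicDiffusion(roi, DiffusionParams()))

runStudy(StudyConfig(manifestPath = "manifest.csv", outputDir = "out"))
# writes features.csv, descriptives.csv, comparisons.csv, roc.csv,
# roc_points_*.csv and run.log (byte-identical across reruns)
```

A thin command-line front end lives at `inst/scripts/lyticgray`
(`simulate`, `run --config FILE`, `features IMAGE --roi x0,y0,w,h`).

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch, the Monte Carlo mean
Mann–Whitney AUCs for the flat-bone MGL and SDGL comparisons: it draws
per-case feature values for MM2 (n = 36) and OL2 (n = 41) from the
calibrated group normals, computes the tie-corrected AUC of each
replicate with OL positive, and averages over 2000 seeded replicates.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The JSON output maps each target id to its recomputed value and the
number of replicates used.
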