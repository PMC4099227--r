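---
title: "Gray-level characterization of lytic bone lesions: methods and design"
author: "lyticgray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gray-level characterization of lytic bone lesions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lyticgray)
```

## The problem

Multiple myeloma (MM) and osteolytic metastases (OL) both produce lytic —
radiolucent — bone lesions on plain radiographs, and the two are hard to
tell apart visually. Myeloma lesions are purely lytic ("punched out", no
osteoblastic response), whereas lytic metastases involve coupled
osteoclast/osteoblast activity, which plausibly leaves a different
gray-level signature on film. `lyticgray` implements a quantitative
pipeline that turns a manually outlined region of interest (ROI) on a
digitized radiograph into three first-order gray-level statistics and then
asks, per bone class, how well each statistic separates the two
pathologies.

The pipeline has five stages:

1. **image acquisition** — 12-bit grayscale digitizations (levels 0–4095,
   0 = black) carried in 16-bit TIFF/PNG containers;
2. **ROI selection** — one rectangle per radiograph (40 wide x 50 tall by
   protocol), recorded in a CSV manifest;
3. **noise filtering** — Perona–Malik anisotropic diffusion;
4. **histogram parameters** — MGL, SDGL, CVGL on the filtered values;
5. **statistics** — group descriptives, two-sample t-tests, and
   nonparametric ROC/AUC per bone-class stratum.

Bone class matters because flat bones (skull, ribs, sternum, pelvis: two
cortical sheets around marrow-bearing diploe) and nonflat bones differ
histologically; groups are labelled MM1/OL1 (nonflat) and MM2/OL2 (flat).

## Image representation and ROI conventions

An `ImageGrid` stores an integer matrix plus a bit depth; validity
enforces values in $[0, 2^{\text{bitDepth}} - 1]$. The source material is
nominally described as "0–4096", but 12 bits give 4096 *levels*, 0–4095;
the package uses 0–4095 throughout. A 16-bit container whose values all
fit below 4096 is treated as 12-bit data.

ROIs use 0-based, half-open rectangles (`[x0, x0+width) x [y0,
y0+height)`), row-major. The convention is arbitrary but explicit and
tested; "40 x 50" is read as width 40, height 50, and any rectangle is
accepted. `extractROI` is a pure restriction — every output pixel equals
the corresponding input pixel — and out-of-bounds requests fail naming the
offending edge.

Because no TIFF package is available in the target environment, the
package carries a minimal TIFF codec: uncompressed, single-channel, 8- or
16-bit, both byte orders on read, little-endian single-strip on write.
This is deliberately the smallest dialect that round-trips 12-bit data
bit-exactly; compressed or multi-sample TIFFs are rejected with named
errors, and the test suite cross-checks the codec against an independent
reader. PNG reading handles 8/16-bit grayscale; PNG *writing* is limited
to 8-bit by the underlying library, so TIFF is the lossless interchange
format.

## Anisotropic diffusion

The denoising stage is the classic scalar Perona–Malik scheme on the
4-neighborhood with zero-flux (Neumann) boundaries:

$$u^{t+1}(p) = u^t(p) + \lambda \sum_{q \in N(p)} g\big(u^t(q) - u^t(p)\big)\,\big(u^t(q) - u^t(p)\big)$$

with conductance $g(s) = e^{-(s/K)^2}$ (default) or
$g(s) = 1/(1 + (s/K)^2)$. All fluxes are computed from the previous
iterate (Jacobi update), so results are independent of traversal order.

Tunable parameters, all exposed via `DiffusionParams` and the
`diffusion.*` config keys:

| parameter | default | units | role |
|---|---|---|---|
| `iterations` | 10 | steps | total smoothing time |
| `kappa` (K) | 30 | gray levels | gradient scale separating noise from edges |
| `lambda` | 0.25 | — | step size; 0.25 is the 4-neighbor stability limit |
| `conductance` | exponential | — | edge-stopping profile |

The source study cites the filter but reports none of these values, so
exact pixel-level replication of its filtered images is impossible; the
defaults are the canonical textbook choices, and first-order ROI
statistics depend only weakly on them (the mean is conserved *exactly*
regardless, see below). Three structural properties are enforced by tests:
gray-mass conservation (antisymmetric pairwise fluxes under Neumann
boundaries), the discrete maximum principle (for $\lambda \le 0.25$,
$g \le 1$), and monotone non-increase of the grid variance.

Filtering runs in floating point and the features are computed on the
unquantized filtered grid: requantizing would introduce a rounding rule
the protocol never specifies. Workflow order (filter at step 3, histogram
at step 4) implies features are computed *after* filtering; a config
switch (`diffusion.enabled = false`) disables the filter for sensitivity
analyses.

## First-order features

For ROI values $x_1,\dots,x_n$:

- $\mathrm{MGL} = \bar{x}$, the mean gray level;
- $\mathrm{SDGL}$, the standard deviation, with the sample ($n-1$)
  denominator by default — the protocol is silent, the choice is
  switchable (`sd_denominator = "n"`), and at $n = 2000$ pixels the two
  differ by under 0.03%;
- $\mathrm{CVGL} = (\mathrm{SDGL}/\mathrm{MGL}) \cdot 100$, the percent
  coefficient of variation, flagged as an error when $\mathrm{MGL} = 0$.

Features are computed from pixels directly; the 4096-bin histogram is a
reporting artifact (at full resolution its moments coincide exactly with
the pixel-wise ones on integer inputs, which the tests check, but
bin-level computation would only add quantization error on filtered
real-valued grids).

## Statistical analysis

**Mean comparison.** The source material says "paired t-test", but the
strata are structurally unpaired (36 vs 41 and 31 vs 35 cases), so the
package implements an unpaired two-sample test: pooled-variance Student
form by default, Welch optional. When both groups are exactly constant the
statistic degenerates; the implementation returns $t = 0, p = 1$ for equal
means and $t = \pm\infty, p = 0$ otherwise rather than erroring, so
noiseless phantom studies run end to end. No multiplicity correction is
applied: raw per-parameter p-values mirror the published analysis.

**ROC analysis.** Diagnostic ability is the tie-corrected Mann–Whitney
estimator

$$\widehat{\mathrm{AUC}} = \frac{1}{n_+ n_-} \sum_{i,j}
\Big[\mathbf{1}\{x_i > y_j\} + \tfrac12 \mathbf{1}\{x_i = y_j\}\Big],$$

computed via midranks and verified against brute-force pair enumeration
and the rank-sum statistic. Osteolytic metastasis is the positive class
and the raw feature value is the score: that is the only orientation
jointly consistent with the published group means and AUC table (flat-bone
MGL/SDGL AUC > 0.5 with OL means higher; nonflat MGL AUC < 0.5). The
standard error is Hanley–McNeil; the test of no diagnostic value uses the
Hanley–McNeil variance evaluated *under the null* AUC = 0.5, the closest
documented analogue of the asymptotic nonparametric test in legacy
statistics packages. DeLong's variance is available as an option, never
the default. `rocCurvePoints` emits one point per distinct threshold; its
trapezoidal area equals the Mann–Whitney estimate identically, ties
included.

`binormalAUC` supplies the closed form
$\Phi\!\big((\mu_+ - \mu_-)/\sqrt{\sigma_+^2 + \sigma_-^2}\big)$ used to
validate the synthetic generator.

## The synthetic world

The study's radiographs are not public, so the generator reproduces the
*statistical* structure of the four groups from their published
descriptive statistics (mean, SD, min, max of MGL/SDGL/CVGL per group,
with group sizes MM1 = 31, OL1 = 35, MM2 = 36, OL2 = 41), hard-coded as
`groupPresets()`.

Generative model, simplest consistent with the published moments:

- case-level $\mathrm{MGL} \sim N(\mu_{\mathrm{MGL}},
  \sigma_{\mathrm{MGL}}^2)$ and $\mathrm{SDGL} \sim
  N(\mu_{\mathrm{SDGL}}, \sigma_{\mathrm{SDGL}}^2)$, independent (no
  correlations are published); SDGL draws are floored at $10^{-6}$, a
  guard that with these parameters would require a >12-sigma event to
  bind;
- CVGL is *derived* per case as $\mathrm{sdgl}/\mathrm{mgl} \cdot 100$,
  matching its definition — so group-mean CVGL is a ratio statistic and
  only approximately matches the published CVGL means (Jensen's
  inequality; the published CVGL rows are indeed inconsistent with exact
  ratios of means). Where a calibration explicitly requires CVGL draws,
  `simulateFeatureAUC(..., cvglFrom = "direct")` samples from the
  published CVGL summary instead;
- published min/max are sanity ranges, not truncation bounds, by default
  (`truncate = TRUE` redraws out-of-range values);
- pixel level: ROI pixels i.i.d. $N(\mathrm{mgl}, \mathrm{sdgl}^2)$,
  rounded, clipped to 0–4095; full phantoms add a background ramp
  (field inhomogeneity), a brighter bone band, and a darker elliptical
  lesion whose ground-truth ROI is the inscribed rectangle (purely
  lesional pixels, like a reader-drawn ROI);
- seeding: one master seed; every stream is derived by a stable hash of
  (seed, group label, case index, stream name), so all generators are
  pure functions of their arguments.

Validation ties the model to the published results: the Monte Carlo mean
of the per-replicate Mann–Whitney AUC at the study group sizes must land
within ±0.03 of each published AUC (flat MGL 0.758, flat SDGL 0.883,
nonflat MGL 0.420, nonflat CVGL 0.600), whose binormal closed forms are
approximately 0.748, 0.878, 0.429 and 0.613 under this model.

What a green run does **not** establish: the generator makes no claim of
anatomical realism (no X-ray physics, scatter, beam hardening, screen-film
response, or bone texture), pixel-level images carry no spatial
correlation beyond the phantom's piecewise structure, and estimated SDGL
from a filtered ROI is systematically *smaller* than the generative target
(diffusion removes i.i.d. noise by design — ranks across cases are
approximately preserved, which is why AUC survives, but absolute SDGL
calibration through the full pixel pipeline is not claimed). Case-level
recovery (unbiased group means, AUC → binormal value) is what is tested.

## Numerical and reporting choices

- Histogram bins are level-aligned: `nBins` equal-width bins spanning
  $[0, 2^{\text{bitDepth}})$, so at full resolution integer level $v$
  falls in bin $v + 1$ (1-based) with no edge ambiguity.
- Descriptive SD of a single observation is 0 by convention.
- Report tables mirror the published layout: `descriptives.csv` is
  parameter x group (12 rows), `roc.csv` parameter x stratum (6 rows).
- Reruns are byte-identical: the run log carries a config fingerprint
  hash instead of a wall-clock timestamp (the in-memory report object
  keeps a timestamp for interactive provenance).
- Strata missing a pathology group (or with n < 2 in either) are skipped
  with a logged warning; missing image files abort with every missing
  path listed, never a silent drop.

## Limitations

- ROIs are taken from the manifest as drawn; there is no automated lesion
  detection or inter-reader variability model.
- The diffusion parameters of the original analysis are unknown;
  conclusions that depend on the exact filter strength (absolute SDGL
  levels, for instance) should be checked across `iterations`/`kappa`
  settings.
- The AUC null test is asymptotic; at these group sizes (31–41) that is
  standard practice but not exact.
- DICOM is out of scope; convert to 16-bit TIFF first.
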