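#' @import methods
NULL

# ---------------------------------------------------------------------------
# ImageGrid
# ---------------------------------------------------------------------------

#' ImageGrid: a single-channel raster of integer gray levels
#'
#' The elementary container of the package: a matrix of non-negative integer
#' gray levels together with the bit depth that bounds them. Digitized
#' radiographs in this workflow carry 12-bit data (gray levels 0--4095,
#' 0 = black) inside a 16-bit file container.
#'
#' @slot pixels Integer matrix, row-major image convention
#'   (`pixels[r, c]` is row `r` from the top, column `c` from the left).
#' @slot bitDepth Integer; all pixel values must lie in
#'   `[0, 2^bitDepth - 1]`.
#'
#' @param pixels A numeric or integer matrix of whole, non-negative values.
#' @param bitDepth Integer bit depth (default 12).
#' @return An `ImageGrid` object.
#' @examples
#' img <- ImageGrid(matrix(0:5, 2, 3), bitDepth = 12)
#' dim(img)
#' @aliases ImageGrid
#' @export ImageGrid
#' @exportClass ImageGrid
setClass("ImageGrid",
  representation(pixels = "matrix", bitDepth = "integer"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (nrow(p) < 1 || ncol(p) < 1) return("image must be at least 1 x 1")
    if (length(object@bitDepth) != 1 || object@bitDepth < 1)
      return("bitDepth must be a single positive integer")
    if (anyNA(p) || any(!is.finite(p))) return("pixels must be finite")
    if (any(p != round(p))) return("pixels must be whole numbers")
    lim <- 2^object@bitDepth - 1
    if (any(p < 0) || any(p > lim))
      return(sprintf("pixel values must lie in [0, %d] for bit depth %d",
                     lim, object@bitDepth))
    TRUE
  })

ImageGrid <- function(pixels, bitDepth = 12L) {
  if (is.vector(pixels)) pixels <- matrix(pixels, nrow = 1)
  storage.mode(pixels) <- "double"
  new("ImageGrid", pixels = pixels, bitDepth = as.integer(bitDepth))
}

#' @describeIn ImageGrid-class Pixel matrix accessor.
#' @param x,object An `ImageGrid`.
#' @export
imagePixels <- function(x) {
  stopifnot(is(x, "ImageGrid"))
  x@pixels
}

#' @describeIn ImageGrid-class Bit depth accessor.
#' @export
bitDepth <- function(x) {
  stopifnot(is(x, "ImageGrid"))
  x@bitDepth
}

#' @describeIn ImageGrid-class Dimensions `(height, width)` in pixels.
#' @export
setMethod("dim", "ImageGrid", function(x) dim(x@pixels))

setMethod("show", "ImageGrid", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageGrid: %d x %d pixels, %d-bit (range %d..%d)\n",
              d[1], d[2], object@bitDepth,
              as.integer(min(object@pixels)),
              as.integer(max(object@pixels))))
})

# ---------------------------------------------------------------------------
# ROISpec
# ---------------------------------------------------------------------------

#' ROISpec: a rectangular region of interest
#'
#' Zero-based, half-open rectangle in image coordinates: columns
#' `[x0, x0 + width)`, rows `[y0, y0 + height)`. The study protocol used
#' manually outlined 40 (wide) x 50 (tall) rectangles over the lesion; any
#' rectangle is accepted.
#'
#' @slot x0,y0 Integer offsets of the top-left corner (0-based).
#' @slot width,height Integer extents in pixels (>= 1).
#'
#' @param x0,y0 Top-left corner, 0-based.
#' @param width,height Extents in pixels.
#' @return An `ROISpec` object.
#' @examples
#' ROISpec(x0 = 10, y0 = 20, width = 40, height = 50)
#' @aliases ROISpec
#' @export ROISpec
#' @exportClass ROISpec
setClass("ROISpec",
  representation(x0 = "integer", y0 = "integer",
                 width = "integer", height = "integer"),
  validity = function(object) {
    if (object@x0 < 0 || object@y0 < 0) return("x0 and y0 must be >= 0")
    if (object@width < 1 || object@height < 1)
      return("width and height must be >= 1")
    TRUE
  })

ROISpec <- function(x0, y0, width, height) {
  new("ROISpec", x0 = as.integer(x0), y0 = as.integer(y0),
      width = as.integer(width), height = as.integer(height))
}

setMethod("show", "ROISpec", function(object) {
  cat(sprintf("ROISpec: [%d, %d) x [%d, %d) (w=%d, h=%d)\n",
              object@x0, object@x0 + object@width,
              object@y0, object@y0 + object@height,
              object@width, object@height))
})

# ---------------------------------------------------------------------------
# DiffusionParams
# ---------------------------------------------------------------------------

#' DiffusionParams: settings for Perona-Malik anisotropic diffusion
#'
#' @slot iterations Non-negative integer number of explicit time steps
#'   (default 10).
#' @slot kappa Positive gradient scale K in native gray units (default 30):
#'   intensity differences well below K are treated as noise and smoothed,
#'   differences well above K as edges and preserved.
#' @slot lambda Step size in `(0, 0.25]`; 0.25 is the stability limit of the
#'   explicit 4-neighbor scheme.
#' @slot conductance `"exponential"` for `g(s) = exp(-(s/K)^2)` or
#'   `"rational"` for `g(s) = 1 / (1 + (s/K)^2)`.
#'
#' @param iterations,kappa,lambda,conductance See slots.
#' @return A `DiffusionParams` object.
#' @examples
#' DiffusionParams(iterations = 10, kappa = 30, lambda = 0.25)
#' @aliases DiffusionParams
#' @export DiffusionParams
#' @exportClass DiffusionParams
setClass("DiffusionParams",
  representation(iterations = "integer", kappa = "numeric",
                 lambda = "numeric", conductance = "character"),
  validity = function(object) {
    if (object@iterations < 0) return("iterations must be >= 0")
    if (object@kappa <= 0) return("kappa must be > 0")
    if (object@lambda <= 0 || object@lambda > 0.25)
      return("lambda must lie in (0, 0.25] (explicit-scheme stability)")
    if (!object@conductance %in% c("exponential", "rational"))
      return("conductance must be 'exponential' or 'rational'")
    TRUE
  })

DiffusionParams <- function(iterations = 10L, kappa = 30, lambda = 0.25,
                            conductance = c("exponential", "rational")) {
  conductance <- match.arg(conductance)
  new("DiffusionParams", iterations = as.integer(iterations),
      kappa = as.numeric(kappa), lambda = as.numeric(lambda),
      conductance = conductance)
}

setMethod("show", "DiffusionParams", function(object) {
  cat(sprintf(
    "DiffusionParams: %d iterations, kappa=%g, lambda=%g, %s conductance\n",
    object@iterations, object@kappa, object@lambda, object@conductance))
})

# ---------------------------------------------------------------------------
# GroupDistributionParams
# ---------------------------------------------------------------------------

#' GroupDistributionParams: generative parameters for one study group
#'
#' Per-group case-level distribution parameters for the synthetic study
#' generator. Case-level MGL and SDGL are modeled as independent normals;
#' CVGL is derived per case as `sdgl / mgl * 100`, matching its definition.
#' The published per-group CVGL summary (mean, sd) is carried alongside so
#' that CVGL can also be simulated directly where a calibration requires it.
#'
#' @slot label One of `"MM1"`, `"OL1"`, `"MM2"`, `"OL2"` (pathology x bone
#'   class; 1 = nonflat, 2 = flat).
#' @slot mglMean,mglSd Case-level mean gray level distribution (gray levels).
#' @slot sdglMean,sdglSd Case-level SD gray level distribution (gray levels).
#' @slot cvglMean,cvglSd Published case-level CVGL distribution (percent).
#' @slot mglRange,sdglRange Published min/max sanity ranges (length-2);
#'   used as truncation bounds only on request.
#' @slot nCases Number of cases (radiographs) in the group.
#'
#' @param label,mglMean,mglSd,sdglMean,sdglSd,cvglMean,cvglSd See slots.
#' @param mglRange,sdglRange Length-2 numeric sanity ranges.
#' @param nCases Integer group size.
#' @return A `GroupDistributionParams` object.
#' @seealso [groupPresets()] for the calibrated study presets.
#' @aliases GroupDistributionParams
#' @export GroupDistributionParams
#' @exportClass GroupDistributionParams
setClass("GroupDistributionParams",
  representation(label = "character",
                 mglMean = "numeric", mglSd = "numeric",
                 sdglMean = "numeric", sdglSd = "numeric",
                 cvglMean = "numeric", cvglSd = "numeric",
                 mglRange = "numeric", sdglRange = "numeric",
                 nCases = "integer"),
  validity = function(object) {
    if (!object@label %in% c("MM1", "OL1", "MM2", "OL2"))
      return("label must be one of MM1, OL1, MM2, OL2")
    if (object@mglSd < 0 || object@sdglSd < 0 || object@cvglSd < 0)
      return("standard deviations must be >= 0")
    if (object@nCases < 1) return("nCases must be >= 1")
    if (length(object@mglRange) != 2 || length(object@sdglRange) != 2)
      return("ranges must have length 2")
    TRUE
  })

GroupDistributionParams <- function(label, mglMean, mglSd, sdglMean, sdglSd,
                                    nCases, cvglMean = NA_real_,
                                    cvglSd = NA_real_,
                                    mglRange = c(-Inf, Inf),
                                    sdglRange = c(0, Inf)) {
  new("GroupDistributionParams", label = label,
      mglMean = as.numeric(mglMean), mglSd = as.numeric(mglSd),
      sdglMean = as.numeric(sdglMean), sdglSd = as.numeric(sdglSd),
      cvglMean = as.numeric(cvglMean), cvglSd = as.numeric(cvglSd),
      mglRange = as.numeric(mglRange), sdglRange = as.numeric(sdglRange),
      nCases = as.integer(nCases))
}

setMethod("show", "GroupDistributionParams", function(object) {
  cat(sprintf(
    "GroupDistributionParams %s: n=%d, MGL ~ N(%.2f, %.2f^2), SDGL ~ N(%.2f, %.2f^2)\n",
    object@label, object@nCases, object@mglMean, object@mglSd,
    object@sdglMean, object@sdglSd))
})

# ---------------------------------------------------------------------------
# SceneConfig
# ---------------------------------------------------------------------------

#' SceneConfig: layout of a synthetic radiograph phantom
#'
#' Describes a full-image phantom: a smooth horizontal background gradient,
#' a brighter horizontal bone band, and a darker (radiolucent) elliptical
#' lytic lesion inside the band. Pixel noise inside the lesion follows the
#' per-case `lesionSdgl` target; pixels outside use `noiseSd`.
#'
#' @slot height,width Image dimensions in pixels.
#' @slot backgroundLevel Soft-tissue background gray level.
#' @slot gradientAmplitude Peak-to-peak amplitude of the left-to-right
#'   intensity ramp (models field inhomogeneity).
#' @slot boneLevel Gray level of the bone band (brighter than background).
#' @slot boneRows Length-2 integer range of rows (1-based, inclusive)
#'   occupied by the bone band.
#' @slot lesionCenter Length-2 `(row, col)` ellipse center, 1-based.
#' @slot lesionAxes Length-2 `(semi-row, semi-col)` ellipse semi-axes.
#' @slot lesionMgl,lesionSdgl Per-case gray-level targets inside the lesion.
#' @slot noiseSd Gaussian noise SD outside the lesion.
#' @slot seed Integer seed; the scene is a pure function of the config.
#'
#' @param height,width,backgroundLevel,gradientAmplitude,boneLevel See slots.
#' @param boneRows,lesionCenter,lesionAxes,lesionMgl,lesionSdgl,noiseSd,seed
#'   See slots.
#' @return A `SceneConfig` object.
#' @aliases SceneConfig
#' @export SceneConfig
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(height = "integer", width = "integer",
                 backgroundLevel = "numeric", gradientAmplitude = "numeric",
                 boneLevel = "numeric", boneRows = "integer",
                 lesionCenter = "numeric", lesionAxes = "numeric",
                 lesionMgl = "numeric", lesionSdgl = "numeric",
                 noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@height < 1 || object@width < 1)
      return("image dimensions must be >= 1")
    if (length(object@lesionCenter) != 2 || length(object@lesionAxes) != 2)
      return("lesionCenter and lesionAxes must have length 2")
    if (any(object@lesionAxes <= 0)) return("lesion semi-axes must be > 0")
    lo <- object@lesionCenter - object@lesionAxes
    hi <- object@lesionCenter + object@lesionAxes
    if (lo[1] < 1 || lo[2] < 1 || hi[1] > object@height ||
        hi[2] > object@width)
      return("lesion ellipse must lie fully inside the image")
    if (object@noiseSd < 0 || object@lesionSdgl < 0)
      return("noise standard deviations must be >= 0")
    TRUE
  })

SceneConfig <- function(height = 128L, width = 128L, backgroundLevel = 900,
                        gradientAmplitude = 120, boneLevel = 2000,
                        boneRows = NULL, lesionCenter = NULL,
                        lesionAxes = c(30, 24), lesionMgl = 1600,
                        lesionSdgl = 250, noiseSd = 40, seed = 1L) {
  if (is.null(boneRows))
    boneRows <- c(round(height * 0.25), round(height * 0.75))
  if (is.null(lesionCenter)) lesionCenter <- c(height / 2, width / 2)
  new("SceneConfig", height = as.integer(height), width = as.integer(width),
      backgroundLevel = as.numeric(backgroundLevel),
      gradientAmplitude = as.numeric(gradientAmplitude),
      boneLevel = as.numeric(boneLevel), boneRows = as.integer(boneRows),
      lesionCenter = as.numeric(lesionCenter),
      lesionAxes = as.numeric(lesionAxes),
      lesionMgl = as.numeric(lesionMgl), lesionSdgl = as.numeric(lesionSdgl),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# StudyConfig
# ---------------------------------------------------------------------------

#' StudyConfig: a complete, serializable description of one pipeline run
#'
#' @slot manifestPath Path to the ROI manifest CSV.
#' @slot outputDir Output directory for report files (`NA` to skip writing).
#' @slot diffusion A [DiffusionParams-class] object.
#' @slot diffusionEnabled Logical; set `FALSE` to compute features on raw
#'   ROI values.
#' @slot sdDenominator `"n_minus_1"` (sample SD, default) or `"n"`.
#' @slot tTest `"pooled"` (Student, default) or `"welch"`.
#' @slot positiveClass Pathology treated as ROC-positive (default `"OL"`).
#' @slot seed Integer seed used by synthetic subcommands.
#'
#' @param manifestPath,outputDir,diffusion,diffusionEnabled See slots.
#' @param sdDenominator,tTest,positiveClass,seed See slots.
#' @return A `StudyConfig` object.
#' @seealso [runStudy()], [readStudyConfig()]
#' @aliases StudyConfig
#' @export StudyConfig
#' @exportClass StudyConfig
setClass("StudyConfig",
  representation(manifestPath = "character", outputDir = "character",
                 diffusion = "DiffusionParams", diffusionEnabled = "logical",
                 sdDenominator = "character", tTest = "character",
                 positiveClass = "character", seed = "integer"),
  validity = function(object) {
    if (!object@sdDenominator %in% c("n_minus_1", "n"))
      return("sdDenominator must be 'n_minus_1' or 'n'")
    if (!object@tTest %in% c("pooled", "welch"))
      return("tTest must be 'pooled' or 'welch'")
    if (!object@positiveClass %in% c("OL", "MM"))
      return("positiveClass must be 'OL' or 'MM'")
    TRUE
  })

StudyConfig <- function(manifestPath, outputDir = NA_character_,
                        diffusion = DiffusionParams(),
                        diffusionEnabled = TRUE,
                        sdDenominator = c("n_minus_1", "n"),
                        tTest = c("pooled", "welch"),
                        positiveClass = c("OL", "MM"), seed = 1L) {
  new("StudyConfig", manifestPath = manifestPath,
      outputDir = as.character(outputDir), diffusion = diffusion,
      diffusionEnabled = isTRUE(diffusionEnabled),
      sdDenominator = match.arg(sdDenominator), tTest = match.arg(tTest),
      positiveClass = match.arg(positiveClass), seed = as.integer(seed))
}

setMethod("show", "StudyConfig", function(object) {
  cat("StudyConfig:\n")
  cat("  manifest:   ", object@manifestPath, "\n")
  cat("  output dir: ", object@outputDir, "\n")
  cat(sprintf("  diffusion:   %s (iter=%d, kappa=%g, lambda=%g, %s)\n",
              if (object@diffusionEnabled) "enabled" else "disabled",
              object@diffusion@iterations, object@diffusion@kappa,
              object@diffusion@lambda, object@diffusion@conductance))
  cat(sprintf("  sd denom: %s | t-test: %s | positive class: %s | seed: %d\n",
              object@sdDenominator, object@tTest, object@positiveClass,
              object@seed))
})
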