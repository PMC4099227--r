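# Synthetic study generator calibrated to the published group statistics.
#
# Case-level model: MGL ~ Normal(mglMean, mglSd) and SDGL ~ Normal(sdglMean,
# sdglSd), independently (the published tables give no correlations);
# CVGL is derived per case as sdgl / mgl * 100, matching its definition.
# Pixel-level model: ROI pixels i.i.d. Normal(case mgl, case sdgl), rounded
# and clipped to the 12-bit range.

#' Calibrated generative presets for the four study groups
#'
#' Hard-coded per-group case-level distribution parameters taken from the
#' published descriptive statistics of the study populations: MGL and SDGL
#' mean/SD (plus min/max sanity ranges) and the per-group CVGL summary, for
#' multiple myeloma (MM) and osteolytic metastases (OL) stratified by bone
#' class (1 = nonflat, 2 = flat), with group sizes MM1 = 31, OL1 = 35,
#' MM2 = 36, OL2 = 41.
#'
#' @return A named list of [GroupDistributionParams-class]
#'   (`MM1`, `OL1`, `MM2`, `OL2`).
#' @examples
#' groupPresets()$MM2
#' @export
groupPresets <- function() {
  list(
    MM1 = GroupDistributionParams("MM1", 1710.42, 332.25, 256.89, 12.98,
                                  nCases = 31, cvglMean = 15.02,
                                  cvglSd = 3.09, mglRange = c(1264, 2017),
                                  sdglRange = c(242.37, 277.56)),
    OL1 = GroupDistributionParams("OL1", 1634.13, 269.36, 258.56, 20.43,
                                  nCases = 35, cvglMean = 16.14,
                                  cvglSd = 2.41, mglRange = c(1312, 2000),
                                  sdglRange = c(228.64, 295.52)),
    MM2 = GroupDistributionParams("MM2", 1593.21, 140.87, 248.12, 9.51,
                                  nCases = 36, cvglMean = 15.57,
                                  cvglSd = 1.45, mglRange = c(1406, 1840),
                                  sdglRange = c(238.10, 264.27)),
    OL2 = GroupDistributionParams("OL2", 1744.53, 176.75, 270.66, 16.80,
                                  nCases = 41, cvglMean = 15.64,
                                  cvglSd = 1.56, mglRange = c(1472, 2096),
                                  sdglRange = c(240.64, 301.28)))
}

# floor for SDGL draws: keeps case SDs strictly positive (with the preset
# parameters a non-positive draw is a > 12-sigma event, so the floor is a
# guard, not a distortion)
SDGL_FLOOR <- 1e-6

#' Draw per-case feature values for one group
#'
#' Case-level MGL and SDGL are drawn independently from the group normals;
#' CVGL is derived per case. Deterministic given `(params, seed)`.
#'
#' @param params A [GroupDistributionParams-class].
#' @param seed Integer master seed.
#' @param nCases Number of cases; defaults to the group size in `params`.
#' @param truncate Logical; if `TRUE`, redraw values falling outside the
#'   published min/max sanity ranges (off by default — the ranges are
#'   sample extremes, not distribution bounds).
#' @return A `data.frame` with columns `case_id`, `mgl`, `sdgl`, `cvgl`.
#' @examples
#' generateGroupCases(groupPresets()$MM2, seed = 1)
#' @export
generateGroupCases <- function(params, seed, nCases = params@nCases,
                               truncate = FALSE) {
  stopifnot(is(params, "GroupDistributionParams"))
  nCases <- as.integer(nCases)
  if (nCases == 0)
    return(data.frame(case_id = character(0), mgl = numeric(0),
                      sdgl = numeric(0), cvgl = numeric(0)))
  draw <- function(n, mean, sd, range, stream) {
    v <- withSeed(deriveSeed(seed, params@label, stream),
                  stats::rnorm(n, mean, sd))
    if (truncate && sd > 0) {
      bad <- which(v < range[1] | v > range[2])
      attempt <- 0L
      while (length(bad) && attempt < 1000L) {
        attempt <- attempt + 1L
        v[bad] <- withSeed(deriveSeed(seed, params@label, stream, attempt),
                           stats::rnorm(length(bad), mean, sd))
        bad <- which(v < range[1] | v > range[2])
      }
    }
    v
  }
  mgl <- draw(nCases, params@mglMean, params@mglSd, params@mglRange, "mgl")
  sdgl <- pmax(draw(nCases, params@sdglMean, params@sdglSd,
                    params@sdglRange, "sdgl"), SDGL_FLOOR)
  data.frame(case_id = sprintf("%s_%03d", params@label, seq_len(nCases)),
             mgl = mgl, sdgl = sdgl, cvgl = sdgl / mgl * 100)
}

#' Render a synthetic ROI image with target first-order statistics
#'
#' Pixels are drawn i.i.d. `Normal(mgl, sdgl)`, rounded, and clipped to the
#' representable range. For 40 x 50 ROIs at radiograph-scale parameters,
#' [computeGrayFeatures()] on the raw rendered image recovers `(mgl, sdgl)`
#' to within sampling error (`SE_mgl = sdgl / sqrt(n)`).
#'
#' @param mgl Target mean gray level in `(0, 4095)`.
#' @param sdgl Target SD of gray level (>= 0; 0 gives a constant image).
#' @param height,width ROI dimensions (defaults: the study's 50 x 40).
#' @param seed Integer seed; rendering is a pure function of its arguments.
#' @param bitDepth Bit depth for rounding/clipping (default 12).
#' @return An [ImageGrid-class].
#' @export
renderROIImage <- function(mgl, sdgl, height = 50L, width = 40L, seed,
                           bitDepth = 12L) {
  if (height < 1 || width < 1)
    lgStop("ROI dimensions must be >= 1", "lg_param_error")
  if (mgl <= 0 || mgl > 2^bitDepth - 1 || sdgl < 0)
    lgStop("need 0 < mgl <= max gray level and sdgl >= 0", "lg_param_error")
  vals <- withSeed(deriveSeed(seed, "render", round(mgl * 100),
                              round(sdgl * 100)),
                   stats::rnorm(height * width, mgl, sdgl))
  vals <- pmin(pmax(round(vals), 0), 2^bitDepth - 1)
  ImageGrid(matrix(vals, nrow = height, ncol = width), bitDepth = bitDepth)
}

#' Render a full synthetic radiograph phantom with a lytic lesion
#'
#' Builds a phantom emulating the appearance of a lytic lesion on a
#' digitized radiograph: a smooth left-to-right background ramp (field
#' inhomogeneity), a brighter horizontal bone band, and a darker
#' (radiolucent) elliptical lesion inside the band whose pixels follow the
#' per-case `Normal(lesionMgl, lesionSdgl)` target. The returned
#' ground-truth ROI is the largest rectangle inscribed in the lesion
#' ellipse, so its pixels are purely lesional.
#'
#' @param config A [SceneConfig-class].
#' @return A list with elements `image` ([ImageGrid-class]) and `roi`
#'   ([ROISpec-class] ground truth).
#' @examples
#' scene <- generateRadiographScene(SceneConfig(seed = 7))
#' roi <- extractROI(scene$image, scene$roi)
#' @export
generateRadiographScene <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  h <- config@height; w <- config@width
  col <- matrix(rep(seq_len(w), each = h), h, w)
  row <- matrix(rep(seq_len(h), times = w), h, w)
  base <- config@backgroundLevel +
    config@gradientAmplitude * (col - 1) / max(w - 1, 1)
  band <- row >= config@boneRows[1] & row <= config@boneRows[2]
  base[band] <- config@boneLevel +
    config@gradientAmplitude * (col[band] - 1) / max(w - 1, 1)
  inLesion <- ((row - config@lesionCenter[1]) / config@lesionAxes[1])^2 +
    ((col - config@lesionCenter[2]) / config@lesionAxes[2])^2 <= 1
  u <- base
  u[inLesion] <- config@lesionMgl
  noise <- withSeed(deriveSeed(config@seed, "scene"),
                    matrix(stats::rnorm(h * w), h, w))
  u[inLesion] <- u[inLesion] + noise[inLesion] * config@lesionSdgl
  u[!inLesion] <- u[!inLesion] + noise[!inLesion] * config@noiseSd
  u <- pmin(pmax(round(u), 0), 4095)
  # ground-truth ROI: largest axis-aligned rectangle inscribed in the
  # ellipse (semi-axes / sqrt(2)), so every ROI pixel lies on the lesion --
  # mirroring how reader-drawn ROIs sit inside the lesion
  halfH <- floor(config@lesionAxes[1] / sqrt(2))
  halfW <- floor(config@lesionAxes[2] / sqrt(2))
  roi <- ROISpec(
    x0 = round(config@lesionCenter[2]) - halfW - 1L,
    y0 = round(config@lesionCenter[1]) - halfH - 1L,
    width = 2L * halfW + 1L, height = 2L * halfH + 1L)
  list(image = ImageGrid(u, bitDepth = 12L), roi = roi)
}

#' Generate a complete synthetic study on disk
#'
#' Draws per-case feature targets for every group from the calibration
#' presets, renders one ROI image per case embedded in a noisy background
#' margin, and writes: the TIFF images, an ROI manifest consumable by
#' [runStudy()], and a ground-truth CSV of the per-case generative targets.
#'
#' @param outDir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param presets Named list of [GroupDistributionParams-class]
#'   (default [groupPresets()]).
#' @param roiHeight,roiWidth ROI dimensions (defaults 50 x 40).
#' @param margin Background margin around the ROI block, in pixels.
#' @return Invisibly, a list with `manifest` (path), `groundTruth` (path)
#'   and `cases` (the ground-truth `data.frame`).
#' @export
simulateStudy <- function(outDir, seed, presets = groupPresets(),
                          roiHeight = 50L, roiWidth = 40L, margin = 8L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  imgDir <- file.path(outDir, "images")
  dir.create(imgDir, showWarnings = FALSE)
  rows <- list(); truth <- list()
  for (label in names(presets)) {
    p <- presets[[label]]
    cases <- generateGroupCases(p, seed)
    group <- substr(label, 1, 2)
    boneClass <- if (substr(label, 3, 3) == "2") "flat" else "nonflat"
    for (i in seq_len(nrow(cases))) {
      caseSeed <- deriveSeed(seed, label, i)
      roiImg <- renderROIImage(cases$mgl[i], cases$sdgl[i],
                               roiHeight, roiWidth, seed = caseSeed)
      full <- matrix(
        pmin(pmax(round(withSeed(deriveSeed(caseSeed, "bg"),
          stats::rnorm((roiHeight + 2 * margin) * (roiWidth + 2 * margin),
                       1000, 30))), 0), 4095),
        nrow = roiHeight + 2 * margin)
      full[margin + seq_len(roiHeight), margin + seq_len(roiWidth)] <-
        imagePixels(roiImg)
      path <- file.path(imgDir, paste0(cases$case_id[i], ".tif"))
      writeImage(ImageGrid(full, 12L), path)
      rows[[length(rows) + 1L]] <- data.frame(
        image_path = path, x0 = margin, y0 = margin,
        width = roiWidth, height = roiHeight,
        group = group, bone_class = boneClass,
        case_id = cases$case_id[i])
    }
    truth[[label]] <- cbind(cases, group = group, bone_class = boneClass)
  }
  manifest <- do.call(rbind, rows)
  manifestPath <- file.path(outDir, "manifest.csv")
  utils::write.csv(manifest, manifestPath, row.names = FALSE, quote = FALSE)
  truthDf <- do.call(rbind, truth)
  rownames(truthDf) <- NULL
  truthPath <- file.path(outDir, "ground_truth.csv")
  utils::write.csv(truthDf, truthPath, row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifestPath, groundTruth = truthPath,
                 cases = truthDf))
}

#' Monte Carlo mean AUC between two simulated groups
#'
#' Repeatedly draws per-case feature values for a positive and a negative
#' group from their calibrated normals at the preset group sizes, computes
#' the tie-corrected Mann-Whitney AUC of each replicate, and returns the
#' replicate mean — the quantity the calibration is validated against.
#' For `feature = "cvgl"`, `cvglFrom` chooses between drawing CVGL directly
#' from its published summary (`"direct"`, default) and deriving it per
#' case from MGL and SDGL draws (`"derived"`).
#'
#' @param posParams,negParams [GroupDistributionParams-class] for the
#'   positive (OL) and negative (MM) groups.
#' @param feature `"mgl"`, `"sdgl"`, or `"cvgl"`.
#' @param nReps Number of Monte Carlo replicates (default 2000).
#' @param seed Integer master seed.
#' @param cvglFrom `"direct"` or `"derived"` (only used for CVGL).
#' @return A list: `meanAUC`, `mcSE` (Monte Carlo standard error of the
#'   mean), `nReps`, `aucs` (per-replicate values).
#' @examples
#' p <- groupPresets()
#' simulateFeatureAUC(p$OL2, p$MM2, "sdgl", nReps = 200, seed = 1)$meanAUC
#' @export
simulateFeatureAUC <- function(posParams, negParams,
                               feature = c("mgl", "sdgl", "cvgl"),
                               nReps = 2000L, seed = 1L,
                               cvglFrom = c("direct", "derived")) {
  feature <- match.arg(feature)
  cvglFrom <- match.arg(cvglFrom)
  pull <- function(params, repSeed) {
    if (feature == "cvgl" && cvglFrom == "direct") {
      withSeed(deriveSeed(repSeed, params@label, "cvgl_direct"),
               stats::rnorm(params@nCases, params@cvglMean, params@cvglSd))
    } else {
      generateGroupCases(params, repSeed)[[feature]]
    }
  }
  aucs <- vapply(seq_len(nReps), function(r) {
    repSeed <- deriveSeed(seed, "rep", r)
    mannWhitneyAUC(pull(posParams, repSeed), pull(negParams, repSeed))
  }, numeric(1))
  list(meanAUC = mean(aucs), mcSE = stats::sd(aucs) / sqrt(nReps),
       nReps = as.integer(nReps), aucs = aucs)
}
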