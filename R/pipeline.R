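# Study orchestration: manifest -> ROI -> diffusion -> features ->
# group statistics, mirroring the five-step radiograph analysis workflow.

strataLabel <- function(group, boneClass) {
  paste0(group, ifelse(boneClass == "flat", "2", "1"))
}

#' Parse a flat key=value study configuration file
#'
#' Recognized keys: `manifest`, `output_dir`, `diffusion.enabled`,
#' `diffusion.iterations`, `diffusion.kappa`, `diffusion.lambda`,
#' `diffusion.conductance`, `sd_denominator`, `t_test`, `positive_class`,
#' `seed`. Lines starting with `#` and blank lines are ignored.
#'
#' @param path Path to the config file.
#' @return A [StudyConfig-class].
#' @export
readStudyConfig <- function(path) {
  if (!file.exists(path))
    lgStop(sprintf("config file not found: %s", path),
           "lg_missing_file_error")
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2)
      lgStop(sprintf("malformed config line: '%s'", ln), "lg_config_error")
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  get <- function(key, default) if (is.null(kv[[key]])) default else kv[[key]]
  if (is.null(kv[["manifest"]]))
    lgStop("config must set 'manifest'", "lg_config_error")
  StudyConfig(
    manifestPath = kv[["manifest"]],
    outputDir = get("output_dir", NA_character_),
    diffusion = DiffusionParams(
      iterations = as.integer(get("diffusion.iterations", 10L)),
      kappa = as.numeric(get("diffusion.kappa", 30)),
      lambda = as.numeric(get("diffusion.lambda", 0.25)),
      conductance = get("diffusion.conductance", "exponential")),
    diffusionEnabled = !tolower(get("diffusion.enabled", "true")) %in%
      c("false", "0", "no"),
    sdDenominator = get("sd_denominator", "n_minus_1"),
    tTest = get("t_test", "pooled"),
    positiveClass = get("positive_class", "OL"),
    seed = as.integer(get("seed", 1L)))
}

#' Run the full lesion-characterization study
#'
#' Executes, for every manifest record: image reading, ROI extraction,
#' anisotropic diffusion (unless disabled), and first-order feature
#' computation; then, per bone-class stratum, the two-group mean
#' comparisons and nonparametric ROC analyses of MGL, SDGL and CVGL. A
#' stratum missing one of the two pathology groups (or with fewer than two
#' cases in either) is skipped with a logged warning; a manifest referencing
#' missing images aborts after listing every missing file.
#'
#' @param config A [StudyConfig-class] (or a manifest path, taken with all
#'   defaults).
#' @return A `StudyReport` list: `features`, `descriptives`, `comparisons`,
#'   `roc`, `rocPoints` (named list of `data.frame`s), `skipped`, `config`,
#'   `version`, `timestamp`. If `config@outputDir` is set the report is
#'   also written via [writeReport()].
#' @seealso [writeReport()], [simulateStudy()]
#' @export
runStudy <- function(config) {
  if (is.character(config)) config <- StudyConfig(manifestPath = config)
  stopifnot(is(config, "StudyConfig"))
  manifest <- loadROIManifest(config@manifestPath)
  if (nrow(manifest) == 0)
    lgStop("manifest contains no records", "lg_manifest_error")
  missing <- manifest$image_path[!file.exists(manifest$image_path)]
  if (length(missing))
    lgStop(paste0("missing image file(s):\n  ",
                  paste(unique(missing), collapse = "\n  ")),
           "lg_missing_file_error")

  featRows <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- manifest[i, ]
    img <- readImage(rec$image_path)
    roi <- extractROI(img, ROISpec(rec$x0, rec$y0, rec$width, rec$height))
    vals <- if (config@diffusionEnabled)
      anisotropicDiffusion(roi, config@diffusion) else imagePixels(roi)
    f <- computeGrayFeatures(vals, sdDenominator = config@sdDenominator)
    data.frame(case_id = rec$case_id, group = rec$group,
               bone_class = rec$bone_class,
               mgl = f$mgl, sdgl = f$sdgl, cvgl = f$cvgl)
  })
  features <- do.call(rbind, featRows)
  features <- features[order(features$case_id), ]
  rownames(features) <- NULL

  params <- c("mgl", "sdgl", "cvgl")
  features$stratum <- strataLabel(features$group, features$bone_class)

  descriptives <- do.call(rbind, lapply(params, function(p)
    do.call(rbind, lapply(sort(unique(features$stratum)), function(g) {
      d <- descriptiveStats(features[[p]][features$stratum == g])
      data.frame(parameter = toupper(p), group = g,
                 mean = d$mean, st_dev = d$st_dev, min = d$min, max = d$max,
                 n = d$n)
    }))))

  comparisons <- list(); roc <- list(); rocPoints <- list()
  skipped <- character(0)
  posGroup <- config@positiveClass
  negGroup <- setdiff(c("MM", "OL"), posGroup)
  for (bc in c("flat", "nonflat")) {
    sub <- features[features$bone_class == bc, ]
    nPos <- sum(sub$group == posGroup); nNeg <- sum(sub$group == negGroup)
    if (nPos < 2 || nNeg < 2) {
      if (nrow(sub) > 0) {
        msg <- sprintf(
          "stratum '%s' skipped: needs >= 2 cases in each group (%s: %d, %s: %d)",
          bc, posGroup, nPos, negGroup, nNeg)
        warning(msg, call. = FALSE)
        skipped <- c(skipped, msg)
      }
      next
    }
    pairLabel <- paste0(strataLabel(negGroup, bc), "-",
                        strataLabel(posGroup, bc))
    for (p in params) {
      pos <- sub[[p]][sub$group == posGroup]
      neg <- sub[[p]][sub$group == negGroup]
      tt <- twoSampleT(neg, pos, pooled = config@tTest == "pooled")
      rr <- empiricalAUC(pos, neg)
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        bone_class = bc, pair = pairLabel, parameter = toupper(p),
        t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value)
      roc[[length(roc) + 1L]] <- data.frame(
        bone_class = bc, pair = pairLabel, parameter = toupper(p),
        auc = rr$auc, se = rr$se, p_value = rr$p_value,
        n_pos = rr$n_pos, n_neg = rr$n_neg)
      rocPoints[[paste(toupper(p), bc, sep = "_")]] <- rocCurvePoints(pos, neg)
    }
  }
  report <- structure(list(
    features = features[, c("case_id", "group", "bone_class",
                            "mgl", "sdgl", "cvgl")],
    descriptives = descriptives,
    comparisons = if (length(comparisons)) do.call(rbind, comparisons) else
      data.frame(),
    roc = if (length(roc)) do.call(rbind, roc) else data.frame(),
    rocPoints = rocPoints,
    skipped = skipped,
    config = config,
    version = as.character(utils::packageVersion("lyticgray")),
    timestamp = Sys.time()), class = "StudyReport")
  if (!is.na(config@outputDir)) writeReport(report, config@outputDir)
  report
}

#' @export
print.StudyReport <- function(x, ...) {
  cat(sprintf("StudyReport: %d ROIs, %d group descriptives, %d ROC rows\n",
              nrow(x$features), nrow(x$descriptives), nrow(x$roc)))
  if (nrow(x$roc)) {
    cat("AUC (positive class ", x$config@positiveClass, "):\n", sep = "")
    print(x$roc[, c("pair", "parameter", "auc", "p_value")],
          row.names = FALSE)
  }
  invisible(x)
}
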