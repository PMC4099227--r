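# Report serialization: CSV tables mirroring the study's published layout
# plus a deterministic run log.

#' Write a study report to disk
#'
#' Writes `features.csv` (per-ROI features), `descriptives.csv` (parameter
#' x group -> mean/sd/min/max, the descriptive-table layout),
#' `comparisons.csv` (t-tests per parameter and bone class), `roc.csv`
#' (AUC/SE/p per parameter and bone class), one `roc_points_<PARAM>_<bone
#' class>.csv` per ROC curve, and `run.log`. All outputs are deterministic
#' functions of the input data and configuration: re-running the same study
#' overwrites every file with identical bytes (the run log therefore
#' carries a config fingerprint, not a wall-clock timestamp).
#'
#' @param report A `StudyReport` from [runStudy()].
#' @param outputDir Destination directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
writeReport <- function(report, outputDir) {
  stopifnot(inherits(report, "StudyReport"))
  ok <- tryCatch({
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    dir.exists(outputDir)
  }, error = function(e) FALSE)
  if (!ok)
    lgStop(sprintf("cannot create output directory '%s'", outputDir),
           "lg_unwritable_error")
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
    df
  }
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(outputDir, name)
    utils::write.csv(fmt(df), p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  emit(report$features, "features.csv")
  emit(report$descriptives, "descriptives.csv")
  emit(report$comparisons, "comparisons.csv")
  emit(report$roc, "roc.csv")
  for (nm in names(report$rocPoints))
    emit(report$rocPoints[[nm]], paste0("roc_points_", nm, ".csv"))

  cfg <- report$config
  logLines <- c(
    "lyticgray study run",
    sprintf("package version: %s", report$version),
    sprintf("config hash: %s", lgHash(list(
      cfg@manifestPath, cfg@diffusionEnabled, cfg@diffusion@iterations,
      cfg@diffusion@kappa, cfg@diffusion@lambda, cfg@diffusion@conductance,
      cfg@sdDenominator, cfg@tTest, cfg@positiveClass, cfg@seed))),
    sprintf("manifest: %s", cfg@manifestPath),
    sprintf("diffusion: %s (iterations=%d kappa=%g lambda=%g %s)",
            if (cfg@diffusionEnabled) "enabled" else "disabled",
            cfg@diffusion@iterations, cfg@diffusion@kappa,
            cfg@diffusion@lambda, cfg@diffusion@conductance),
    sprintf("sd denominator: %s | t-test: %s | positive class: %s",
            cfg@sdDenominator, cfg@tTest, cfg@positiveClass),
    sprintf("ROIs processed: %d", nrow(report$features)),
    if (length(report$skipped))
      paste("WARNING:", report$skipped) else "no strata skipped",
    "per-ROI features:",
    sprintf("  %s %s/%s MGL=%.6g SDGL=%.6g CVGL=%.6g",
            report$features$case_id, report$features$group,
            report$features$bone_class, report$features$mgl,
            report$features$sdgl, report$features$cvgl))
  logPath <- file.path(outputDir, "run.log")
  writeLines(logLines, logPath)
  invisible(c(paths, logPath))
}
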