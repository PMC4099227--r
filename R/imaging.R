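#' Extract a rectangular region of interest from an image
#'
#' Returns the sub-image covered by `roi` (0-based, half-open coordinates:
#' columns `[x0, x0 + width)`, rows `[y0, y0 + height)`). Output pixel
#' `(r, c)` equals input pixel `(y0 + r, x0 + c)`; no resampling of any
#' kind. The study protocol extracted one manually outlined 40 x 50
#' rectangle per radiograph.
#'
#' @param image An [ImageGrid-class].
#' @param roi An [ROISpec-class], fully inside the image.
#' @return An [ImageGrid-class] of dimensions `(roi height, roi width)`.
#' @examples
#' img <- ImageGrid(matrix(1:9, 3, 3, byrow = TRUE))
#' extractROI(img, ROISpec(1, 1, 2, 2))
#' @export
extractROI <- function(image, roi) {
  stopifnot(is(image, "ImageGrid"), is(roi, "ROISpec"))
  h <- nrow(image@pixels); w <- ncol(image@pixels)
  edges <- c(
    if (roi@x0 + roi@width > w) "right",
    if (roi@y0 + roi@height > h) "bottom")
  if (length(edges))
    lgStop(sprintf(
      "ROI extends past the %s edge of the %d x %d image",
      paste(edges, collapse = " and "), h, w), "lg_bounds_error")
  rows <- seq.int(roi@y0 + 1L, roi@y0 + roi@height)
  cols <- seq.int(roi@x0 + 1L, roi@x0 + roi@width)
  ImageGrid(image@pixels[rows, cols, drop = FALSE],
            bitDepth = image@bitDepth)
}

MANIFEST_COLUMNS <- c("image_path", "x0", "y0", "width", "height",
                      "group", "bone_class", "case_id")

#' Load an ROI manifest
#'
#' Reads the study manifest: a UTF-8 CSV with header exactly
#' `image_path,x0,y0,width,height,group,bone_class,case_id`. Each row
#' describes the single ROI taken from one radiograph: the pathology group
#' (`MM` = multiple myeloma, `OL` = osteolytic metastasis) and the bone
#' class (`flat` or `nonflat`) of the lesion site.
#'
#' @param path Path to the manifest CSV.
#' @return A `data.frame` with one validated row per ROI record.
#' @seealso [runStudy()]
#' @export
loadROIManifest <- function(path) {
  if (!file.exists(path))
    lgStop(sprintf("manifest not found: %s", path), "lg_missing_file_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), MANIFEST_COLUMNS))
    lgStop(sprintf("manifest header must be exactly '%s'",
                   paste(MANIFEST_COLUMNS, collapse = ",")),
           "lg_manifest_error")
  if (nrow(df) == 0) return(df)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    geom <- suppressWarnings(
      as.numeric(row[c("x0", "y0", "width", "height")]))
    if (anyNA(geom) || any(geom != round(geom)) ||
        geom[1] < 0 || geom[2] < 0 || geom[3] < 1 || geom[4] < 1)
      lgStop(sprintf("manifest row %d: malformed ROI geometry", i),
             "lg_manifest_error")
    if (!row$group %in% c("MM", "OL"))
      lgStop(sprintf("manifest row %d: unknown group '%s' (want MM or OL)",
                     i, row$group), "lg_manifest_error")
    if (!row$bone_class %in% c("flat", "nonflat"))
      lgStop(sprintf(
        "manifest row %d: unknown bone_class '%s' (want flat or nonflat)",
        i, row$bone_class), "lg_manifest_error")
    if (!nzchar(row$case_id))
      lgStop(sprintf("manifest row %d: empty case_id", i),
             "lg_manifest_error")
  }
  for (col in c("x0", "y0", "width", "height"))
    df[[col]] <- as.integer(df[[col]])
  df
}
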