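# Raster I/O for single-channel grayscale images.
#
# TIFF support is a minimal native implementation (uncompressed, single
# sample per pixel, 8- or 16-bit, either byte order on read; little-endian
# single-strip on write) because no TIFF package is available. PNG reading
# goes through the `png` package; PNG writing is limited to 8-bit data by
# that package, so 12-bit images must be written as TIFF.

TIFF_TAGS <- c(width = 256L, height = 257L, bitsPerSample = 258L,
               compression = 259L, photometric = 262L, stripOffsets = 273L,
               samplesPerPixel = 277L, rowsPerStrip = 278L,
               stripByteCounts = 279L)

# unsigned read that avoids readBin's size-4 signed limitation (values
# >= 2^31 never occur in the files this package writes or targets)
readUint <- function(src, n, size, endian) {
  v <- readBin(src, "integer", n = n, size = size,
               signed = size == 4, endian = endian)
  v[v < 0] <- v[v < 0] + 2^32
  v
}

# Read one IFD entry's value vector (SHORT or LONG), inline or at offset.
readTiffTagValues <- function(con, type, count, valueBytes, endian) {
  size <- switch(as.character(type), "3" = 2L, "4" = 4L, NA_integer_)
  if (is.na(size)) return(NULL)  # types we do not interpret
  if (size * count <= 4) {
    vals <- readUint(valueBytes, n = count, size = size, endian = endian)
  } else {
    offset <- readUint(valueBytes, n = 1, size = 4, endian = endian)
    pos <- seek(con)
    seek(con, offset)
    vals <- readUint(con, n = count, size = size, endian = endian)
    seek(con, pos)
  }
  vals
}

readTiffGray <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  order <- rawToChar(readBin(con, "raw", 2))
  endian <- switch(order, II = "little", MM = "big",
                   lgStop("not a TIFF file (bad byte-order mark)",
                          "lg_unsupported_format_error"))
  magic <- readUint(con, 1, size = 2, endian = endian)
  if (magic != 42L)
    lgStop("not a TIFF file (bad magic number)",
           "lg_unsupported_format_error")
  ifdOffset <- readUint(con, 1, size = 4, endian = endian)
  seek(con, ifdOffset)
  nTags <- readUint(con, 1, size = 2, endian = endian)
  tags <- list()
  for (i in seq_len(nTags)) {
    id <- readUint(con, 1, size = 2, endian = endian)
    type <- readUint(con, 1, size = 2, endian = endian)
    count <- readUint(con, 1, size = 4, endian = endian)
    valueBytes <- readBin(con, "raw", 4)
    tags[[as.character(id)]] <-
      readTiffTagValues(con, type, count, valueBytes, endian)
  }
  getTag <- function(name, default = NULL) {
    v <- tags[[as.character(TIFF_TAGS[[name]])]]
    if (is.null(v)) default else v
  }
  width <- getTag("width"); height <- getTag("height")
  if (is.null(width) || is.null(height))
    lgStop("TIFF missing image dimensions", "lg_unsupported_format_error")
  spp <- getTag("samplesPerPixel", 1L)
  if (spp != 1L)
    lgStop(sprintf("multi-channel image (%d samples per pixel); %s",
                   spp, "only single-channel grayscale is supported"),
           "lg_multichannel_error")
  bits <- getTag("bitsPerSample", 1L)
  if (!bits %in% c(8L, 16L))
    lgStop(sprintf("unsupported TIFF bit depth %d (want 8 or 16)", bits),
           "lg_unsupported_format_error")
  if (getTag("compression", 1L) != 1L)
    lgStop("compressed TIFF not supported; rewrite uncompressed",
           "lg_unsupported_format_error")
  offsets <- getTag("stripOffsets")
  counts <- getTag("stripByteCounts")
  if (is.null(offsets))
    lgStop("TIFF missing strip offsets", "lg_unsupported_format_error")
  if (is.null(counts))
    counts <- rep(width * height * bits / 8 / length(offsets),
                  length(offsets))
  vals <- integer(0)
  for (i in seq_along(offsets)) {
    seek(con, offsets[i])
    n <- counts[i] / (bits / 8)
    vals <- c(vals, readUint(con, n = n, size = bits / 8, endian = endian))
  }
  if (length(vals) != width * height)
    lgStop("TIFF pixel data truncated", "lg_unsupported_format_error")
  list(pixels = matrix(vals, nrow = height, ncol = width, byrow = TRUE),
       containerBits = bits)
}

writeTiffGray <- function(pixels, path, bits = 16L) {
  con <- file(path, "wb")
  on.exit(close(con))
  h <- nrow(pixels); w <- ncol(pixels)
  nTags <- 9L
  ifdSize <- 2L + nTags * 12L + 4L
  dataOffset <- 8L + ifdSize
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")
  writeBin(nTags, con, size = 2, endian = "little")
  writeTag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT: left-justified in the 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeTag(TIFF_TAGS[["width"]], 4L, 1L, w)
  writeTag(TIFF_TAGS[["height"]], 4L, 1L, h)
  writeTag(TIFF_TAGS[["bitsPerSample"]], 3L, 1L, bits)
  writeTag(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
  writeTag(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)  # BlackIsZero
  writeTag(TIFF_TAGS[["stripOffsets"]], 4L, 1L, dataOffset)
  writeTag(TIFF_TAGS[["samplesPerPixel"]], 3L, 1L, 1L)
  writeTag(TIFF_TAGS[["rowsPerStrip"]], 4L, 1L, h)
  writeTag(TIFF_TAGS[["stripByteCounts"]], 4L, 1L, w * h * bits / 8)
  writeBin(0L, con, size = 4, endian = "little")  # no further IFD
  v <- as.integer(t(pixels))
  # writeBin truncates via two's complement; map the upper unsigned range
  # explicitly so 16-bit values > 32767 survive the signed representation
  if (bits == 16L) v[v > 32767L] <- v[v > 32767L] - 65536L
  writeBin(v, con, size = bits / 8, endian = "little")
  invisible(NULL)
}

readPngGray <- function(path) {
  arr <- png::readPNG(path, info = TRUE)
  info <- attr(arr, "info")
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] > 1)
      lgStop(sprintf("multi-channel image (%d channels); %s", dim(arr)[3],
                     "only single-channel grayscale is supported"),
             "lg_multichannel_error")
    arr <- arr[, , 1]
  }
  bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  list(pixels = round(arr * (2^bits - 1)), containerBits = as.integer(bits))
}

#' Read a grayscale raster image
#'
#' Reads a single-channel TIFF (uncompressed, 8/16-bit) or PNG image into an
#' [ImageGrid-class]. A 16-bit container whose values all fit in 12 bits
#' (<= 4095) is flagged as 12-bit data, the native depth of the digitized
#' radiographs this pipeline targets; otherwise the container depth is kept.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return An [ImageGrid-class].
#' @examples
#' f <- tempfile(fileext = ".tif")
#' writeImage(ImageGrid(matrix(c(0, 100, 200, 4095), 2, 2)), f)
#' readImage(f)
#' @seealso [writeImage()], [extractROI()]
#' @export
readImage <- function(path) {
  if (!file.exists(path))
    lgStop(sprintf("image file not found: %s", path), "lg_missing_file_error")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = readTiffGray(path),
    png = readPngGray(path),
    lgStop(sprintf("unsupported image format '.%s' (want TIFF or PNG)", ext),
           "lg_unsupported_format_error"))
  depth <- raw$containerBits
  if (depth == 16L && max(raw$pixels) <= 4095) depth <- 12L
  ImageGrid(raw$pixels, bitDepth = depth)
}

#' Write a grayscale raster image losslessly
#'
#' Writes an [ImageGrid-class] to disk. TIFF output is a 16-bit (or 8-bit
#' for `bitDepth <= 8`) uncompressed single-strip grayscale file; pixel
#' values are stored unscaled, so `readImage(writeImage(x))` is bit-exact.
#' PNG output is only available for images with `bitDepth <= 8`.
#'
#' @param image An [ImageGrid-class].
#' @param path Destination path; format chosen by extension.
#' @return Invisibly, `path`.
#' @seealso [readImage()]
#' @export
writeImage <- function(image, path) {
  stopifnot(is(image, "ImageGrid"))
  ok <- tryCatch({
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !dir.exists(dirname(path)))
    lgStop(sprintf("cannot write to '%s'", path), "lg_unwritable_error")
  ext <- tolower(tools::file_ext(path))
  bits <- if (image@bitDepth <= 8L) 8L else 16L
  if (ext %in% c("tif", "tiff")) {
    writeTiffGray(image@pixels, path, bits = bits)
  } else if (ext == "png") {
    if (bits > 8L)
      lgStop("PNG output supports only bit depth <= 8 here; use TIFF",
             "lg_unsupported_format_error")
    png::writePNG(image@pixels / 255, path)
  } else {
    lgStop(sprintf("unsupported image format '.%s' (want TIFF or PNG)", ext),
           "lg_unsupported_format_error")
  }
  invisible(path)
}
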