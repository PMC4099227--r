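test_that("ImageGrid validity enforces the representable gray-level range", {
  expect_s4_class(ImageGrid(matrix(c(0, 4095), 1, 2)), "ImageGrid")
  expect_error(ImageGrid(matrix(c(0, 4096), 1, 2), bitDepth = 12))
  expect_error(ImageGrid(matrix(-1, 1, 1)))
  expect_error(ImageGrid(matrix(1.5, 1, 1)))
  img8 <- ImageGrid(matrix(255, 1, 1), bitDepth = 8)
  expect_identical(bitDepth(img8), 8L)
  expect_identical(dim(ImageGrid(matrix(0, 5, 7))), c(5L, 7L))
})

test_that("TIFF write/read round trip is bit-exact and infers 12-bit depth", {
  f <- withr::local_tempfile(fileext = ".tif")
  img <- ImageGrid(matrix(c(0, 100, 200, 4095), 2, 2))
  writeImage(img, f)
  back <- readImage(f)
  expect_identical(imagePixels(back), imagePixels(img))
  expect_identical(bitDepth(back), 12L)

  # random 12-bit grid, including extremes of the range
  set.seed(42)
  g <- randomGrid(40, 50)
  g[1, 1] <- 0; g[2, 2] <- 4095
  f2 <- withr::local_tempfile(fileext = ".tif")
  writeImage(ImageGrid(g), f2)
  expect_identical(imagePixels(readImage(f2)), g + 0)

  # 16-bit container with values above 4095 keeps container depth
  f3 <- withr::local_tempfile(fileext = ".tif")
  writeImage(ImageGrid(matrix(c(0, 60000), 1, 2), bitDepth = 16), f3)
  expect_identical(bitDepth(readImage(f3)), 16L)
})

test_that("our TIFF container round-trips through an independent reader", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  set.seed(7)
  g <- randomGrid(9, 11)
  f <- withr::local_tempfile(fileext = ".tif")
  writeImage(ImageGrid(g), f)
  out <- withr::local_tempfile(fileext = ".csv")
  script <- sprintf(
    "import tifffile, numpy as np; a = tifffile.imread(%s); np.savetxt(%s, a.astype(int), fmt='%%d', delimiter=',')",
    shQuote(f), shQuote(out))
  status <- system2(py, c("-c", shQuote(script)))
  expect_identical(status, 0L)
  a <- as.matrix(utils::read.csv(out, header = FALSE))
  expect_equal(unname(a), g, ignore_attr = TRUE)

  # and the reverse: a file written by tifffile reads back identically
  f2 <- withr::local_tempfile(fileext = ".tif")
  script2 <- sprintf(
    "import tifffile, numpy as np; a = np.loadtxt(%s, delimiter=',').astype('uint16'); tifffile.imwrite(%s, a)",
    shQuote(out), shQuote(f2))
  expect_identical(system2(py, c("-c", shQuote(script2))), 0L)
  expect_equal(imagePixels(readImage(f2)), g, ignore_attr = TRUE)
})

test_that("PNG reading recovers gray levels and rejects multi-channel", {
  f <- withr::local_tempfile(fileext = ".png")
  g <- matrix(c(0, 63, 128, 255), 2, 2)
  png::writePNG(g / 255, f)
  img <- readImage(f)
  expect_equal(imagePixels(img), g, ignore_attr = TRUE)
  expect_identical(bitDepth(img), 8L)

  frgb <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(12), dim = c(2, 2, 3)), frgb)
  expect_error(readImage(frgb), class = "lg_multichannel_error")
})

test_that("readImage raises named errors for missing/unsupported files", {
  expect_error(readImage("no/such/file.tif"), class = "lg_missing_file_error")
  f <- withr::local_tempfile(fileext = ".bmp")
  writeLines("x", f)
  expect_error(readImage(f), class = "lg_unsupported_format_error")
  ftxt <- withr::local_tempfile(fileext = ".tif")
  writeBin(charToRaw("notatiff"), ftxt)
  expect_error(readImage(ftxt), class = "lg_unsupported_format_error")
})

test_that("extractROI follows the 0-based half-open convention exactly", {
  img <- ImageGrid(matrix(1:9, 3, 3, byrow = TRUE))
  sub <- extractROI(img, ROISpec(1, 1, 2, 2))
  expect_equal(imagePixels(sub), matrix(c(5, 6, 8, 9), 2, 2, byrow = TRUE))

  # whole-image ROI is the identity
  whole <- extractROI(img, ROISpec(0, 0, 3, 3))
  expect_identical(imagePixels(whole), imagePixels(img))

  # restriction property on a random image/ROI pair
  set.seed(1)
  g <- randomGrid(50, 40)
  roi <- ROISpec(x0 = 5, y0 = 7, width = 20, height = 30)
  out <- imagePixels(extractROI(ImageGrid(g), roi))
  expect_identical(dim(out), c(30L, 20L))
  expect_identical(out, g[8:37, 6:25] + 0)
})

test_that("extractROI names the offending edge on out-of-bounds requests", {
  img <- ImageGrid(randomGrid(50, 40))  # 50 rows x 40 cols
  expect_error(extractROI(img, ROISpec(0, 0, 41, 50)),
               regexp = "right", class = "lg_bounds_error")
  expect_error(extractROI(img, ROISpec(0, 0, 40, 51)),
               regexp = "bottom", class = "lg_bounds_error")
  expect_error(extractROI(img, ROISpec(35, 45, 10, 10)),
               class = "lg_bounds_error")
})

test_that("ROI manifest loading validates structure, enums and rows", {
  d <- withr::local_tempdir()
  f <- file.path(d, "manifest.csv")
  writeLines(c("image_path,x0,y0,width,height,group,bone_class,case_id",
               "a.tif,0,0,40,50,MM,flat,c1",
               "b.tif,3,4,40,50,OL,nonflat,c2"), f)
  m <- loadROIManifest(f)
  expect_identical(nrow(m), 2L)
  expect_identical(m$group, c("MM", "OL"))
  expect_identical(m$x0, c(0L, 3L))

  writeLines(c("image_path,x0,y0,width,height,group,bone_class,case_id"), f)
  expect_identical(nrow(loadROIManifest(f)), 0L)

  writeLines(c("image_path,x0,y0,width,height,group,bone_class,case_id",
               "a.tif,0,0,40,50,MM,flat,c1",
               "b.tif,0,0,40,50,XX,flat,c2"), f)
  expect_error(loadROIManifest(f), regexp = "row 2",
               class = "lg_manifest_error")

  writeLines(c("image_path,x0,y0,width,height,group,bone_class,case_id",
               "a.tif,0,0,40,50,MM,round,c1"), f)
  expect_error(loadROIManifest(f), regexp = "row 1",
               class = "lg_manifest_error")

  writeLines(c("path,x0,y0,width,height,group,bone_class,case_id",
               "a.tif,0,0,40,50,MM,flat,c1"), f)
  expect_error(loadROIManifest(f), class = "lg_manifest_error")
})
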