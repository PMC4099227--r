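test_that("group presets carry the published calibration values", {
  p <- groupPresets()
  expect_setequal(names(p), c("MM1", "OL1", "MM2", "OL2"))
  expect_equal(p$MM2@mglMean, 1593.21)
  expect_equal(p$MM2@mglSd, 140.87)
  expect_equal(p$OL2@mglMean, 1744.53)
  expect_equal(p$OL2@sdglMean, 270.66)
  expect_equal(p$OL2@sdglSd, 16.80)
  expect_equal(p$MM1@cvglMean, 15.02)
  expect_equal(p$OL1@cvglMean, 16.14)
  expect_identical(vapply(p, slot, integer(1), "nCases"),
                   c(MM1 = 31L, OL1 = 35L, MM2 = 36L, OL2 = 41L))
})

test_that("case generation is a pure function of (params, seed)", {
  p <- groupPresets()$MM2
  a <- generateGroupCases(p, seed = 7)
  b <- generateGroupCases(p, seed = 7)
  expect_identical(a, b)
  expect_identical(nrow(a), 36L)
  expect_false(identical(a$mgl, generateGroupCases(p, seed = 8)$mgl))
  expect_identical(nrow(generateGroupCases(p, seed = 1, nCases = 0)), 0L)
  # derived CV matches its definition per case
  expect_equal(a$cvgl, a$sdgl / a$mgl * 100)
  # truncation honors the published sanity range
  tr <- generateGroupCases(p, seed = 3, nCases = 2000, truncate = TRUE)
  expect_true(all(tr$mgl >= p@mglRange[1] & tr$mgl <= p@mglRange[2]))
})

test_that("large-sample case means recover the preset moments", {
  p <- groupPresets()$MM2
  cases <- generateGroupCases(p, seed = 123, nCases = 10000)
  expect_lt(abs(mean(cases$mgl) - 1593.21), 3 * 140.87 / sqrt(10000))
  expect_lt(abs(mean(cases$sdgl) - 248.12), 3 * 9.51 / sqrt(10000))
  expect_lt(abs(sd(cases$mgl) - 140.87), 5 * 140.87 / sqrt(2 * 10000))
})

test_that("rendered ROI images hit their first-order targets", {
  img <- renderROIImage(1593.21, 248.12, 50, 40, seed = 5)
  expect_identical(dim(img), c(50L, 40L))
  f <- computeGrayFeatures(imagePixels(img))
  expect_lt(abs(f$mgl - 1593.21), 3 * 248.12 / sqrt(2000))
  expect_lt(abs(f$sdgl - 248.12), 3 * 248.12 / sqrt(2 * 2000))

  expect_identical(imagePixels(renderROIImage(1000, 20, 10, 10, seed = 9)),
                   imagePixels(renderROIImage(1000, 20, 10, 10, seed = 9)))
  flat <- renderROIImage(1500.4, 0, 5, 5, seed = 1)
  expect_true(all(imagePixels(flat) == 1500))
  expect_error(renderROIImage(0, 10, 5, 5, seed = 1),
               class = "lg_param_error")
})

test_that("radiograph scenes are deterministic with a radiolucent lesion", {
  cfg <- SceneConfig(seed = 11)
  s1 <- generateRadiographScene(cfg)
  s2 <- generateRadiographScene(cfg)
  expect_identical(imagePixels(s1$image), imagePixels(s2$image))

  # lesion ROI is darker than the surrounding bone band
  roiVals <- imagePixels(extractROI(s1$image, s1$roi))
  band <- imagePixels(s1$image)[cfg@boneRows[1]:cfg@boneRows[2], 1:15]
  expect_lt(mean(roiVals), mean(band))

  # noiseless, gradient-free scene is piecewise constant with exact levels
  quiet <- generateRadiographScene(SceneConfig(
    gradientAmplitude = 0, noiseSd = 0, lesionSdgl = 0,
    lesionMgl = 1600, seed = 2))
  px <- imagePixels(quiet$image)
  expect_setequal(unique(as.vector(px)), c(900, 2000, 1600))
  center <- px[64, 64]
  expect_identical(center, 1600)

  expect_error(SceneConfig(lesionCenter = c(5, 5), lesionAxes = c(30, 30)))
})

test_that("scene -> ROI -> diffusion -> features recovers the lesion level", {
  cfg <- SceneConfig(lesionMgl = 1600, lesionSdgl = 120, seed = 21)
  scene <- generateRadiographScene(cfg)
  roi <- extractROI(scene$image, scene$roi)
  # the ground-truth ROI is purely lesional and diffusion conserves the
  # mean, so MGL should match within sampling error (plus rounding)
  n <- prod(dim(roi))
  filtered <- anisotropicDiffusion(roi, DiffusionParams())
  f <- computeGrayFeatures(filtered)
  expect_lt(abs(f$mgl - 1600), 5 * 120 / sqrt(n) + 1)
  # and diffusion left the ROI mean exactly at the raw ROI mean
  expect_equal(f$mgl, mean(imagePixels(roi)), tolerance = 1e-12)
})

test_that("group means across many synthetic studies are unbiased", {
  p <- groupPresets()
  nStudies <- 200
  for (label in c("MM2", "OL2")) {
    prm <- p[[label]]
    means <- vapply(seq_len(nStudies), function(s)
      mean(generateGroupCases(prm, seed = deriveSeed(1000, "study", s))$mgl),
      numeric(1))
    # t-test of zero bias at alpha = 0.01
    tt <- t.test(means, mu = prm@mglMean)
    expect_gt(tt$p.value, 0.01)
    sdMeans <- vapply(seq_len(nStudies), function(s)
      mean(generateGroupCases(prm, seed = deriveSeed(1000, "study", s))$sdgl),
      numeric(1))
    expect_gt(t.test(sdMeans, mu = prm@sdglMean)$p.value, 0.01)
  }
})

test_that("simulated flat-bone AUCs match the binormal closed form", {
  p <- groupPresets()
  for (feat in c("mgl", "sdgl")) {
    mc <- simulateFeatureAUC(p$OL2, p$MM2, feat, nReps = 400, seed = 42)
    target <- binormalAUC(
      slot(p$OL2, paste0(feat, "Mean")), slot(p$OL2, paste0(feat, "Sd")),
      slot(p$MM2, paste0(feat, "Mean")), slot(p$MM2, paste0(feat, "Sd")))
    expect_lt(abs(mc$meanAUC - target), 3 * mc$mcSE)
  }
})
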