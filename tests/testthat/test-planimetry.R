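test_that("PNG I/O is a lossless round trip", {
  px <- array(0L, dim = c(2, 2, 3))
  px[1, 1, ] <- c(0L, 0L, 0L)
  px[1, 2, ] <- c(255L, 0L, 0L)
  px[2, 1, ] <- c(0L, 0L, 255L)
  px[2, 2, ] <- c(200L, 200L, 200L)
  img <- RasterImage(px)
  path <- tempfile(fileext = ".png")
  writeToothImage(img, path, "png")
  back <- readToothImage(path)
  expect_identical(pixelArray(back), px)

  rimg <- randomImage(64, 64, seed = 101)
  p2 <- tempfile(fileext = ".png")
  writeToothImage(rimg, p2, "png")
  expect_identical(pixelArray(readToothImage(p2)), pixelArray(rimg))
})

test_that("JPEG round trip perturbs pixels and the black matte", {
  sc <- generateScene(sceneSpec(targetFraction = 0.25, seed = 9))
  jp <- tempfile(fileext = ".jpg")
  writeToothImage(sc@image, jp, "jpeg", quality = 0.95)
  back <- readToothImage(jp)
  dev <- max(abs(pixelArray(back) - pixelArray(sc@image)))
  expect_gt(dev, 0)        # lossy
  expect_lt(dev, 128)      # but bounded at quality 95
  bg <- sc@truthMask == 0L
  # some matte pixels are no longer exactly (0,0,0)
  expect_lt(mean(pixelArray(back)[array(bg, dim = c(dim(bg), 3))] == 0L), 1)

  cfg <- calibrateRedThreshold(sc@image)
  pPng <- measurePlaque(sc@image, cfg)@pPercent
  driftTol0 <- abs(measurePlaque(back, cfg)@pPercent - pPng)
  cfg8 <- thresholdConfig(cfg@redMin, blackTol = 8)
  driftTol8 <- abs(measurePlaque(back, cfg8)@pPercent - pPng)
  expect_lt(driftTol8, 3)            # bounded drift with matte tolerance
  expect_gt(driftTol0, driftTol8)    # exact-black rule suffers from JPEG halo
})

test_that("alpha channels are rejected unless fully opaque; grayscale promoted", {
  arr <- array(runif(16 * 16 * 4), dim = c(16, 16, 4))
  arr[, , 4] <- 1
  ok <- tempfile(fileext = ".png")
  png::writePNG(arr, ok)
  expect_s4_class(readToothImage(ok), "RasterImage")

  arr[3, 3, 4] <- 0.5
  bad <- tempfile(fileext = ".png")
  png::writePNG(arr, bad)
  expect_error(readToothImage(bad), "alpha")

  gray <- matrix(seq(0, 1, length.out = 64), 8, 8)
  gp <- tempfile(fileext = ".png")
  png::writePNG(gray, gp)
  gi <- readToothImage(gp)
  expect_identical(pixelArray(gi)[, , 1], pixelArray(gi)[, , 2])
  expect_identical(pixelArray(gi)[, , 1], pixelArray(gi)[, , 3])

  expect_error(readToothImage(tempfile()), "not found")
})

test_that("classification follows the two-filter rule", {
  px <- array(0L, dim = c(1, 3, 3))
  px[1, 1, ] <- c(0L, 0L, 0L)
  px[1, 2, ] <- c(130L, 40L, 60L)
  px[1, 3, ] <- c(100L, 200L, 200L)
  img <- RasterImage(px)
  cm <- classifyPixels(img, thresholdConfig(redMin = 120))
  expect_identical(as.vector(cm@labels), c(0L, 1L, 2L))

  # vacuous threshold: every non-background pixel is plaque
  cm0 <- classifyPixels(img, thresholdConfig(redMin = 0))
  expect_identical(as.vector(cm0@labels), c(0L, 1L, 1L))

  # threshold 256 can never be reached
  cm256 <- classifyPixels(img, thresholdConfig(redMin = 256))
  expect_identical(sum(cm256@labels == 1L), 0L)
})

test_that("classification equals the per-pixel loop oracle", {
  cfgs <- list(
    thresholdConfig(redMin = 120),
    thresholdConfig(redMin = 90, greenMin = 40, blueMin = 10),
    thresholdConfig(redMin = 100, blackTol = 8),
    thresholdConfig(redMin = 0.45, channelMode = "normalized"),
    thresholdConfig(redMin = 0.4, greenMin = 0.2, channelMode = "normalized",
                    blackTol = 8))
  for (s in 1:3) {
    img <- randomImage(64, 64, seed = 200 + s)
    for (cfg in cfgs) {
      got <- classifyPixels(img, cfg)@labels
      expect_identical(got, oracleClassify(img, cfg))
      expect_identical(sum(labelCounts(classifyPixels(img, cfg))),
                       64L * 64L)  # count conservation
    }
  }
})

test_that("P% is plaque over tooth pixels and empty crops error", {
  px <- array(0L, dim = c(10, 20, 3))
  px[1:10, 1:10, 1] <- 200L   # 100 tooth pixels, red only
  px[1:5, 1:5, 2] <- 10L
  img <- RasterImage(px)
  res <- measurePlaque(img, thresholdConfig(redMin = 100, greenMin = 5))
  expect_identical(res@nTooth, 100L)
  expect_identical(res@nPlaque, 25L)
  expect_equal(res@pPercent, 25)
  expect_identical(res@nBackground + res@nTooth, res@nTotal)

  all_in <- measurePlaque(img, thresholdConfig(redMin = 100))
  expect_equal(all_in@pPercent, 100)

  black <- RasterImage(array(0L, dim = c(8, 8, 3)))
  expect_error(measurePlaque(black, thresholdConfig(redMin = 100)),
               "empty crop")
})

test_that("overlay turns clean pixels blue, keeps plaque, stays black", {
  img <- randomImage(32, 32, seed = 77)
  cfg <- thresholdConfig(redMin = 140)
  cm <- classifyPixels(img, cfg)
  ov <- renderOverlay(img, cm)
  px <- pixelArray(img); po <- pixelArray(ov)
  clean <- cm@labels == 2L; plaque <- cm@labels == 1L; bg <- cm@labels == 0L
  expect_true(all(po[, , 1][clean] == 0L & po[, , 2][clean] == 0L &
                    po[, , 3][clean] == 255L))
  for (ch in 1:3) {
    expect_identical(po[, , ch][plaque], px[, , ch][plaque])
    expect_true(all(po[, , ch][bg] == 0L))
  }
  # blue pixels never classify as plaque for any positive red threshold
  cm2 <- classifyPixels(ov, cfg)
  expect_identical(cm2@labels == 1L, cm@labels == 1L)

  # with zero clean pixels the overlay is the identity
  cmAll <- classifyPixels(img, thresholdConfig(redMin = 0))
  expect_identical(pixelArray(renderOverlay(img, cmAll)), px)

  small <- classifyPixels(randomImage(8, 8, seed = 1),
                          thresholdConfig(redMin = 10))
  expect_error(renderOverlay(img, small), "dimensions")
})

test_that("threshold sweep is a non-increasing step curve", {
  img <- randomImage(48, 48, seed = 5)
  sw <- thresholdSweep(img, c(0, 64, 128, 192, 256))
  expect_equal(sw$p_percent[1], 100)
  expect_equal(sw$p_percent[5], 0)
  expect_true(all(diff(sw$p_percent) <= 0))

  # image whose tooth pixels all share one red value: a pure step function
  px <- array(0L, dim = c(6, 6, 3))
  px[2:5, 2:5, 1] <- 137L
  px[2:5, 2:5, 2] <- 20L
  step <- thresholdSweep(RasterImage(px), c(100, 137, 138, 200))
  expect_equal(step$p_percent, c(100, 100, 0, 0))

  expect_error(thresholdSweep(img, c(10, 5)), "increasing")
  black <- RasterImage(array(0L, dim = c(4, 4, 3)))
  expect_error(thresholdSweep(black, c(0, 10)), "empty crop")
})

test_that("batch measurement matches element-wise measurement", {
  imgs <- list(a = randomImage(24, 24, seed = 11),
               b = randomImage(24, 24, seed = 12),
               c = randomImage(24, 24, seed = 13))
  cfg <- thresholdConfig(redMin = 130)
  over <- list(b = thresholdConfig(redMin = 60),
               c = thresholdConfig(redMin = 0.5, channelMode = "normalized"))

  res <- batchMeasure(imgs, cfg)
  expect_identical(res$id, c("a", "b", "c"))
  for (i in 1:3)
    expect_equal(res$p_percent[i], measurePlaque(imgs[[i]], cfg)@pPercent)

  resO <- batchMeasure(imgs, cfg, overrides = over)
  expect_equal(resO$p_percent[1], measurePlaque(imgs$a, cfg)@pPercent)
  expect_equal(resO$p_percent[2], measurePlaque(imgs$b, over$b)@pPercent)
  expect_equal(resO$p_percent[3], measurePlaque(imgs$c, over$c)@pPercent)

  # permutation invariance per id
  perm <- batchMeasure(imgs[c("c", "a", "b")], cfg)
  expect_equal(perm$p_percent[match(res$id, perm$id)], res$p_percent)

  expect_error(batchMeasure(setNames(imgs, c("a", "a", "b")), cfg),
               "duplicate")

  # an empty crop is reported per id, not fatal
  imgs$black <- RasterImage(array(0L, dim = c(4, 4, 3)))
  resB <- batchMeasure(imgs, cfg)
  expect_true(is.na(resB$p_percent[resB$id == "black"]))
  expect_match(resB$error[resB$id == "black"], "empty crop")
  expect_false(anyNA(resB$p_percent[resB$id != "black"]))
})

test_that("PNG round trip leaves the planimetry result unchanged", {
  sc <- generateScene(sceneSpec(targetFraction = 0.3, seed = 21))
  cfg <- calibrateRedThreshold(sc@image)
  before <- measurePlaque(sc@image, cfg)
  path <- tempfile(fileext = ".png")
  writeToothImage(sc@image, path, "png")
  after <- measurePlaque(readToothImage(path), cfg)
  expect_identical(as.data.frame(before), as.data.frame(after))
})
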