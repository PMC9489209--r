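# Spot detection, sub-pixel localization, linking and QC.

# noise-free single-spot frame via the renderer
renderSpotFrame <- function(x_um, y_um, shape = c(32L, 32L), peak = 50,
                            bg = 100, noise = "none") {
  ts <- trajectorySet(data.frame(cell_id = "s", condition = "x", frame = 0L,
                                 t_s = 0, x_um = 0, y_um = 0), 0.1)
  mv <- renderMovie(ts, imageShape = shape, spotPeak = peak,
                    backgroundMean = bg, noiseModel = noise,
                    origins = matrix(c(x_um, y_um), 1))
  mv@pixels[, , 1]
}

test_that("a rendered high-SNR spot yields exactly one detection within 1 px", {
  set.seed(81)
  px <- 0.108
  img <- renderSpotFrame(15 * px, 11 * px, peak = 10 * sqrt(100),
                         noise = "poisson")
  det <- detectSpots(img)
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$x_px - 15), 1)
  expect_lt(abs(det$y_px - 11), 1)
  expect_gt(det$snr, 5)
})

test_that("zero spots means a pure background stack and zero detections", {
  set.seed(82)
  misses <- vapply(1:300, function(i) {
    img <- matrix(rpois(48 * 48, 100), 48, 48)
    nrow(detectSpots(img)) == 0L
  }, TRUE)
  expect_gte(mean(misses), 0.97)
  # constant and empty images are not errors
  expect_identical(nrow(detectSpots(matrix(5, 16, 16))), 0L)
})

test_that("two well-separated spots give two detections", {
  ts <- trajectorySet(data.frame(cell_id = c("a", "b"), condition = "x",
                                 frame = 0L, t_s = 0, x_um = 0, y_um = 0),
                      0.1)
  s <- 1.2 * 0.108  # PSF sigma in um
  mv <- renderMovie(ts, imageShape = c(40L, 40L), spotPeak = 80,
                    noiseModel = "none",
                    origins = matrix(c(1.0, 1.0, 1.0 + 10 * s, 1.0), 2,
                                     byrow = TRUE))
  expect_identical(nrow(detectSpots(mv@pixels[, , 1])), 2L)
})

test_that("sub-pixel localization is accurate and symmetric", {
  img <- renderSpotFrame(10.30 * 0.108, 7.70 * 0.108)
  det <- detectSpots(img)
  loc <- localizeSubpixel(img, det[1, ])
  expect_lt(abs(loc$x_px - 10.30), 0.05)
  expect_lt(abs(loc$y_px - 7.70), 0.05)

  imgC <- renderSpotFrame(16 * 0.108, 16 * 0.108)
  locC <- localizeSubpixel(imgC, detectSpots(imgC)[1, ])
  expect_lt(abs(locC$x_px - 16), 1e-6)
  expect_lt(abs(locC$y_px - 16), 1e-6)
})

test_that("localization error at SNR 3 stays within 2x the photon bound", {
  set.seed(83)
  bg <- 100
  peak <- 3 * sqrt(bg)
  sPx <- 1.2
  peakFrac <- (pnorm(0.5 / sPx) - pnorm(-0.5 / sPx))^2
  nPhot <- peak / peakFrac
  bound <- oracleLocalizationBound(sPx, nPhot, bgVar = bg)
  errs <- replicate(500, {
    x0 <- 14 + runif(1, -0.5, 0.5)
    img <- renderSpotFrame(x0 * 0.108, 14 * 0.108, peak = peak,
                           noise = "poisson")
    spot <- data.frame(x_px = round(x0), y_px = 14, peak = img[15, round(x0) + 1],
                       bgMean = bg, bgSd = sqrt(bg), snr = 3, response = 1)
    loc <- localizeSubpixel(img, spot)
    loc$x_px - x0
  })
  rmse <- sqrt(mean(errs^2))
  expect_lt(rmse, 2 * bound)
})

test_that("linking separates, bridges gaps and splits on jumps as specified", {
  p <- trackingParams(maxLinkDisplacement = 0.5, maxGapFrames = 2L)
  # two stationary spots 5 um apart over 10 frames
  det <- data.frame(frame = rep(0:9, each = 2),
                    x_um = rep(c(0, 5), 10), y_um = 0)
  ts <- linkSpots(det, p)
  expect_identical(nCells(ts), 2L)
  expect_true(all(table(trajectoryData(ts)$cell_id) == 10))

  # one spot missing a single frame is bridged, the gap not interpolated
  det2 <- data.frame(frame = c(0:3, 5:9), x_um = 0.01 * c(0:3, 5:9), y_um = 0)
  ts2 <- linkSpots(det2, p)
  expect_identical(nCells(ts2), 1L)
  expect_false(4L %in% trajectoryData(ts2)$frame)

  # a jump of 2x the limit starts a new trajectory
  det3 <- data.frame(frame = 0:9, x_um = c(rep(0, 5), rep(1.0, 5)), y_um = 0)
  ts3 <- linkSpots(det3, p)
  expect_identical(nCells(ts3), 2L)
})

test_that("linking is invariant to detection order and never reuses a frame", {
  set.seed(84)
  det <- do.call(rbind, lapply(0:19, function(f) {
    data.frame(frame = f,
               x_um = c(1, 3, 5) + rnorm(3, 0, 0.05),
               y_um = c(2, 2, 2) + rnorm(3, 0, 0.05))
  }))
  ts1 <- linkSpots(det, trackingParams())
  ts2 <- linkSpots(det[sample(nrow(det)), ], trackingParams())
  expect_identical(trajectoryData(ts1), trajectoryData(ts2))
  perCellFrames <- split(trajectoryData(ts1)$frame, trajectoryData(ts1)$cell_id)
  expect_true(all(vapply(perCellFrames, anyDuplicated, 0L) == 0L))
  expect_identical(nCells(ts1), 3L)
})

test_that("QC keeps boundary cases inclusively and reports reasons", {
  p <- trackingParams(minTrackLength = 5L, minMeanSnr = 2)
  mk <- function(id, n, snr) data.frame(cell_id = id, condition = "x",
                                        frame = 0:(n - 1), t_s = 0:(n - 1) * 0.1,
                                        x_um = 0, y_um = 0, snr = snr)
  ts <- trajectorySet(rbind(mk("long_ok", 5L, 2.0),     # both exactly at threshold
                            mk("short", 4L, 9),
                            mk("dim", 6L, 1.5)), 0.1)
  res <- qcFilter(ts, p)
  expect_identical(cellIds(res$kept), "long_ok")
  qc <- qcFlags(res$rejected)
  expect_identical(qc$reason[qc$cell_id == "short"], "length")
  expect_identical(qc$reason[qc$cell_id == "dim"], "snr")

  allPass <- trajectorySet(mk("fine", 10L, 5), 0.1)
  res2 <- qcFilter(allPass, p)
  expect_identical(trajectoryData(res2$kept), trajectoryData(allPass))
  expect_identical(nrow(trajectoryData(res2$rejected)), 0L)
})

test_that("rendering places the peak at the rounded ground-truth pixel", {
  img <- renderSpotFrame(20 * 0.108, 9 * 0.108)
  hit <- which(img == max(img), arr.ind = TRUE)
  expect_identical(as.integer(hit[1, "col"]) - 1L, 20L)
  expect_identical(as.integer(hit[1, "row"]) - 1L, 9L)

  # positions outside the image are clipped with a warning and flagged
  ts <- trajectorySet(data.frame(cell_id = "s", condition = "x", frame = 0L,
                                 t_s = 0, x_um = 0, y_um = 0), 0.1)
  expect_warning(
    mv <- renderMovie(ts, imageShape = c(16L, 16L), noiseModel = "none",
                      origins = matrix(c(5, 5), 1)),
    "clipped")
  expect_true("clipped" %in% qcFlags(groundTruth(mv))$reason)
})
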