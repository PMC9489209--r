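# MSD estimator, population averaging, power-law fitting, summary lags.

test_that("non-overlapping MSD matches the hand-enumerated example", {
  d <- data.frame(cell_id = "c", condition = "demo", frame = 0:4,
                  t_s = 0:4, x_um = c(0, 1, 1, 2, 2), y_um = c(0, 0, 1, 1, 2))
  cv <- trajectoryMSD(trajectorySet(d, 1), maxLag = 4)[["c"]]
  expect_equal(msdValues(cv)[lagTimes(cv) == 1], 1.0)
  expect_equal(msdValues(cv)[lagTimes(cv) == 2], 2.0)
  expect_equal(msdValues(cv)[lagTimes(cv) == 4], 8.0)
  expect_equal(intervalCounts(cv), c(4, 2, 1, 1))
})

test_that("trajectory MSD equals brute-force enumeration on random gappy tracks", {
  set.seed(71)
  for (i in 1:100) {
    d <- randomGappyTrajectory(sprintf("r%03d", i))
    ts <- trajectorySet(d, 0.5)
    lagSteps <- 1:6
    cv <- trajectoryMSD(ts, maxLag = 3, lags = lagSteps * 0.5)[[1]]
    ref <- oracleMSD(d$frame, d$x_um, d$y_um, lagSteps)
    refN <- oracleMSDCounts(d$frame, d$x_um, d$y_um, lagSteps)
    keep <- refN > 0L
    expect_equal(msdValues(cv), ref[keep], tolerance = 1e-12)
    expect_equal(intervalCounts(cv), as.numeric(refN[keep]))
  }
})

test_that("degenerate motions give their closed-form MSD", {
  still <- stationarySet(nFrames = 50L)
  expect_true(all(msdValues(trajectoryMSD(still, maxLag = 2)[[1]]) == 0))

  k <- 0:99
  ball <- trajectorySet(data.frame(cell_id = "v", condition = "ballistic",
                                   frame = k, t_s = k, x_um = k, y_um = 0),
                        1)
  cv <- trajectoryMSD(ball, maxLag = 20)[[1]]
  expect_equal(msdValues(cv), lagTimes(cv)^2, tolerance = 1e-12)
  fit <- fitPowerLaw(cv, window = c(1, 20))
  expect_equal(alphaExponent(fit), 2, tolerance = 1e-10)
})

test_that("interval counts never increase with lag on gap-free tracks", {
  set.seed(72)
  k <- 0:199
  d <- data.frame(cell_id = "g", condition = "x", frame = k, t_s = k * 0.1,
                  x_um = cumsum(rnorm(200)), y_um = cumsum(rnorm(200)))
  cv <- trajectoryMSD(trajectorySet(d, 0.1), maxLag = 10)[[1]]
  expect_true(all(diff(intervalCounts(cv)) <= 0))
  expect_equal(intervalCounts(cv), floor(199 / seq_len(100)))
})

test_that("offset-averaged segmentation agrees at lag 1 and pools more intervals", {
  set.seed(73)
  k <- 0:120
  d <- data.frame(cell_id = "o", condition = "x", frame = k, t_s = k,
                  x_um = cumsum(rnorm(121)), y_um = cumsum(rnorm(121)))
  ts <- trajectorySet(d, 1)
  a <- trajectoryMSD(ts, maxLag = 10)[[1]]
  o <- trajectoryMSD(ts, maxLag = 10, segmentation = "offset")[[1]]
  expect_equal(msdValues(o)[1], msdValues(a)[1])
  expect_true(all(intervalCounts(o) >= intervalCounts(a)))
})

test_that("population averaging weights each trajectory once", {
  mk <- function(id, msd, lags = seq_along(msd)) {
    methods::new("MSDCurve", lags = lags, msd = msd,
                 nIntervals = rep(1, length(msd)),
                 nTrajectories = rep(1, length(msd)), level = "trajectory",
                 frameInterval = 1, cellId = id, condition = "c")
  }
  p <- populationMSD(list(mk("a", c(1, 2)), mk("b", c(3, 4))))
  expect_equal(msdValues(p), c(2, 3))

  same <- populationMSD(list(mk("a", c(1, 2)), mk("b", c(1, 2))))
  expect_equal(msdValues(same), c(1, 2))

  long <- mk("a", 1:10)
  short <- mk("b", 2 * (1:5), lags = 1:5)
  p2 <- populationMSD(list(long, short))
  expect_equal(p2@nTrajectories, c(rep(2, 5), rep(1, 5)))
  expect_equal(msdValues(p2)[6:10], 6:10)   # lags 6..10 from curve a only
  expect_error(populationMSD(list()), "no MSD curves")
})

test_that("power-law fit reproduces hand OLS on logs", {
  cv <- methods::new("MSDCurve", lags = c(1, 2, 4), msd = c(1, 2, 8),
                     nIntervals = c(4, 2, 1), nTrajectories = rep(1, 3),
                     level = "trajectory", frameInterval = 1, cellId = "c",
                     condition = "")
  fit <- fitPowerLaw(cv, window = c(1, 4))
  # closed-form least squares on (log t, log msd)
  xv <- log(c(1, 2, 4)); yv <- log(c(1, 2, 8))
  slope <- sum((xv - mean(xv)) * (yv - mean(yv))) / sum((xv - mean(xv))^2)
  inter <- mean(yv) - slope * mean(xv)
  expect_equal(alphaExponent(fit), slope, tolerance = 1e-12)
  expect_equal(amplitude(fit), exp(inter), tolerance = 1e-12)
  expect_equal(alphaExponent(fit), 1.50, tolerance = 0.01)
  expect_equal(amplitude(fit), 0.89, tolerance = 0.01)
})

test_that("an exact power law is recovered to machine precision", {
  lags <- seq(0.1, 10, by = 0.1)
  cv <- methods::new("MSDCurve", lags = lags, msd = 0.01231 * lags^0.6,
                     nIntervals = rep(1, length(lags)),
                     nTrajectories = rep(1, length(lags)),
                     level = "population", frameInterval = 0.1, cellId = "",
                     condition = "")
  fit <- fitPowerLaw(cv)
  expect_equal(alphaExponent(fit), 0.6, tolerance = 1e-10)
  expect_equal(amplitude(fit), 0.01231, tolerance = 1e-10)
  expect_equal(fit@rSquared, 1, tolerance = 1e-10)
  nls <- fitPowerLaw(cv, method = "nls")
  expect_equal(alphaExponent(nls), 0.6, tolerance = 1e-6)
})

test_that("fit window and degenerate inputs are handled", {
  lags <- seq(0.1, 20, by = 0.1)
  cv <- methods::new("MSDCurve", lags = lags, msd = 0.02 * lags^0.5,
                     nIntervals = rep(1, length(lags)),
                     nTrajectories = rep(1, length(lags)),
                     level = "population", frameInterval = 0.1, cellId = "",
                     condition = "")
  fit <- fitPowerLaw(cv, window = c(0.1, 10))
  expect_equal(fit@nPoints, 100L)           # lags beyond 10 s excluded
  few <- methods::new("MSDCurve", lags = c(1, 2), msd = c(1, 2),
                      nIntervals = c(1, 1), nTrajectories = c(1, 1),
                      level = "trajectory", frameInterval = 1, cellId = "c",
                      condition = "")
  expect_error(fitPowerLaw(few, window = c(1, 2)), "fewer than 3")
  d <- data.frame(cell_id = "c", condition = "x", frame = 0:3, t_s = 0:3,
                  x_um = c(0, 1, 1, 2), y_um = 0)
  expect_error(trajectoryMSD(trajectorySet(d, 1), maxLag = 0.5), "maxLag")
})

test_that("msdAtLag returns grid values and is exact on power laws off-grid", {
  lags <- seq(0.1, 10, by = 0.1)
  cv <- methods::new("MSDCurve", lags = lags, msd = 0.01 * lags^0.5,
                     nIntervals = rep(1, length(lags)),
                     nTrajectories = rep(1, length(lags)),
                     level = "population", frameInterval = 0.1, cellId = "",
                     condition = "")
  expect_equal(msdAtLag(cv, 10), 0.01 * 10^0.5, tolerance = 1e-12)
  expect_equal(msdAtLag(cv, 0.15), 0.01 * 0.15^0.5, tolerance = 1e-9)
  expect_error(msdAtLag(cv, 11), "outside")

  fixed <- methods::new("MSDCurve", lags = 10, msd = 0.049,
                        nIntervals = 17, nTrajectories = 1,
                        level = "trajectory", frameInterval = 0.1,
                        cellId = "c", condition = "")
  expect_identical(msdAtLag(fixed, 10), 0.049)
})

test_that("fold change is a ratio of MSDs at the lag", {
  mk <- function(f) methods::new("MSDCurve", lags = c(5, 10),
                                 msd = f * c(0.03, 0.049),
                                 nIntervals = c(1, 1), nTrajectories = c(1, 1),
                                 level = "population", frameInterval = 5,
                                 cellId = "", condition = "")
  expect_equal(foldChange(mk(1), mk(1), 10), 1.0)
  expect_equal(foldChange(mk(2), mk(1), 10), 2.0)
  expect_equal(0.088 / 0.049, 1.7959, tolerance = 1e-4)
})
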