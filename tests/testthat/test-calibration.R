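test_that("per-sample scale solves the origin-constrained least squares", {
  expect_equal(perSampleScale(100, 200, 300, 600), 3)
  expect_equal(perSampleScale(120, 240, 120, 240), 1)
  expect_error(perSampleScale(0, 0, 10, 20), "zero")
  # grid-search oracle on a random pair
  set.seed(3)
  for (i in 1:5) {
    icm <- runif(2, 50, 500); fcm <- runif(2, 50, 500)
    s <- perSampleScale(icm[1], icm[2], fcm[1], fcm[2])
    grid <- seq(0.01, 10, by = 1e-4)
    loss <- vapply(grid, function(g)
      (fcm[1] - g * icm[1])^2 + (fcm[2] - g * icm[2])^2, 0)
    expect_equal(s, grid[which.min(loss)], tolerance = 1e-4)
  }
})

test_that("ratio statistics and the naive transfer are plain moments", {
  expect_equal(ratioStats(c(2, 2))$mean, 2)
  expect_equal(ratioStats(c(2, 2))$sd, 0)
  rs <- ratioStats(c(1.9, 2.1), "m")
  expect_equal(rs$mean, 2)
  expect_equal(rs$sd, sd(c(1.9, 2.1)))
  expect_equal(rs$sd, 0.1414214, tolerance = 1e-6)
  nv <- naiveTransfer(c(2, 4))
  expect_equal(unname(nv["scale"]), 3)
  expect_equal(unname(nv["sd"]), sqrt(2))
  expect_equal(unname(naiveTransfer(rep(5, 6))["sd"]), 0)
  set.seed(5)
  x <- runif(9, 1, 3)
  expect_equal(unname(naiveTransfer(x)), c(mean(x), sd(x)))
})

test_that("regression recovers exact lines and noisy slopes", {
  x <- c(1, 2, 3, 4, 5)
  f <- fitRegression(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$rmse, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  set.seed(7)
  xr <- runif(100, 0, 10)
  sigma <- 0.8
  yr <- 3 * xr + rnorm(100, 0, sigma)
  fr <- fitRegression(xr, yr)
  se <- sigma / sqrt(sum((xr - mean(xr))^2))
  expect_lt(abs(fr$slope - 3), 3 * se)
  expect_lt(abs(fr$rmse - sigma) / sigma, 0.2)
  expect_gt(fr$shapiro_p, 0.001)
  expect_error(fitRegression(rep(2, 5), 1:5), "degenerate")
  expect_error(fitRegression(1:5, 1:5, exclude = c(F, F, T, T, T)), "3 points")
})

test_that("unit consistency: rescaling FCM rescales the fit, R2 unchanged", {
  set.seed(9)
  icm <- runif(20, 100, 1000)
  fcm <- 0.01 * icm + rnorm(20, 0, 0.5)
  f1 <- fitRegression(icm, fcm)
  alpha <- 7
  f2 <- fitRegression(icm, alpha * fcm)
  expect_equal(f2$slope, alpha * f1$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, alpha * f1$intercept, tolerance = 1e-10)
  expect_equal(f2$rmse, alpha * f1$rmse, tolerance = 1e-10)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
  s1 <- perSampleScale(icm[1], icm[2], fcm[1], fcm[2])
  s2 <- perSampleScale(icm[1], icm[2], alpha * fcm[1], alpha * fcm[2])
  expect_equal(s2, alpha * s1, tolerance = 1e-12)
})

test_that("intensity outliers are flagged by the modified z-score rule", {
  set.seed(11)
  peaks <- c(runif(14, 950, 1050), runif(3, 280, 320))
  flags <- flagIntensityOutliers(peaks)
  expect_identical(which(flags), 15:17)
  expect_false(any(flagIntensityOutliers(runif(10, 900, 1100))))
  expect_warning(f0 <- flagIntensityOutliers(rep(100, 6), manual = 2), "MAD")
  expect_identical(which(f0), 2L)
})

test_that("outlier recovery matches generator ground truth", {
  coh <- generateCohort(17, sampleSpec(nCells = 400, cv = 0.03, seed = 13),
                        icmScaleJitter = 0.05,
                        outlierIndices = c(1, 12, 17), outlierScale = 0.3)
  peaks2N <- vapply(coh$samples, function(s)
    fitNormalPeak(s$features$dna[s$truth$population == "2N"])$mu, 0)
  flags <- flagIntensityOutliers(peaks2N)
  expect_identical(flags, coh$outlierTruth)
})

test_that("cohort calibration assembles scales, fits and ratio stats", {
  # constructed cohort on an exact line fcm = 0.01 * icm
  ids <- 1:6
  pairs <- data.frame(sample_id = rep(ids, each = 2),
                      method = rep(c("icm_bin", "icm_fit"), 6),
                      icm_2N = rep(c(1000, 1010), 6)[1:12] + 10 * rep(ids, each = 2),
                      fcm_2N = 0, icm_4N = 0, fcm_4N = 0)
  pairs$icm_4N <- 2 * pairs$icm_2N
  pairs$fcm_2N <- 0.01 * pairs$icm_2N
  pairs$fcm_4N <- 0.01 * pairs$icm_4N
  cal <- calibrateCohort(pairs, scaleMethod = "icm_fit")
  expect_equal(unname(sampleScales(cal)), rep(0.01, 6), tolerance = 1e-12)
  expect_equal(unname(naiveScale(cal)["scale"]), 0.01, tolerance = 1e-12)
  reg <- regressionTable(cal)
  expect_equal(reg$slope, rep(0.01, 2), tolerance = 1e-10)
  expect_equal(reg$rmse, rep(0, 2), tolerance = 1e-10)
  rs <- ratioStatsTable(cal)
  expect_equal(rs$mean, rep(2, 2), tolerance = 1e-12)
  expect_false(any(outlierFlags(cal)))
})
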