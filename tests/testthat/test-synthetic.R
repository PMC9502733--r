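test_that("zero-noise degenerate sample yields exact DNA values", {
  s <- generateEventSample(sampleSpec(nCells = 100, mu2N = 100, cv = 0,
                                      frac4N = 0, fracDebris = 0,
                                      icmScale = 3, seed = 1))
  expect_true(all(s$features$dna == 300))
  expect_true(all(s$truth$population == "2N"))
})

test_that("4N/2N population mean ratio is 2 within sampling error", {
  s <- generateEventSample(sampleSpec(nCells = 4000, cv = 0.05,
                                      frac4N = 0.25, seed = 3))
  v2 <- s$features$dna[s$truth$population == "2N"]
  v4 <- s$features$dna[s$truth$population == "4N"]
  ratio <- mean(v4) / mean(v2)
  se <- ratio * sqrt(var(v4) / (mean(v4)^2 * length(v4)) +
                     var(v2) / (mean(v2)^2 * length(v2)))
  expect_lt(abs(ratio - 2), 3 * se)
})

test_that("2N sample mean falls in the Monte-Carlo CI of a direct draw", {
  spec <- sampleSpec(nCells = 2000, cv = 0.03, icmScale = 1.3, seed = 7)
  s <- generateEventSample(spec)
  v2 <- s$features$dna[s$truth$population == "2N"]
  # independent direct draw with the same parameters
  set.seed(7001)
  direct <- replicate(400, {
    mean(spec$icmScale * spec$mu2N * (1 + spec$cv * rnorm(length(v2))))
  })
  ci <- quantile(direct, c(0.005, 0.995))
  expect_gt(mean(v2), ci[1])
  expect_lt(mean(v2), ci[2])
})

test_that("event generation is deterministic and refuses tiny samples", {
  expect_error(generateEventSample(sampleSpec(nCells = 20)), "50")
  a <- generateEventSample(sampleSpec(nCells = 200, seed = 9))
  b <- generateEventSample(sampleSpec(nCells = 200, seed = 9))
  expect_identical(a, b)
})

test_that("population ratio invariance holds under global scaling", {
  for (sc in c(0.2, 1, 8)) {
    s <- generateEventSample(sampleSpec(nCells = 3000, cv = 0.02,
                                        icmScale = sc, fcmScale = sc / 10,
                                        seed = 13))
    v2 <- s$features$dna[s$truth$population == "2N"]
    v4 <- s$features$dna[s$truth$population == "4N"]
    expect_lt(abs(mean(v4) / mean(v2) - 2), 0.01)
    f2 <- s$events$fsc_area[s$truth$population == "2N"]
    f4 <- s$events$fsc_area[s$truth$population == "4N"]
    expect_lt(abs(mean(f4) / mean(f2) - 2), 0.01)
  }
})

test_that("image scenes carry consistent rasters and exact ground truth", {
  sp <- sampleSpec(nCells = 8, mu2N = 40000, cv = 0.05, fracDebris = 0.1,
                   seed = 5)
  sc <- imageSceneSpec(imageSize = c(300, 300), noiseSd = 0,
                       backgroundGradient = 0, seed = 9)
  g <- generateImageSample(sp, sc)
  expect_identical(dim(intensityMatrix(g$image)), dim(labelMatrix(g$image)))
  expect_identical(objectIds(g$image), 1:8)
  # ground-truth IOD equals the painted above-background increments
  base <- sc$backgroundLevel
  for (i in 1:8) {
    sel <- labelMatrix(g$image) == i
    expect_equal(sum(intensityMatrix(g$image)[sel]) - sum(sel) * base,
                 g$truth$true_iod[i])
    expect_identical(sum(sel), g$truth$true_area[i])
  }
})

test_that("impossible placement fails with a clear constraint message", {
  sp <- sampleSpec(nCells = 60, seed = 1)
  sc <- imageSceneSpec(imageSize = c(120, 120), minSeparation = 60, seed = 1)
  expect_error(generateImageSample(sp, sc), "minSeparation")
})

test_that("cohorts flag designated outliers and regenerate bit-identically", {
  base <- sampleSpec(nCells = 100, seed = 5)
  coh <- generateCohort(17, base, outlierIndices = c(1, 12, 17),
                        outlierScale = 0.3)
  expect_identical(sum(coh$outlierTruth), 3L)
  expect_identical(which(coh$outlierTruth), c(1L, 12L, 17L))
  expect_lt(coh$specs[[12]]$icmScale, 0.5 * coh$specs[[2]]$icmScale)
  expect_identical(coh, generateCohort(17, base,
                                       outlierIndices = c(1, 12, 17),
                                       outlierScale = 0.3))
  expect_error(generateCohort(5, base, outlierIndices = 9,
                              outlierScale = 0.3), "range")
})

test_that("jitter-free cohorts share the 2N ICM peak location", {
  coh <- generateCohort(5, sampleSpec(nCells = 3000, cv = 0.02, seed = 8),
                        icmScaleJitter = 0)
  means <- vapply(coh$samples, function(s)
    mean(s$features$dna[s$truth$population == "2N"]), 0)
  expect_lt(diff(range(means)) / mean(means), 0.01)
})
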