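test_that("membership symmetry and the zero-distance rule hold", {
  # a point equidistant from two well-separated groups, c = 2
  pts <- rbind(matrix(c(-5, 0, -5.2, 0.2, -4.8, -0.2), 3, 2, byrow = TRUE),
               matrix(c(5, 0, 5.2, -0.2, 4.8, 0.2), 3, 2, byrow = TRUE),
               c(0, 0))
  fc <- fuzzyCMeans(pts, c = 2, seed = 3)
  u <- memberships(fc)[7, ]
  expect_equal(unname(u), c(0.5, 0.5), tolerance = 1e-3)
  # a point coincident with a center gets membership 1
  p3 <- rbind(matrix(rnorm(20, 0, 0.01), 10, 2),
              sweep(matrix(rnorm(20, 0, 0.01), 10, 2), 2, c(8, 8), "+"))
  fc3 <- fuzzyCMeans(p3, c = 2, seed = 1)
  hits <- which(apply(p3, 1, function(x)
    any(colSums(abs(t(clusterCenters(fc3)) - x)) == 0)))
  for (h in hits)
    expect_equal(max(memberships(fc3)[h, ]), 1)
})

test_that("membership rows always sum to one", {
  set.seed(5)
  pts <- matrix(rnorm(600), 300, 2)
  for (c in 2:4) {
    fc <- fuzzyCMeans(pts, c = c, seed = c)
    expect_lt(max(abs(rowSums(memberships(fc)) - 1)), 1e-9)
    expect_true(all(memberships(fc) >= 0 & memberships(fc) <= 1))
  }
})

test_that("argmax memberships match k-means on well-separated blobs", {
  set.seed(7)
  pts <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
               sweep(matrix(rnorm(100, 0, 0.3), 50, 2), 2, c(6, 0), "+"),
               sweep(matrix(rnorm(100, 0, 0.3), 50, 2), 2, c(0, 6), "+"))
  fc <- fuzzyCMeans(pts, c = 3, seed = 11)
  km <- kmeans(pts, 3, nstart = 10)
  lab <- max.col(memberships(fc))
  agreement <- sum(apply(table(lab, km$cluster), 1, max)) / nrow(pts)
  expect_equal(agreement, 1)
  expect_true(fc@converged)
})

test_that("fuzzy c-means is deterministic under a fixed seed", {
  set.seed(9)
  pts <- matrix(rnorm(400), 200, 2)
  a <- fuzzyCMeans(pts, c = 3, seed = 21)
  b <- fuzzyCMeans(pts, c = 3, seed = 21)
  expect_identical(memberships(a), memberships(b))
  expect_identical(clusterCenters(a), clusterCenters(b))
})

test_that("uncertainty filtering applies the threshold and its bounds", {
  set.seed(13)
  pts <- rbind(matrix(rnorm(60, 0, 0.2), 30, 2),
               sweep(matrix(rnorm(60, 0, 0.2), 30, 2), 2, c(4, 4), "+"),
               c(2, 2))  # midpoint: uncertain
  fc <- fuzzyCMeans(pts, c = 2, seed = 2)
  kept <- filterUncertain(fc, threshold = 0.6)
  mx <- apply(memberships(fc), 1, max)
  expect_identical(kept, mx >= 0.6)
  expect_false(kept[61])
  # threshold just above 1/c keeps every point with a strict argmax
  eps <- 1e-9
  keptAll <- filterUncertain(fc, threshold = 0.5 + eps)
  expect_true(all(keptAll[mx > 0.5 + eps]))
  expect_error(filterUncertain(fc, threshold = 0.5), "threshold")
  expect_error(filterUncertain(fc, threshold = 1.2), "threshold")
})

test_that("population labels follow the DNA ordering of the centers", {
  set.seed(17)
  pts <- rbind(cbind(rnorm(40, 100, 5), rnorm(40, 30, 3)),
               cbind(rnorm(40, 100, 5), rnorm(40, 100, 5)),
               cbind(rnorm(40, 105, 5), rnorm(40, 200, 8)))
  fc <- fuzzyCMeans(pts, c = 3, seed = 5)
  dnaCenters <- clusterCenters(fc)[, 2]
  assign <- labelPopulations(fc, dnaCenters)
  expect_false(attr(assign, "flagged"))
  pops <- attr(assign, "populationOfCluster")
  expect_identical(pops[order(dnaCenters)], c("debris", "2N", "4N"))
  # relabeling invariance: population depends only on the DNA coordinate
  expect_true(all(assign$population[1:40] == "debris"))
  expect_true(all(assign$population[41:80] == "2N"))
  expect_true(all(assign$population[81:120] == "4N"))
})

test_that("implausible 4N/2N center ratios flag the sample", {
  set.seed(19)
  pts <- rbind(cbind(rnorm(50, 100, 2), rnorm(50, 100, 2)),
               cbind(rnorm(50, 100, 2), rnorm(50, 120, 2)),
               cbind(rnorm(50, 100, 2), rnorm(50, 130, 2)))
  fc <- fuzzyCMeans(pts, c = 3, seed = 7)
  expect_warning(assign <- labelPopulations(fc, clusterCenters(fc)[, 2]),
                 "flagged")
  expect_true(attr(assign, "flagged"))
})

test_that("generated cohort samples recover ground-truth labels", {
  s <- generateEventSample(sampleSpec(nCells = 2000, cv = 0.03, seed = 23))
  ft <- data.frame(area = s$features$area, dna = s$features$dna,
                   gran = s$features$gran_dmg)
  den <- pcaCorrect(ft, fitPloidyPca(ft))
  fc <- fuzzyCMeans(cbind(den$area_denoised, den$dna_denoised),
                    c = 3, seed = 29)
  assign <- labelPopulations(fc, clusterCenters(fc)[, 2])
  nonDebris <- s$truth$population != "debris"
  acc <- mean(as.character(assign$population[nonDebris]) ==
              s$truth$population[nonDebris])
  expect_gte(acc, 0.95)
})
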