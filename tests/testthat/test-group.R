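test_that("one-sample t matches the textbook formula and edge conventions", {
  set.seed(71)
  n <- 30L
  maps <- lapply(seq_len(n), function(i) array(rnorm(27, 0.2, 0.5), c(3, 3, 3)))
  stat <- oneSampleT(maps)
  # hand-computed voxel
  v <- vapply(maps, function(m) m[2, 2, 2], 0)
  tExp <- mean(v) / (sd(v) / sqrt(n))
  expect_equal(tMap(stat)[2, 2, 2], tExp, tolerance = 1e-10)
  expect_equal(pMap(stat)[2, 2, 2], 2 * pt(-abs(tExp), n - 1),
               tolerance = 1e-10)
  expect_equal(pMap(stat)[2, 2, 2],
               t.test(v)$p.value, tolerance = 1e-10)
  expect_identical(stat@df, n - 1L)

  # symmetric betas: t = 0, p = 1
  sym <- lapply(c(-2, -1, 1, 2), function(x) array(x, c(2, 2, 2)))
  s2 <- oneSampleT(sym)
  expect_identical(tMap(s2)[1, 1, 1], 0)
  expect_identical(pMap(s2)[1, 1, 1], 1)

  # near-constant betas: huge t, p near 0
  set.seed(72)
  tight <- lapply(1:10, function(i) array(1 + rnorm(8, 0, 1e-8), c(2, 2, 2)))
  s3 <- oneSampleT(tight)
  expect_gt(min(tMap(s3)), 1e6)
  expect_lt(max(pMap(s3)), 1e-10)

  # zero variance, nonzero mean: +/- Inf convention
  const <- lapply(1:5, function(i) array(2, c(2, 2, 2)))
  expect_message(s4 <- oneSampleT(const), "zero across-subject variance")
  expect_true(all(tMap(s4) == Inf))
  expect_true(all(pMap(s4) > 0))
  expect_error(oneSampleT(maps[1]), "at least 2")
})

test_that("corner-touching voxels form one cluster only under corners", {
  b <- array(FALSE, c(4, 4, 4))
  b[1, 1, 1] <- TRUE
  b[2, 2, 2] <- TRUE
  expect_identical(labelClusters(b, "corners")$sizes, 2L)
  expect_identical(sort(labelClusters(b, "faces")$sizes), c(1L, 1L))
  expect_identical(sort(labelClusters(b, "edges")$sizes), c(1L, 1L))
  # edge-touching pair: one cluster under edges and corners, two under faces
  e <- array(FALSE, c(3, 3, 3))
  e[1, 1, 1] <- TRUE; e[2, 2, 1] <- TRUE
  expect_identical(labelClusters(e, "edges")$sizes, 2L)
  expect_identical(sort(labelClusters(e, "faces")$sizes), c(1L, 1L))
  # isolated voxel: one cluster of size 1
  i1 <- array(FALSE, c(3, 3, 3)); i1[2, 2, 2] <- TRUE
  expect_identical(labelClusters(i1)$sizes, 1L)
  # empty map: no clusters
  expect_identical(labelClusters(array(FALSE, c(3, 3, 3)))$nClusters, 0L)
})

test_that("labeling matches the flood-fill oracle on random fields", {
  set.seed(73)
  for (conn in c("faces", "edges", "corners")) {
    for (rep in 1:25) {
      b <- array(runif(6^3) < 0.35, c(6, 6, 6))
      got <- labelClusters(b, conn)$labels
      expect_true(samePartition(got, floodFillLabels(b, conn)))
    }
  }
})

test_that("Monte-Carlo extent threshold behaves at the degenerate tail", {
  # a lax alpha on a sparse excursion set lets any cluster pass
  mask <- array(TRUE, c(4, 4, 4))
  spec <- clusterThresholdSpec(mask, fwhm = 0, voxelP = 0.005,
                               alphaFwe = 0.9, nIterations = 200L,
                               seed = 81)
  mc <- monteCarloClusterThreshold(spec)
  expect_identical(mc$threshold, 1L)
  expect_error(monteCarloClusterThreshold(
    clusterThresholdSpec(mask, fwhm = 0, alphaFwe = 0.001,
                         nIterations = 200L)), "tail")
})

test_that("unsmoothed threshold agrees with an independent naive simulator", {
  mask <- array(TRUE, c(10, 10, 10))
  spec <- clusterThresholdSpec(mask, fwhm = 0, voxelP = 0.01, alphaFwe = 0.05,
                               connectivity = "corners", nIterations = 600L,
                               seed = 82)
  mc <- monteCarloClusterThreshold(spec)
  set.seed(83)
  naive <- naiveMaxClusterThreshold(c(10, 10, 10), 0.01, 0.05, 400L)
  expect_lte(abs(mc$threshold - naive), 1L)
})

test_that("extent threshold is nondecreasing in the applied smoothness", {
  mask <- array(TRUE, c(12, 12, 12))
  th <- vapply(c(0, 4, 8), function(f) {
    monteCarloClusterThreshold(clusterThresholdSpec(
      mask, voxelDims = c(4, 4, 4), fwhm = f, voxelP = 0.005,
      alphaFwe = 0.05, nIterations = 300L, seed = 84))$threshold
  }, 0L)
  expect_true(all(diff(th) >= 0))
  # stricter voxel threshold gives a smaller or equal extent threshold
  th2 <- vapply(c(0.01, 0.001), function(p) {
    monteCarloClusterThreshold(clusterThresholdSpec(
      mask, voxelDims = c(4, 4, 4), fwhm = 8, voxelP = p,
      alphaFwe = 0.05, nIterations = 300L, seed = 85))$threshold
  }, 0L)
  expect_lte(th2[2], th2[1])
})

test_that("cluster report finds a planted effect and keeps sign bookkeeping", {
  set.seed(86)
  d <- c(10, 10, 6)
  core <- cubeRegion(d, c(3, 3, 2), c(7, 8, 5))   # 5*6*4 = 120 voxels
  n <- 20L
  maps <- lapply(seq_len(n), function(i)
    array(rnorm(prod(d), 0, 0.05), d) + ifelse(core, 0.8, 0))
  stat <- oneSampleT(maps)
  tab <- clusterReport(stat, maps, extentThreshold = 10, voxelP = 0.005,
                       voxelDims = c(4, 4, 4))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$sign, "positive")
  expect_gte(tab$n_voxels, sum(core))
  expect_gt(tab$mean_effect, 0.5)
  # flipping all betas flips the sign and negates the peak t
  mapsNeg <- lapply(maps, function(m) -m)
  statNeg <- oneSampleT(mapsNeg)
  tabNeg <- clusterReport(statNeg, mapsNeg, extentThreshold = 10,
                          voxelP = 0.005, voxelDims = c(4, 4, 4))
  expect_identical(tabNeg$sign, "negative")
  expect_equal(tabNeg$peak_t, -tab$peak_t, tolerance = 1e-12)
  expect_equal(tabNeg$mean_effect, -tab$mean_effect, tolerance = 1e-12)
  # nothing surviving: an empty table, not an error
  tabNone <- clusterReport(stat, maps, extentThreshold = 1e6)
  expect_identical(nrow(tabNone), 0L)
})
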