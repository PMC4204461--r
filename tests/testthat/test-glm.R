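regFromValues <- function(v, label, runStarts = 1L, tr = 2)
  new("Regressor", label = label, values = v, runStarts = as.integer(runStarts),
      tr = tr)

test_that("design matrix has the expected column structure", {
  set.seed(4)
  nv <- c(30L, 30L)
  xT <- regFromValues(rnorm(60), "task", c(1L, 31L))
  xR <- regFromValues(rnorm(60), "rt", c(1L, 31L))
  motion <- matrix(rnorm(60 * 6), 60, 6)
  # 2 runs x (intercept + 2 drift) + 6 motion + 2 effects = 14
  dm <- buildDesignMatrix(list(xT, xR), nv, motion = motion, driftOrder = 2L)
  expect_identical(ncol(designMatrix(dm)), 14L)
  expect_identical(effectColumns(dm), c("task", "rt"))
  expect_true(is.finite(conditionNumber(dm)))
  # drift order 0, 1 run, no motion: intercept + 2 effects
  dm0 <- buildDesignMatrix(list(regFromValues(rnorm(30), "task"),
                                regFromValues(rnorm(30), "rt")),
                           30L, driftOrder = 0L)
  expect_identical(ncol(designMatrix(dm0)), 3L)
})

test_that("constant motion columns are dropped; rank deficiency is named", {
  set.seed(5)
  xT <- regFromValues(rnorm(30), "task")
  xR <- regFromValues(rnorm(30), "rt")
  zeroMotion <- matrix(0, 30, 6)
  expect_message(dm <- buildDesignMatrix(list(xT, xR), 30L,
                                         motion = zeroMotion),
                 "constant motion")
  expect_identical(ncol(designMatrix(dm)), 5L)  # intercept + 2 drift + 2 effects
  # a duplicated effect column must be rejected by name
  dup <- regFromValues(regressorValues(xT), "task_copy")
  expect_error(buildDesignMatrix(list(xT, dup), 30L, driftOrder = 0L),
               "task_copy")
  expect_error(buildDesignMatrix(list(xT, xR), 30L,
                                 motion = matrix(rnorm(30 * 5), 30, 5)),
               "6 columns")
  expect_error(buildDesignMatrix(list(xT, xR), 30L,
                                 motion = matrix(rnorm(29 * 6), 29, 6)),
               "do not match")
})

test_that("noiseless voxels built from the design are recovered exactly", {
  set.seed(6)
  xT <- regFromValues(rnorm(50), "task")
  xR <- regFromValues(rnorm(50), "rt")
  dm <- buildDesignMatrix(list(xT, xR), 50L, driftOrder = 1L)
  y <- 7 + 0.5 * regressorValues(xT) + 0.2 * regressorValues(xR)
  dat <- new("VolumeSeries", data = array(y, c(1, 1, 1, 50)),
             voxelDims = c(4, 4, 4), tr = 2, runId = "run-1", mask = NULL)
  fit <- fitVoxelwiseGLM(dat, dm)
  expect_equal(betaMap(fit, "task")[1, 1, 1], 0.5, tolerance = 1e-8)
  expect_equal(betaMap(fit, "rt")[1, 1, 1], 0.2, tolerance = 1e-8)
  expect_lt(fit@sigma2[1, 1, 1], 1e-16)
})

test_that("fitted betas equal the normal-equation oracle on random instances", {
  for (rep in 1:20) {
    set.seed(100 + rep)
    nVol <- sample(20:50, 1)
    nVox <- sample(1:10, 1)
    xT <- regFromValues(rnorm(nVol), "task")
    xR <- regFromValues(rnorm(nVol), "rt")
    dm <- buildDesignMatrix(list(xT, xR), nVol,
                            driftOrder = sample(0:2, 1))
    X <- designMatrix(dm)
    Y <- matrix(rnorm(nVol * nVox, 100, 3), nVol, nVox)
    dat <- new("VolumeSeries", data = array(t(Y), c(nVox, 1, 1, nVol)),
               voxelDims = c(4, 4, 4), tr = 2, runId = "r", mask = NULL)
    fit <- fitVoxelwiseGLM(dat, dm)
    for (v in seq_len(nVox)) {
      bo <- normalEquationBetas(X, Y[, v])
      expect_equal(betaMap(fit, "task")[v, 1, 1],
                   bo[match("task", colnames(X))], tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_equal(betaMap(fit, "rt")[v, 1, 1],
                   bo[match("rt", colnames(X))], tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
    # df bookkeeping: volumes minus design rank
    expect_identical(dfResidual(fit), nVol - qr(X)$rank)
  }
})

test_that("motion-shaped artifacts are absorbed by motion columns", {
  set.seed(7)
  nVol <- 80L
  xT <- regFromValues(rnorm(nVol), "task")
  xR <- regFromValues(rnorm(nVol), "rt")
  motion <- matrix(rnorm(nVol * 6), nVol, 6)
  dm <- buildDesignMatrix(list(xT, xR), nVol, motion = motion)
  y <- 100 + 0.4 * regressorValues(xT) + rnorm(nVol, 0, 0.1)
  mk <- function(yy) new("VolumeSeries", data = array(yy, c(1, 1, 1, nVol)),
                         voxelDims = c(4, 4, 4), tr = 2, runId = "r",
                         mask = NULL)
  b0 <- betaMap(fitVoxelwiseGLM(mk(y), dm), "task")[1, 1, 1]
  # add a pure motion-shaped artifact: effect betas must not move
  b1 <- betaMap(fitVoxelwiseGLM(mk(y + motion %*% c(3, -2, 1, 5, 0.5, -1)),
                                dm), "task")[1, 1, 1]
  expect_equal(b0, b1, tolerance = 1e-8)
})

test_that("non-finite in-mask data are rejected with a count", {
  xT <- regFromValues(rnorm(10), "task")
  dm <- buildDesignMatrix(list(xT), 10L, driftOrder = 0L)
  bad <- array(1, c(2, 1, 1, 10)); bad[1, 1, 1, 3] <- NA
  # the VolumeSeries validity itself refuses non-finite data
  expect_error(new("VolumeSeries", data = bad, voxelDims = c(4, 4, 4),
                   tr = 2, runId = "r", mask = NULL), "finite")
})
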