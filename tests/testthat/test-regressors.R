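test_that("single trial at onset 0 reproduces the sampled HRF", {
  sch <- makeSchedule(onsets = 0, rts = 1200)
  reg <- canonicalRegressor(sch)
  tv <- (0:39) * 2
  expect_equal(regressorValues(reg), gammaHRF(tv), tolerance = 1e-10)
})

test_that("overlapping responses superpose linearly", {
  sch2 <- makeSchedule(onsets = c(4, 6), rts = c(1000, 1000))
  reg2 <- regressorValues(canonicalRegressor(sch2))
  oracle <- bruteForceRegressor(c(4, 6), c(1, 1), 40, 2)
  expect_equal(reg2, oracle, tolerance = 1e-10)
  # equals the sum of the two shifted single-trial regressors
  one <- function(on) regressorValues(canonicalRegressor(
    makeSchedule(onsets = on, rts = 1000)))
  expect_equal(reg2, one(4) + one(6), tolerance = 1e-12)
})

test_that("a schedule with no correct trials gives an all-zero regressor", {
  sch <- makeSchedule(onsets = c(0, 10), rts = c(NA, NA),
                      correct = c(FALSE, FALSE))
  expect_warning(reg <- canonicalRegressor(sch), "all zero")
  expect_identical(regressorValues(reg), rep(0, 40))
})

test_that("RT modulation scales each trial by log RT before superposition", {
  # common RT factors out
  sch <- makeSchedule(onsets = c(2, 9, 20), rts = rep(900, 3))
  expect_equal(regressorValues(rtModulatedRegressor(sch)),
               log(900) * regressorValues(canonicalRegressor(sch)),
               tolerance = 1e-12)
  # RT of 1 ms contributes nothing (log 1 = 0)
  schMix <- makeSchedule(onsets = c(2, 9, 20), rts = c(1, 900, 1600))
  schDrop <- makeSchedule(onsets = c(9, 20), rts = c(900, 1600))
  expect_equal(regressorValues(rtModulatedRegressor(schMix)),
               regressorValues(rtModulatedRegressor(schDrop)),
               tolerance = 1e-12)
  # mixed RTs match the brute-force per-trial scaling oracle
  oracle <- bruteForceRegressor(c(2, 9, 20), log(c(1, 900, 1600)), 40, 2)
  expect_equal(regressorValues(rtModulatedRegressor(schMix)), oracle,
               tolerance = 1e-10)
  # incorrect trials are excluded
  schInc <- makeSchedule(onsets = c(2, 9, 20), rts = c(700, 900, 1600),
                         correct = c(FALSE, TRUE, TRUE))
  oracleInc <- bruteForceRegressor(c(9, 20), log(c(900, 1600)), 40, 2)
  expect_equal(regressorValues(rtModulatedRegressor(schInc)), oracleInc,
               tolerance = 1e-10)
  # nonpositive RTs are rejected already at schedule construction
  expect_error(makeSchedule(onsets = c(2, 9), rts = c(-5, 900)), "positive")
})

test_that("residualization removes canonical and constant components", {
  sch <- simulateRTs(SubjectParams(),
                     simulateSchedule(ProtocolSpec(), seed = 21), seed = 22)
  xT <- canonicalRegressor(sch)
  xM <- rtModulatedRegressor(sch)
  xR <- orthogonalizeRegressor(xM, xT)
  v <- regressorValues(xR)
  ct <- regressorValues(xT)
  expect_lt(abs(sum(v * ct)), 1e-8 * sqrt(sum(v^2)) * sqrt(sum(ct^2)))
  expect_lt(abs(sum(v)), 1e-8 * sqrt(sum(v^2)) * sqrt(length(v)))
  # exact collinearity: residual identically zero
  x32 <- new("Regressor", label = "scaled", values = 3.2 * ct,
             runStarts = runStarts(xT), tr = 2)
  expect_lt(max(abs(regressorValues(orthogonalizeRegressor(x32, xT)))), 1e-10)
})

test_that("residualization matches the closed-form projection on 6 samples", {
  canon <- new("Regressor", label = "c", values = c(0, 1, 2, 1, 0, 0),
               runStarts = 1L, tr = 2)
  modul <- new("Regressor", label = "m", values = c(1, 3, 2, 5, 4, 0),
               runStarts = 1L, tr = 2)
  X <- cbind(1, c(0, 1, 2, 1, 0, 0))
  expected <- c(1, 3, 2, 5, 4, 0) -
    X %*% normalEquationBetas(X, c(1, 3, 2, 5, 4, 0))
  expect_equal(regressorValues(orthogonalizeRegressor(modul, canon)),
               as.numeric(expected), tolerance = 1e-12)
})

test_that("an all-zero canonical regressor falls back to centering", {
  z <- new("Regressor", label = "z", values = rep(0, 6), runStarts = 1L, tr = 2)
  m <- new("Regressor", label = "m", values = c(1, 2, 3, 4, 5, 6),
           runStarts = 1L, tr = 2)
  expect_warning(r <- orthogonalizeRegressor(m, z), "identically zero")
  expect_equal(regressorValues(r), c(1, 2, 3, 4, 5, 6) - 3.5)
})

test_that("regressor of a union of disjoint schedules is the sum of parts", {
  a <- makeSchedule(onsets = c(0, 12), rts = c(800, 1100))
  b <- makeSchedule(onsets = c(30, 44), rts = c(1500, 950))
  u <- makeSchedule(onsets = c(0, 12, 30, 44), rts = c(800, 1100, 1500, 950))
  expect_equal(regressorValues(canonicalRegressor(u)),
               regressorValues(canonicalRegressor(a)) +
                 regressorValues(canonicalRegressor(b)), tolerance = 1e-12)
  expect_equal(regressorValues(rtModulatedRegressor(u)),
               regressorValues(rtModulatedRegressor(a)) +
                 regressorValues(rtModulatedRegressor(b)), tolerance = 1e-12)
})

test_that("halving the oversampling step changes values by < 0.1% of peak", {
  sch <- simulateRTs(SubjectParams(),
                     simulateSchedule(ProtocolSpec(), seed = 31), seed = 32)
  r1 <- regressorValues(canonicalRegressor(sch, dt = 0.1))
  r2 <- regressorValues(canonicalRegressor(sch, dt = 0.05))
  expect_lt(max(abs(r1 - r2)), 0.001 * max(abs(r1)))
  expect_error(canonicalRegressor(sch, dt = 0.3), "divide")
})
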