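tinyEffects <- function(grid = c(8L, 8L, 8L)) {
  effectMapSpec(grid, list(
    list(mask = cubeRegion(grid, c(1, 1, 1), c(3, 3, 3)),
         role = "task_positive", betaTask = 0.5),
    list(mask = cubeRegion(grid, c(5, 5, 5), c(7, 7, 7)),
         role = "rt_positive", betaRt = 0.3)))
}

test_that("effect maps validate geometry and roles", {
  grid <- c(6L, 6L, 6L)
  expect_error(effectMapSpec(grid, list(
    list(voxels = rbind(c(7, 1, 1)), role = "task_positive", betaTask = 1))),
    "outside the grid")
  expect_error(effectMapSpec(grid, list(
    list(mask = cubeRegion(grid, c(1, 1, 1), c(2, 2, 2)), role = "null",
         betaTask = 0.5))), "null regions")
  expect_error(effectMapSpec(grid, list(
    list(mask = cubeRegion(grid, c(1, 1, 1), c(3, 3, 3)),
         role = "task_positive", betaTask = 1),
    list(mask = cubeRegion(grid, c(3, 3, 3), c(4, 4, 4)),
         role = "rt_positive", betaRt = 1))), "disjoint")
  eff <- tinyEffects()
  expect_identical(sum(eff@betaTask == 0.5), 27L)
  expect_identical(sum(eff@betaRt == 0.3), 27L)
})

test_that("the noiseless pipeline inverts the generator exactly", {
  protocol <- tinyProtocol()
  sch <- simulateRTs(SubjectParams(),
                     simulateSchedule(protocol, seed = 41), seed = 42)
  eff <- tinyEffects()
  sim <- simulateBold(sch, eff, SubjectParams(noiseSd = 0, driftAmplitude = 0),
                      seed = 43)
  fit <- fitSubject(sim$runs, sch, motion = sim$motion, fwhm = 0)
  expect_lt(max(abs(betaMap(fit, "task") - sim$truth@betaTask)), 1e-6)
  expect_lt(max(abs(betaMap(fit, "rt") - sim$truth@betaRt)), 1e-6)
})

test_that("incorrect trials are rendered but handled by the nuisance", {
  protocol <- tinyProtocol()
  # low accuracy guarantees incorrect trials
  p <- SubjectParams(accuracyRate = 0.6, noiseSd = 0, driftAmplitude = 0)
  sch <- simulateRTs(p, simulateSchedule(protocol, seed = 44), seed = 45)
  expect_gt(sum(!events(sch)$correct), 0)
  eff <- tinyEffects()
  sim <- simulateBold(sch, eff, p, seed = 46)
  fitWith <- fitSubject(sim$runs, sch, fwhm = 0, modelIncorrect = TRUE)
  expect_lt(max(abs(betaMap(fitWith, "task") - sim$truth@betaTask)), 1e-6)
  # without the nuisance the unmodeled events bias the task beta
  fitWithout <- fitSubject(sim$runs, sch, fwhm = 0, modelIncorrect = FALSE)
  expect_gt(max(abs(betaMap(fitWithout, "task") - sim$truth@betaTask)), 1e-3)
})

test_that("identical seeds give identical volumes, RTs and motion", {
  protocol <- tinyProtocol(grid = c(4L, 4L, 4L))
  eff <- effectMapSpec(c(4L, 4L, 4L))
  run1 <- function() {
    sch <- simulateRTs(SubjectParams(), simulateSchedule(protocol, seed = 51),
                       seed = 52)
    simulateBold(sch, eff, SubjectParams(), seed = 53)
  }
  a <- run1(); b <- run1()
  expect_identical(boldData(a$runs[[1]]), boldData(b$runs[[1]]))
  expect_identical(a$motion, b$motion)
  expect_identical(events(a$truth@schedule), events(b$truth@schedule))
  # motion series is volumes x 6
  expect_identical(dim(a$motion[[1]]), c(40L, 6L))
  expect_identical(colnames(a$motion[[1]]),
                   c("roll", "pitch", "yaw", "x", "y", "z"))
})

test_that("cohorts are written to disk reproducibly", {
  protocol <- tinyProtocol(grid = c(4L, 4L, 4L))
  d1 <- file.path(tempdir(), "cohortA")
  d2 <- file.path(tempdir(), "cohortB")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  m <- simulateCohort(d1, nSubjects = 2L, protocol = protocol, seed = 61)
  expect_identical(length(m$subjects), 2L)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_true(file.exists(file.path(d1, "truth", "beta_task.nii.gz")))
  for (s in c("sub-01", "sub-02")) for (r in 1:2) {
    expect_true(file.exists(file.path(d1, s, sprintf("run-%d_bold.nii.gz", r))))
    expect_true(file.exists(file.path(d1, s, sprintf("run-%d_events.tsv", r))))
    expect_true(file.exists(file.path(d1, s, sprintf("run-%d_motion.txt", r))))
  }
  vs <- readVolume(file.path(d1, "sub-01", "run-1_bold.nii.gz"))
  expect_identical(dim(boldData(vs)), c(4L, 4L, 4L, 40L))
  expect_equal(repetitionTime(vs), 2)
  # same master seed: byte-identical event tables
  simulateCohort(d2, nSubjects = 2L, protocol = protocol, seed = 61)
  for (s in c("sub-01", "sub-02")) for (r in 1:2) {
    f <- sprintf("%s/run-%d_events.tsv", s, r)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # refuses to clobber a non-empty directory without overwrite
  expect_error(simulateCohort(d1, nSubjects = 2L, protocol = protocol,
                              seed = 62), "not empty")
  expect_silent(suppressMessages(
    simulateCohort(d1, nSubjects = 2L, protocol = protocol, seed = 62,
                   overwrite = TRUE)))
})
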