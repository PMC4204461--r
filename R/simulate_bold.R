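#' Construct a planted effect geography
#'
#' Builds voxel-wise ground-truth beta maps from a list of labelled, disjoint
#' regions. Each region is a list with elements \code{mask} (logical 3D
#' array on the grid) or \code{voxels} (n x 3 integer index matrix),
#' \code{role} (one of \code{task_positive}, \code{task_negative},
#' \code{rt_positive}, \code{rt_negative}, \code{null}), and effect sizes
#' \code{betaTask} (percent signal change per unit canonical regressor) and
#' \code{betaRt} (percent signal change per unit residual log-RT).
#'
#' @param gridShape voxels per axis.
#' @param regions list of region descriptions; may be empty for an all-null
#'   map.
#' @return an \linkS4class{EffectMapSpec}.
#' @export
effectMapSpec <- function(gridShape, regions = list()) {
  gridShape <- as.integer(gridShape)
  stopifnot(length(gridShape) == 3L)
  bt <- array(0, gridShape)
  br <- array(0, gridShape)
  regs <- lapply(regions, function(rg) {
    if (is.null(rg$mask)) {
      if (is.null(rg$voxels)) stop("each region needs a mask or a voxels matrix")
      vox <- as.matrix(rg$voxels)
      if (ncol(vox) != 3L) stop("voxels must be an n x 3 index matrix")
      if (any(vox < 1L) || any(vox > matrix(gridShape, nrow(vox), 3, byrow = TRUE)))
        stop("effect region lies outside the grid")
      m <- array(FALSE, gridShape)
      m[vox] <- TRUE
      rg$mask <- m
    }
    if (!identical(dim(rg$mask), gridShape))
      stop("effect region lies outside the grid (mask dimension mismatch)")
    rg$betaTask <- if (is.null(rg$betaTask)) 0 else rg$betaTask
    rg$betaRt <- if (is.null(rg$betaRt)) 0 else rg$betaRt
    rg
  })
  for (rg in regs) {
    bt[rg$mask] <- rg$betaTask
    br[rg$mask] <- rg$betaRt
  }
  new("EffectMapSpec", gridShape = gridShape, betaTask = bt, betaRt = br,
      regions = regs)
}

#' Cuboid region helper
#'
#' Logical mask for an axis-aligned block, convenient for building effect
#' geographies on small grids.
#'
#' @param gridShape voxels per axis.
#' @param lower,upper inclusive voxel index bounds, length 3.
#' @return logical 3D array.
#' @export
cubeRegion <- function(gridShape, lower, upper) {
  gridShape <- as.integer(gridShape)
  if (any(lower < 1L) || any(upper > gridShape) || any(lower > upper))
    stop("block bounds must lie inside the grid")
  m <- array(FALSE, gridShape)
  m[lower[1]:upper[1], lower[2]:upper[2], lower[3]:upper[3]] <- TRUE
  m
}

# AR(1) noise matrix (voxels x volumes) with stationary unit variance
.ar1Noise <- function(nVox, nVol, phi) {
  e <- matrix(stats::rnorm(nVox * nVol), nVox, nVol)
  if (phi == 0 || nVol == 1L) return(e)
  x <- e
  x[, 1L] <- e[, 1L]
  s <- sqrt(1 - phi^2)
  for (t in 2:nVol) x[, t] <- phi * x[, t - 1L] + s * e[, t]
  x
}

# smooth random-walk motion series, nVol x 6 (roll, pitch, yaw, x, y, z)
.simulateMotion <- function(nVol, step = 0.02, taskValues = NULL,
                            taskCoupling = 0) {
  m <- apply(matrix(stats::rnorm(nVol * 6, sd = step), nVol, 6), 2, cumsum)
  k <- rep(1 / 5, 5)
  m <- apply(m, 2, function(col)
    stats::filter(c(rep(col[1], 4), col), k, sides = 1)[-(1:4)])
  m <- matrix(as.numeric(m), nVol, 6)
  if (taskCoupling != 0 && !is.null(taskValues))
    m <- m + taskCoupling * taskValues
  colnames(m) <- c("roll", "pitch", "yaw", "x", "y", "z")
  m
}

#' Simulate a subject's 4D BOLD runs
#'
#' Renders the raw signal of each voxel as
#' \code{baseline * (1 + [betaTask * xTask(t) + betaRt * xRt(t) + drift(t)] / 100)}
#' plus AR(1) Gaussian noise scaled to \code{noiseSd} percent of baseline.
#' \code{xTask} is the canonical regressor and \code{xRt} the residualized
#' RT regressor built from this schedule and these RTs — the same regressors
#' the analysis fits — so the planted betas are recoverable; the task and
#' drift components are centered within each run so the run temporal mean
#' stays at baseline and percent-signal-change conversion is exact. Trials
#' flagged incorrect (or without a response) are still rendered, with the
#' region's task amplitude, via a separate incorrect-trial regressor.
#'
#' @param schedule a \linkS4class{TrialSchedule} with simulated RTs.
#' @param effects an \linkS4class{EffectMapSpec}.
#' @param params a \linkS4class{SubjectParams}.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @param voxelDims voxel size, mm per axis.
#' @param dt regressor oversampling step, seconds.
#' @param b,c HRF parameters.
#' @param motionCoupling amount of canonical-regressor leakage into the
#'   motion series (a stress test; 0 = independent motion).
#' @return list with elements \code{runs} (list of \linkS4class{VolumeSeries},
#'   one per run), \code{motion} (list of volumes x 6 matrices), and
#'   \code{truth} (a \linkS4class{GroundTruth}).
#' @export
simulateBold <- function(schedule, effects, params, seed = NULL,
                         voxelDims = c(4, 4, 4), dt = 0.1,
                         b = 8.6, c = 0.547, motionCoupling = 0) {
  stopifnot(is(schedule, "TrialSchedule"), is(effects, "EffectMapSpec"),
            is(params, "SubjectParams"))
  if (!is.null(seed)) set.seed(seed)
  grid <- effects@gridShape
  nVox <- prod(grid)
  nVolRun <- schedule@nVolumes
  nVol <- sum(nVolRun)
  tr <- schedule@tr

  xTask <- centerRegressor(canonicalRegressor(schedule, dt = dt, b = b, c = c))
  ev <- schedule@events
  anyIncorrect <- any(is.na(ev$correct) | !ev$correct)
  xInc <- if (anyIncorrect) {
    centerRegressor(suppressWarnings(
      canonicalRegressor(schedule, dt = dt, b = b, c = c, which = "incorrect")))
  } else NULL
  xMod <- rtModulatedRegressor(schedule, dt = dt, b = b, c = c)
  xRt <- orthogonalizeRegressor(xMod, canonicalRegressor(schedule, dt = dt,
                                                         b = b, c = c))

  sig <- outer(as.numeric(effects@betaTask), regressorValues(xTask)) +
         outer(as.numeric(effects@betaRt), regressorValues(xRt))
  if (!is.null(xInc))
    sig <- sig + outer(as.numeric(effects@betaTask), regressorValues(xInc))
  if (params@driftAmplitude > 0) {
    drift <- numeric(0)
    for (r in seq_along(nVolRun)) {
      t <- seq_len(nVolRun[r]) - 1
      d <- params@driftAmplitude *
        cos(2 * pi * t / nVolRun[r] + stats::runif(1, 0, 2 * pi))
      drift <- c(drift, d - mean(d))    # run-centered slow drift
    }
    sig <- sweep(sig, 2L, drift, "+")
  }
  raw <- params@baselineLevel * (1 + sig / 100)
  if (params@noiseSd > 0) {
    starts <- c(1L, cumsum(nVolRun)[-length(nVolRun)] + 1L)
    ends <- cumsum(nVolRun)
    for (r in seq_along(nVolRun)) {
      cols <- starts[r]:ends[r]
      raw[, cols] <- raw[, cols] +
        (params@noiseSd / 100) * params@baselineLevel *
        .ar1Noise(nVox, length(cols), params@ar1)
    }
  }

  runs <- vector("list", length(nVolRun))
  motion <- vector("list", length(nVolRun))
  off <- 0L
  for (r in seq_along(nVolRun)) {
    cols <- off + seq_len(nVolRun[r])
    runs[[r]] <- new("VolumeSeries",
      data = array(raw[, cols], c(grid, nVolRun[r])),
      voxelDims = voxelDims, tr = tr, runId = sprintf("run-%d", r),
      mask = NULL)
    motion[[r]] <- .simulateMotion(nVolRun[r],
      taskValues = regressorValues(xTask)[cols],
      taskCoupling = motionCoupling)
    off <- off + nVolRun[r]
  }
  truth <- new("GroundTruth", betaTask = effects@betaTask,
               betaRt = effects@betaRt, schedule = schedule,
               regressors = c(list(task = xTask, rt = xRt),
                              if (!is.null(xInc)) list(incorrect = xInc)))
  list(runs = runs, motion = motion, truth = truth)
}

#' Simulate and write a multi-subject cohort to disk
#'
#' Generates \code{nSubjects} subjects under a shared protocol and effect
#' geography — each with their own schedule, reaction times, noise and
#' motion — and writes a directory layout consumable by
#' \code{\link{fitSubjectDir}} and the command-line interface: per subject
#' one 4D NIfTI, one events table and one motion file per run, plus
#' ground-truth beta maps and a JSON manifest recording every seed and
#' parameter.
#'
#' @param outDir output directory; must be empty or absent unless
#'   \code{overwrite}.
#' @param nSubjects cohort size, >= 2.
#' @param protocol a \linkS4class{ProtocolSpec}.
#' @param effects an \linkS4class{EffectMapSpec}; defaults to an all-null map
#'   on the protocol grid.
#' @param subjectParams optional list of \linkS4class{SubjectParams}, one per
#'   subject; drawn by \code{\link{sampleCohortParams}} when \code{NULL}.
#' @param seed master integer seed; per-subject seeds are \code{seed + i}.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param ... passed to \code{\link{simulateBold}}.
#' @return (invisibly) the manifest list.
#' @export
simulateCohort <- function(outDir, nSubjects = 30L, protocol = ProtocolSpec(),
                           effects = NULL, subjectParams = NULL, seed = 1L,
                           overwrite = FALSE, ...) {
  stopifnot(nSubjects >= 2L)
  if (dir.exists(outDir) && length(dir(outDir)) > 0L && !overwrite)
    stop("output directory ", outDir, " is not empty; use overwrite = TRUE")
  dir.create(file.path(outDir, "truth"), recursive = TRUE, showWarnings = FALSE)
  if (is.null(effects))
    effects <- effectMapSpec(protocol@gridShape)
  if (is.null(subjectParams))
    subjectParams <- sampleCohortParams(nSubjects, seed = seed)
  stopifnot(length(subjectParams) == nSubjects)

  writeVolume3D(effects@betaTask, file.path(outDir, "truth", "beta_task.nii.gz"),
                voxelDims = protocol@voxelDims)
  writeVolume3D(effects@betaRt, file.path(outDir, "truth", "beta_rt.nii.gz"),
                voxelDims = protocol@voxelDims)

  subjects <- list()
  for (i in seq_len(nSubjects)) {
    sid <- sprintf("sub-%02d", i)
    sdir <- file.path(outDir, sid)
    dir.create(sdir, showWarnings = FALSE)
    subSeed <- seed + i
    sched <- simulateSchedule(protocol, seed = subSeed)
    sched <- simulateRTs(subjectParams[[i]], sched)
    sim <- simulateBold(sched, effects, subjectParams[[i]],
                        voxelDims = protocol@voxelDims, ...)
    for (r in seq_len(nRuns(sched))) {
      writeVolume(sim$runs[[r]],
                  file.path(sdir, sprintf("run-%d_bold.nii.gz", r)))
      writeEvents(sched, r, file.path(sdir, sprintf("run-%d_events.tsv", r)))
      writeMotion(sim$motion[[r]],
                  file.path(sdir, sprintf("run-%d_motion.txt", r)))
    }
    p <- subjectParams[[i]]
    subjects[[sid]] <- list(seed = subSeed,
      rtLocation = p@rtLocation, rtScale = p@rtScale,
      accuracyRate = p@accuracyRate, baselineLevel = p@baselineLevel,
      noiseSd = p@noiseSd, ar1 = p@ar1, driftAmplitude = p@driftAmplitude)
  }
  manifest <- list(
    package = "rtbold",
    version = as.character(utils::packageVersion("rtbold")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, nSubjects = nSubjects,
    protocol = list(nRuns = protocol@nRuns,
      trialsPerRun = protocol@trialsPerRun,
      trialDuration = protocol@trialDuration,
      restDurations = protocol@restDurations,
      restsPerRun = protocol@restsPerRun, tr = protocol@tr,
      volumesPerRun = protocol@volumesPerRun,
      gridShape = protocol@gridShape, voxelDims = protocol@voxelDims),
    subjects = subjects)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
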