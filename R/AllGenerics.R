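# Generics and accessors. Slot access everywhere else goes through these.

#' @rdname TrialSchedule-class
#' @param x a \linkS4class{TrialSchedule}.
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname TrialSchedule-class
#' @export
setMethod("events", "TrialSchedule", function(x) x@events)

#' @rdname TrialSchedule-class
#' @export
setGeneric("restPeriods", function(x) standardGeneric("restPeriods"))
#' @rdname TrialSchedule-class
#' @export
setMethod("restPeriods", "TrialSchedule", function(x) x@rests)

#' @rdname TrialSchedule-class
#' @export
setGeneric("nRuns", function(x) standardGeneric("nRuns"))
#' @rdname TrialSchedule-class
#' @export
setMethod("nRuns", "TrialSchedule", function(x) length(x@nVolumes))

#' @rdname TrialSchedule-class
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))
#' @rdname TrialSchedule-class
#' @export
setMethod("nVolumes", "TrialSchedule", function(x) x@nVolumes)

#' @rdname TrialSchedule-class
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
#' @rdname TrialSchedule-class
#' @export
setMethod("repetitionTime", "TrialSchedule", function(x) x@tr)
#' @rdname VolumeSeries-class
#' @export
setMethod("repetitionTime", "VolumeSeries", function(x) x@tr)
#' @rdname Regressor-class
#' @export
setMethod("repetitionTime", "Regressor", function(x) x@tr)

#' @rdname Regressor-class
#' @param x a \linkS4class{Regressor}.
#' @export
setGeneric("regressorValues", function(x) standardGeneric("regressorValues"))
#' @rdname Regressor-class
#' @export
setMethod("regressorValues", "Regressor", function(x) x@values)

#' @rdname Regressor-class
#' @export
setGeneric("regressorLabel", function(x) standardGeneric("regressorLabel"))
#' @rdname Regressor-class
#' @export
setMethod("regressorLabel", "Regressor", function(x) x@label)

#' @rdname Regressor-class
#' @export
setGeneric("runStarts", function(x) standardGeneric("runStarts"))
#' @rdname Regressor-class
#' @export
setMethod("runStarts", "Regressor", function(x) x@runStarts)

#' @rdname VolumeSeries-class
#' @param x a \linkS4class{VolumeSeries}.
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))
#' @rdname VolumeSeries-class
#' @export
setMethod("boldData", "VolumeSeries", function(x) x@data)

#' @rdname VolumeSeries-class
#' @export
setGeneric("voxelDims", function(x) standardGeneric("voxelDims"))
#' @rdname VolumeSeries-class
#' @export
setMethod("voxelDims", "VolumeSeries", function(x) x@voxelDims)

#' @rdname VolumeSeries-class
#' @export
setGeneric("analysisMask", function(x) standardGeneric("analysisMask"))
#' @rdname VolumeSeries-class
#' @export
setMethod("analysisMask", "VolumeSeries", function(x) x@mask)
#' @rdname BetaMaps-class
#' @export
setMethod("analysisMask", "BetaMaps", function(x) x@mask)
#' @rdname GroupStatMap-class
#' @export
setMethod("analysisMask", "GroupStatMap", function(x) x@mask)

#' @rdname DesignMatrix-class
#' @param x a \linkS4class{DesignMatrix}.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))
#' @rdname DesignMatrix-class
#' @export
setMethod("designMatrix", "DesignMatrix", function(x) x@X)

#' @rdname DesignMatrix-class
#' @export
setGeneric("effectColumns", function(x) standardGeneric("effectColumns"))
#' @rdname DesignMatrix-class
#' @export
setMethod("effectColumns", "DesignMatrix", function(x) x@effectColumns)

#' @rdname DesignMatrix-class
#' @export
setGeneric("conditionNumber", function(x) standardGeneric("conditionNumber"))
#' @rdname DesignMatrix-class
#' @export
setMethod("conditionNumber", "DesignMatrix", function(x) x@kappa)

#' @rdname BetaMaps-class
#' @param x a \linkS4class{BetaMaps}.
#' @export
setGeneric("betaLabels", function(x) standardGeneric("betaLabels"))
#' @rdname BetaMaps-class
#' @export
setMethod("betaLabels", "BetaMaps", function(x) x@labels)

#' Extract one effect map
#'
#' @param x a \linkS4class{BetaMaps}.
#' @param label effect label, e.g. \code{"task"} or \code{"rt"}.
#' @return 3D array of betas, percent signal change per unit regressor.
#' @export
setGeneric("betaMap", function(x, label) standardGeneric("betaMap"))
#' @rdname betaMap
#' @export
setMethod("betaMap", "BetaMaps", function(x, label) {
  i <- match(label, x@labels)
  if (is.na(i)) stop("no effect named '", label, "'; available: ",
                     paste(x@labels, collapse = ", "))
  array(x@betas[, , , i, drop = FALSE], dim(x@betas)[1:3])
})

#' @rdname BetaMaps-class
#' @export
setGeneric("dfResidual", function(x) standardGeneric("dfResidual"))
#' @rdname BetaMaps-class
#' @export
setMethod("dfResidual", "BetaMaps", function(x) x@df)

#' @rdname GroupStatMap-class
#' @param x a \linkS4class{GroupStatMap}.
#' @export
setGeneric("tMap", function(x) standardGeneric("tMap"))
#' @rdname GroupStatMap-class
#' @export
setMethod("tMap", "GroupStatMap", function(x) x@tMap)

#' @rdname GroupStatMap-class
#' @export
setGeneric("pMap", function(x) standardGeneric("pMap"))
#' @rdname GroupStatMap-class
#' @export
setMethod("pMap", "GroupStatMap", function(x) x@pMap)

# show methods ---------------------------------------------------------------

setMethod("show", "ProtocolSpec", function(object) {
  cat(sprintf(
    "ProtocolSpec: %d run(s) x %d trials (%.1f s), %d rests/run from {%s} s\n",
    object@nRuns, object@trialsPerRun, object@trialDuration,
    object@restsPerRun, paste(object@restDurations, collapse = ", ")))
  cat(sprintf("  TR = %g s, %d volumes/run; grid %s at %s mm\n",
    object@tr, object@volumesPerRun,
    paste(object@gridShape, collapse = "x"),
    paste(object@voxelDims, collapse = "x")))
})

setMethod("show", "TrialSchedule", function(object) {
  ev <- object@events
  cat(sprintf("TrialSchedule: %d trial(s) over %d run(s), TR = %g s\n",
    nrow(ev), length(object@nVolumes), object@tr))
  nc <- sum(ev$correct, na.rm = TRUE)
  if (all(is.na(ev$correct)))
    cat("  responses not yet simulated/recorded\n")
  else
    cat(sprintf("  %d correct (%.1f%%), median RT %.0f ms\n", nc,
      100 * nc / nrow(ev), stats::median(ev$response_time, na.rm = TRUE)))
})

setMethod("show", "Regressor", function(object) {
  cat(sprintf("Regressor '%s': %d volumes over %d run(s), range [%.4g, %.4g]\n",
    object@label, length(object@values), length(object@runStarts),
    min(object@values), max(object@values)))
})

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeSeries '%s': %dx%dx%d voxels x %d volumes, %gx%gx%g mm, TR = %g s\n",
    object@runId, d[1], d[2], d[3], d[4],
    object@voxelDims[1], object@voxelDims[2], object@voxelDims[3], object@tr))
  if (!is.null(object@mask))
    cat(sprintf("  mask: %d of %d voxels\n", sum(object@mask), prod(d[1:3])))
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d volumes x %d columns (%d effect, %d nuisance)\n",
    nrow(object@X), ncol(object@X), length(object@effectColumns),
    ncol(object@X) - length(object@effectColumns)))
  cat(sprintf("  runs: %s volumes; condition number %.3g\n",
    paste(object@runLengths, collapse = " + "), object@kappa))
})

setMethod("show", "BetaMaps", function(object) {
  d <- dim(object@betas)
  cat(sprintf("BetaMaps: effects [%s] on a %dx%dx%d grid, df = %g\n",
    paste(object@labels, collapse = ", "), d[1], d[2], d[3], object@df))
})

setMethod("show", "GroupStatMap", function(object) {
  tm <- object@tMap[object@mask]
  cat(sprintf("GroupStatMap: n = %d subjects, df = %g, t in [%.2f, %.2f]\n",
    object@nSubjects, object@df, min(tm), max(tm)))
})

setMethod("show", "SubjectParams", function(object) {
  cat(sprintf(
    "SubjectParams: RT ~ lognormal(%.3f, %.3f) ms, accuracy %.3f\n",
    object@rtLocation, object@rtScale, object@accuracyRate))
  cat(sprintf("  baseline %g, noise %.2f%% (AR1 %.2f), drift %.2f%%\n",
    object@baselineLevel, object@noiseSd, object@ar1, object@driftAmplitude))
})

setMethod("show", "EffectMapSpec", function(object) {
  cat(sprintf("EffectMapSpec: grid %s, %d region(s)\n",
    paste(object@gridShape, collapse = "x"), length(object@regions)))
  for (rg in object@regions)
    cat(sprintf("  %-13s %5d voxels, beta_task = %g, beta_rt = %g\n",
      rg$role, sum(rg$mask), rg$betaTask, rg$betaRt))
})

setMethod("show", "ClusterThresholdSpec", function(object) {
  cat(sprintf(
    "ClusterThresholdSpec: %d mask voxels, fwhm %g mm, voxel p %g, FWE alpha %g\n",
    sum(object@mask), object@fwhm, object@voxelP, object@alphaFwe))
  cat(sprintf("  %s connectivity, %d iterations, seed %d\n",
    object@connectivity, object@nIterations, object@seed))
})
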