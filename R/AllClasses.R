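#' @import methods
NULL

#' Acquisition and task protocol description
#'
#' Describes the event-related acquisition protocol: how many runs, how many
#' trials and rest periods per run, the trial and rest durations, the
#' repetition time, the number of volumes per run, and the voxel grid on which
#' synthetic data are generated.
#'
#' @slot nRuns number of functional runs.
#' @slot trialsPerRun number of task trials per run.
#' @slot trialDuration stimulus/response window duration, seconds.
#' @slot restDurations candidate jittered rest durations, seconds.
#' @slot restsPerRun number of rest periods per run.
#' @slot tr repetition time, seconds.
#' @slot volumesPerRun volumes acquired per run.
#' @slot gridShape synthetic voxel grid, voxels per axis.
#' @slot voxelDims voxel size, mm per axis.
#' @export
setClass("ProtocolSpec",
  representation(
    nRuns = "integer", trialsPerRun = "integer", trialDuration = "numeric",
    restDurations = "numeric", restsPerRun = "integer", tr = "numeric",
    volumesPerRun = "integer", gridShape = "integer", voxelDims = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nRuns < 1L) msg <- c(msg, "nRuns must be >= 1")
    if (object@trialsPerRun < 1L) msg <- c(msg, "trialsPerRun must be >= 1")
    if (object@trialDuration <= 0) msg <- c(msg, "trialDuration must be > 0")
    if (object@tr <= 0) msg <- c(msg, "tr must be > 0")
    if (any(object@restDurations < 0)) msg <- c(msg, "rest durations must be >= 0")
    if (object@restsPerRun < 0L) msg <- c(msg, "restsPerRun must be >= 0")
    if (object@volumesPerRun * object@tr < object@trialsPerRun * object@trialDuration)
      msg <- c(msg, "total trial time exceeds run length (volumesPerRun * tr)")
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
      msg <- c(msg, "gridShape must be three positive integers")
    if (length(object@voxelDims) != 3L || any(object@voxelDims <= 0))
      msg <- c(msg, "voxelDims must be three positive values (mm)")
    if (length(msg)) msg else TRUE
  })

#' Per-run trial event schedule
#'
#' Holds the trial events of a multi-run session: one row per trial with run
#' index, onset and duration (seconds), response time (ms, \code{NA} for
#' no-response trials), correctness flag, and probe-present flag, together
#' with the rest periods that separate trials, the repetition time and the
#' per-run volume counts.
#'
#' @slot events \code{data.frame} with columns \code{run}, \code{onset},
#'   \code{duration}, \code{response_time}, \code{correct},
#'   \code{probe_present}.
#' @slot rests \code{data.frame} of rest periods with columns \code{run},
#'   \code{onset}, \code{duration}.
#' @slot tr repetition time, seconds.
#' @slot nVolumes integer vector of volumes per run.
#' @export
setClass("TrialSchedule",
  representation(events = "data.frame", rests = "data.frame",
                 tr = "numeric", nVolumes = "integer"),
  validity = function(object) {
    ev <- object@events
    need <- c("run", "onset", "duration", "response_time", "correct", "probe_present")
    miss <- setdiff(need, names(ev))
    if (length(miss))
      return(paste("events is missing columns:", paste(miss, collapse = ", ")))
    if (object@tr <= 0) return("tr must be > 0")
    if (any(ev$onset < 0)) return("onsets must be >= 0")
    for (r in unique(ev$run)) {
      on <- ev$onset[ev$run == r]
      du <- ev$duration[ev$run == r]
      if (any(diff(on) <= 0))
        return(sprintf("onsets must be strictly increasing within run %d", r))
      if (r > length(object@nVolumes)) return("run index exceeds nVolumes length")
      if (any(on + du > object@nVolumes[r] * object@tr + 1e-9))
        return(sprintf("trial extends past the end of run %d", r))
    }
    rt <- ev$response_time
    if (any(!is.na(rt) & rt <= 0)) return("response times must be positive")
    TRUE
  })

#' Subject-level generative parameters
#'
#' Parameters of one simulated subject: the lognormal reaction-time law
#' (location and scale on the log-ms scale), response accuracy, and the BOLD
#' noise model (baseline intensity, AR(1) noise as percent of baseline, slow
#' drift amplitude).
#'
#' @slot rtLocation lognormal location, log-ms.
#' @slot rtScale lognormal scale, log-ms.
#' @slot accuracyRate probability of a correct response.
#' @slot baselineLevel baseline signal intensity, arbitrary scanner units.
#' @slot noiseSd AR(1) noise standard deviation, percent of baseline.
#' @slot ar1 AR(1) autocorrelation coefficient, in (-1, 1).
#' @slot driftAmplitude slow cosine drift amplitude, percent of baseline.
#' @export
setClass("SubjectParams",
  representation(rtLocation = "numeric", rtScale = "numeric",
                 accuracyRate = "numeric", baselineLevel = "numeric",
                 noiseSd = "numeric", ar1 = "numeric", driftAmplitude = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@rtScale < 0) msg <- c(msg, "rtScale must be >= 0")
    if (object@accuracyRate < 0 || object@accuracyRate > 1)
      msg <- c(msg, "accuracyRate must be in [0, 1]")
    if (object@baselineLevel <= 0) msg <- c(msg, "baselineLevel must be > 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (abs(object@ar1) >= 1) msg <- c(msg, "|ar1| must be < 1")
    if (object@driftAmplitude < 0) msg <- c(msg, "driftAmplitude must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Planted effect geography
#'
#' Voxel-wise ground-truth effect maps used by the synthetic BOLD generator:
#' a task-response amplitude map (percent signal change per unit canonical
#' regressor) and an RT-coupling map (percent signal change per unit residual
#' log-RT regressor), together with the labelled regions that define them.
#'
#' @slot gridShape voxels per axis.
#' @slot betaTask 3D array of task-effect amplitudes, percent signal change.
#' @slot betaRt 3D array of RT-coupling slopes, percent signal change per
#'   unit centered log-RT.
#' @slot regions list of regions, each a list with elements \code{mask}
#'   (logical 3D array), \code{role}, \code{betaTask}, \code{betaRt}.
#' @export
setClass("EffectMapSpec",
  representation(gridShape = "integer", betaTask = "array", betaRt = "array",
                 regions = "list"),
  validity = function(object) {
    if (!identical(dim(object@betaTask), object@gridShape) ||
        !identical(dim(object@betaRt), object@gridShape))
      return("beta map dimensions must equal gridShape")
    roles <- c("task_positive", "task_negative", "rt_positive", "rt_negative", "null")
    cover <- array(0L, object@gridShape)
    for (rg in object@regions) {
      if (!rg$role %in% roles)
        return(paste("unknown region role:", rg$role))
      if (!identical(dim(rg$mask), object@gridShape))
        return("region mask dimensions must equal gridShape")
      if (rg$role == "null" && (rg$betaTask != 0 || rg$betaRt != 0))
        return("null regions must have both betas equal to 0")
      cover <- cover + rg$mask
    }
    if (any(cover > 1L)) return("regions must be disjoint")
    TRUE
  })

#' Ground truth record for a simulated subject
#'
#' @slot betaTask 3D array of planted task effects.
#' @slot betaRt 3D array of planted RT-coupling effects.
#' @slot schedule the \linkS4class{TrialSchedule} used, with simulated RTs.
#' @slot regressors list of the exact \linkS4class{Regressor} objects used to
#'   render the signal.
#' @export
setClass("GroundTruth",
  representation(betaTask = "array", betaRt = "array",
                 schedule = "TrialSchedule", regressors = "list"))

#' Model regressor sampled on the volume grid
#'
#' A per-volume model time-series spanning all runs of a session, with the
#' index of the first volume of each run recorded so run-aware operations
#' (centering, orthogonalization, design building) know the block structure.
#'
#' @slot label regressor name.
#' @slot values numeric amplitude per volume, all runs concatenated.
#' @slot runStarts integer index of the first volume of each run.
#' @slot tr repetition time, seconds.
#' @export
setClass("Regressor",
  representation(label = "character", values = "numeric",
                 runStarts = "integer", tr = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@values))) return("regressor values must be finite")
    if (length(object@runStarts) < 1L || object@runStarts[1L] != 1L)
      return("runStarts must begin at 1")
    if (any(diff(object@runStarts) <= 0) ||
        any(object@runStarts > length(object@values)))
      return("runStarts must be increasing and within the series")
    if (object@tr <= 0) return("tr must be > 0")
    TRUE
  })

#' 4D BOLD volume series
#'
#' A 4D intensity array indexed (x, y, z, t) with voxel dimensions (mm),
#' repetition time (s), a run identifier and an optional analysis mask.
#'
#' @slot data 4D numeric array.
#' @slot voxelDims voxel size, mm per axis.
#' @slot tr repetition time, seconds.
#' @slot runId run identifier.
#' @slot mask logical 3D array or \code{NULL}.
#' @export
setClass("VolumeSeries",
  representation(data = "array", voxelDims = "numeric", tr = "numeric",
                 runId = "character", mask = "ANY"),
  validity = function(object) {
    if (length(dim(object@data)) != 4L) return("data must be a 4D array")
    if (any(!is.finite(object@data))) return("data must be finite")
    if (length(object@voxelDims) != 3L || any(object@voxelDims <= 0))
      return("voxelDims must be three positive values (mm)")
    if (object@tr <= 0) return("tr must be > 0")
    if (!is.null(object@mask)) {
      if (!is.logical(object@mask) ||
          !identical(dim(object@mask), dim(object@data)[1:3]))
        return("mask must be a logical array matching the spatial grid")
    }
    TRUE
  })

#' Deconvolution design matrix
#'
#' Volumes-by-columns design with per-run intercepts and polynomial drift,
#' optional motion nuisances, and the effect regressors of interest. The
#' condition number of the assembled matrix is recorded.
#'
#' @slot X numeric matrix with named columns.
#' @slot effectColumns names of the effect (non-nuisance) columns.
#' @slot runLengths volumes per run.
#' @slot kappa condition number of \code{X}.
#' @export
setClass("DesignMatrix",
  representation(X = "matrix", effectColumns = "character",
                 runLengths = "integer", kappa = "numeric"),
  validity = function(object) {
    if (is.null(colnames(object@X))) return("design columns must be named")
    if (nrow(object@X) != sum(object@runLengths))
      return("design rows must equal total volumes")
    if (!all(object@effectColumns %in% colnames(object@X)))
      return("effectColumns must name design columns")
    TRUE
  })

#' Subject-level effect maps
#'
#' Per-effect 3D beta maps in percent-signal-change units, with the residual
#' variance map and residual degrees of freedom of the voxel-wise fit.
#'
#' @slot betas 4D array (x, y, z, effect); the 4th dimension is named by
#'   effect label.
#' @slot labels effect labels.
#' @slot sigma2 3D residual variance map.
#' @slot df residual degrees of freedom (volumes minus design rank).
#' @slot mask logical 3D analysis mask.
#' @export
setClass("BetaMaps",
  representation(betas = "array", labels = "character", sigma2 = "array",
                 df = "numeric", mask = "array"),
  validity = function(object) {
    d <- dim(object@betas)
    if (length(d) != 4L) return("betas must be a 4D array (x, y, z, effect)")
    if (d[4L] != length(object@labels)) return("one label per effect map")
    if (!identical(dim(object@sigma2), d[1:3])) return("sigma2 grid mismatch")
    if (!identical(dim(object@mask), d[1:3])) return("mask grid mismatch")
    if (object@df <= 0) return("df must be positive")
    TRUE
  })

#' Group-level statistical map
#'
#' Voxel-wise one-sample t statistics across subjects with the matching
#' two-sided p map, degrees of freedom (subjects minus one) and the group
#' analysis mask.
#'
#' @slot tMap 3D array of t statistics.
#' @slot pMap 3D array of two-sided p values.
#' @slot df degrees of freedom.
#' @slot nSubjects number of subjects.
#' @slot mask logical 3D array.
#' @export
setClass("GroupStatMap",
  representation(tMap = "array", pMap = "array", df = "numeric",
                 nSubjects = "integer", mask = "array"),
  validity = function(object) {
    if (!identical(dim(object@tMap), dim(object@pMap)))
      return("t and p maps must share a grid")
    if (!identical(dim(object@mask), dim(object@tMap)))
      return("mask grid mismatch")
    if (object@df != object@nSubjects - 1L)
      return("df must equal nSubjects - 1")
    p <- object@pMap[object@mask]
    if (any(p <= 0 | p > 1)) return("p values must lie in (0, 1]")
    TRUE
  })

#' Monte-Carlo cluster-threshold specification
#'
#' Parameters of the null-noise simulation used to calibrate the
#' cluster-extent threshold: the analysis mask and voxel geometry, the
#' applied smoothness, the voxel-wise two-sided threshold, the familywise
#' alpha, the neighbourhood definition and the number of iterations.
#'
#' @slot mask logical 3D array.
#' @slot voxelDims voxel size, mm per axis.
#' @slot fwhm applied Gaussian smoothness, mm.
#' @slot voxelP voxel-wise two-sided p threshold.
#' @slot alphaFwe familywise type-1 error target.
#' @slot connectivity one of \code{"faces"}, \code{"edges"}, \code{"corners"}.
#' @slot nIterations Monte-Carlo iterations.
#' @slot seed integer seed.
#' @export
setClass("ClusterThresholdSpec",
  representation(mask = "array", voxelDims = "numeric", fwhm = "numeric",
                 voxelP = "numeric", alphaFwe = "numeric",
                 connectivity = "character", nIterations = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
      msg <- c(msg, "mask must be a logical 3D array")
    if (object@voxelP <= 0 || object@voxelP >= 1)
      msg <- c(msg, "voxelP must be in (0, 1)")
    if (object@alphaFwe <= 0 || object@alphaFwe >= 1)
      msg <- c(msg, "alphaFwe must be in (0, 1)")
    if (object@fwhm < 0) msg <- c(msg, "fwhm must be >= 0")
    if (!object@connectivity %in% c("faces", "edges", "corners"))
      msg <- c(msg, "connectivity must be faces, edges or corners")
    if (object@nIterations < 100L) msg <- c(msg, "nIterations must be >= 100")
    if (length(msg)) msg else TRUE
  })
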