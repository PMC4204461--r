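# Standard-format I/O: events tables, motion series, NIfTI volumes, config.

#' Write one run's events table
#'
#' Tab-separated with columns \code{onset} and \code{duration} in seconds,
#' \code{response_time} in milliseconds (\code{n/a} for no-response trials),
#' \code{correct} and \code{probe_present} as 0/1.
#'
#' @param schedule a \linkS4class{TrialSchedule}.
#' @param run run index.
#' @param path output file.
#' @export
writeEvents <- function(schedule, run, path) {
  stopifnot(is(schedule, "TrialSchedule"))
  ev <- schedule@events
  ev <- ev[ev$run == run, c("onset", "duration", "response_time", "correct",
                            "probe_present")]
  if (nrow(ev) == 0L) stop("no events for run ", run)
  ev$response_time <- ifelse(is.na(ev$response_time), "n/a",
                             format(ev$response_time, digits = 10))
  ev$correct <- as.integer(ev$correct)
  ev$probe_present <- as.integer(ev$probe_present)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-run events tables into a schedule
#'
#' Each file holds one run (tab-separated; onset/duration in seconds,
#' response_time in ms, \code{n/a} or \code{NA} for no-response trials).
#' Missing required columns and non-monotone onsets are errors naming the
#' file and row.
#'
#' @param paths character vector of event files, one per run, in run order.
#' @param tr repetition time, seconds.
#' @param nVolumes volumes per run (scalar or one per file).
#' @return a \linkS4class{TrialSchedule}.
#' @export
readEvents <- function(paths, tr, nVolumes) {
  stopifnot(length(paths) >= 1L)
  if (length(nVolumes) == 1L) nVolumes <- rep(nVolumes, length(paths))
  need <- c("onset", "duration", "response_time", "correct", "probe_present")
  evAll <- list()
  for (r in seq_along(paths)) {
    ev <- utils::read.table(paths[r], header = TRUE, sep = "\t",
                            na.strings = c("n/a", "NA"),
                            stringsAsFactors = FALSE)
    miss <- setdiff(need, names(ev))
    if (length(miss))
      stop(paths[r], ": missing column(s): ", paste(miss, collapse = ", "))
    bad <- which(diff(ev$onset) <= 0)
    if (length(bad))
      stop(paths[r], ": onsets not strictly increasing at row ", bad[1] + 1L)
    ev$response_time <- as.numeric(ev$response_time)
    noresp <- is.na(ev$response_time)
    ev$correct <- as.logical(ev$correct)
    ev$correct[noresp] <- FALSE
    evAll[[r]] <- data.frame(run = r, onset = ev$onset,
                             duration = ev$duration,
                             response_time = ev$response_time,
                             correct = ev$correct,
                             probe_present = as.logical(ev$probe_present))
  }
  new("TrialSchedule", events = do.call(rbind, evAll),
      rests = data.frame(run = integer(), onset = numeric(),
                         duration = numeric()),
      tr = tr, nVolumes = as.integer(nVolumes))
}

#' Write a motion-parameter series
#'
#' Six whitespace-delimited columns (roll, pitch, yaw, x, y, z), one row per
#' volume.
#'
#' @param motion volumes x 6 numeric matrix.
#' @param path output file.
#' @export
writeMotion <- function(motion, path) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have 6 columns")
  utils::write.table(motion, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a motion-parameter series
#'
#' @param path whitespace-delimited file with 6 numeric columns.
#' @param nVolumes expected number of rows; checked when supplied.
#' @return volumes x 6 matrix with columns roll, pitch, yaw, x, y, z.
#' @export
readMotion <- function(path, nVolumes = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stop(path, ": expected 6 motion columns, found ", ncol(m))
  if (!is.numeric(m)) stop(path, ": motion values must be numeric")
  if (!is.null(nVolumes) && nrow(m) != nVolumes)
    stop(path, ": ", nrow(m), " rows for ", nVolumes, " volumes")
  colnames(m) <- c("roll", "pitch", "yaw", "x", "y", "z")
  m
}

#' Write a 4D volume series as NIfTI
#'
#' Voxel dimensions and TR are stored in the NIfTI pixdim field.
#'
#' @param series a \linkS4class{VolumeSeries}.
#' @param path output .nii or .nii.gz file.
#' @export
writeVolume <- function(series, path) {
  stopifnot(is(series, "VolumeSeries"))
  img <- RNifti::asNifti(series@data)
  RNifti::pixdim(img) <- c(series@voxelDims, series@tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a 3D map as NIfTI
#'
#' @param map 3D numeric or logical array.
#' @param path output file.
#' @param voxelDims voxel size, mm per axis.
#' @export
writeVolume3D <- function(map, path, voxelDims = c(4, 4, 4)) {
  img <- RNifti::asNifti(array(as.numeric(map), dim(map)))
  RNifti::pixdim(img) <- voxelDims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI run
#'
#' @param path .nii or .nii.gz file.
#' @param runId run identifier attached to the result.
#' @return a \linkS4class{VolumeSeries}; voxel dimensions and TR are taken
#'   from the NIfTI pixdim field.
#' @export
readVolume <- function(path, runId = basename(path)) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop(path, ": expected a 4D volume")
  pd <- RNifti::pixdim(img)
  new("VolumeSeries", data = array(as.numeric(img), d),
      voxelDims = pd[1:3], tr = if (length(pd) >= 4L && pd[4] > 0) pd[4] else 1,
      runId = runId, mask = NULL)
}

#' Read a 3D NIfTI map
#'
#' @param path .nii or .nii.gz file.
#' @return 3D numeric array.
#' @export
readVolume3D <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L) stop(path, ": expected a 3D map")
  array(as.numeric(img), d)
}

#' Default run configuration
#'
#' All pipeline parameters with their defaults: acquisition protocol
#' (3 runs x 52 trials of 3.5 s, 23 rests/run, TR = 2 s, 150 volumes/run),
#' HRF (b = 8.6, c = 0.547), preprocessing (fwhm = 8 mm, 10% intensity mask),
#' GLM (drift order 2, motion and incorrect-trial nuisances on) and group
#' inference (voxel p = 0.005, FWE alpha = 0.05, corner connectivity, 2000
#' iterations), plus cohort size 30.
#'
#' @return nested list of parameters.
#' @export
defaultConfig <- function() {
  list(
    protocol = list(n_runs = 3L, trials_per_run = 52L, trial_duration = 3.5,
                    rest_durations = c(0.5, 4.5, 8.5, 12.5),
                    rests_per_run = 23L, tr = 2, volumes_per_run = 150L,
                    grid_shape = c(24L, 24L, 18L), voxel_dims = c(4, 4, 4)),
    hrf = list(b = 8.6, c = 0.547, dt = 0.1),
    preprocess = list(fwhm = 8, mask_fraction = 0.1),
    glm = list(drift_order = 2L, use_motion = TRUE, model_incorrect = TRUE,
               center_log_rt = FALSE),
    group = list(voxel_p = 0.005, alpha_fwe = 0.05, connectivity = "corners",
                 n_iterations = 2000L),
    cohort = list(n_subjects = 30L, seed = 1L))
}

#' Read a YAML run configuration
#'
#' User values are merged over \code{\link{defaultConfig}}, so a config file
#' only needs to state what it overrides.
#'
#' @param path YAML file, or \code{NULL} for pure defaults.
#' @return nested list of parameters.
#' @export
readConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}

.protocolFromConfig <- function(cfg) {
  p <- cfg$protocol
  ProtocolSpec(nRuns = p$n_runs, trialsPerRun = p$trials_per_run,
               trialDuration = p$trial_duration,
               restDurations = unlist(p$rest_durations),
               restsPerRun = p$rests_per_run, tr = p$tr,
               volumesPerRun = p$volumes_per_run,
               gridShape = unlist(p$grid_shape),
               voxelDims = unlist(p$voxel_dims))
}
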