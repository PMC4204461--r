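#' Construct a protocol specification
#'
#' Defaults describe the digit-symbol verification protocol emulated by the
#' synthetic generator: 3 runs of 52 trials of 3.5 s, 23 jittered rest
#' periods per run drawn from {0.5, 4.5, 8.5, 12.5} s, TR = 2 s and 150
#' volumes per run. The synthetic voxel grid defaults to a desk-scale
#' 24 x 24 x 18 lattice of 4 mm voxels; the acquisition geometry is metadata
#' and can be set to anything.
#'
#' @param nRuns number of runs.
#' @param trialsPerRun trials per run.
#' @param trialDuration trial duration, seconds.
#' @param restDurations candidate rest durations, seconds.
#' @param restsPerRun rest periods per run.
#' @param tr repetition time, seconds.
#' @param volumesPerRun volumes per run.
#' @param gridShape synthetic grid, voxels per axis.
#' @param voxelDims voxel size, mm per axis.
#' @return a \linkS4class{ProtocolSpec}.
#' @export
ProtocolSpec <- function(nRuns = 3L, trialsPerRun = 52L, trialDuration = 3.5,
                         restDurations = c(0.5, 4.5, 8.5, 12.5),
                         restsPerRun = 23L, tr = 2, volumesPerRun = 150L,
                         gridShape = c(24L, 24L, 18L),
                         voxelDims = c(4, 4, 4)) {
  new("ProtocolSpec", nRuns = as.integer(nRuns),
      trialsPerRun = as.integer(trialsPerRun), trialDuration = trialDuration,
      restDurations = restDurations, restsPerRun = as.integer(restsPerRun),
      tr = tr, volumesPerRun = as.integer(volumesPerRun),
      gridShape = as.integer(gridShape), voxelDims = voxelDims)
}

#' Simulate a multi-run trial schedule
#'
#' Lays out each run as trials separated by randomly intermixed rest periods.
#' When \code{restsPerRun >= 1}, one rest of each run is the tail after the
#' last trial, padded or truncated so the run length equals exactly
#' \code{volumesPerRun * tr}; the remaining rests are placed in randomly
#' chosen inter-trial gaps with durations drawn from \code{restDurations},
#' restricted at each draw to durations that keep the remaining trials (plus
#' minimal remaining rests) inside the run. Probe-present flags are balanced
#' half present, half absent within each run.
#'
#' @param protocol a \linkS4class{ProtocolSpec}.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return a \linkS4class{TrialSchedule} covering all runs; response times
#'   and correctness are \code{NA} until filled by \code{\link{simulateRTs}}.
#' @export
simulateSchedule <- function(protocol = ProtocolSpec(), seed = NULL) {
  stopifnot(is(protocol, "ProtocolSpec"))
  if (!is.null(seed)) set.seed(seed)
  nT <- protocol@trialsPerRun
  nR <- protocol@restsPerRun
  dur <- protocol@trialDuration
  runLen <- protocol@volumesPerRun * protocol@tr
  minRest <- if (nR > 0L) min(protocol@restDurations) else 0
  minLen <- nT * dur + max(nR - 1L, 0L) * minRest
  if (minLen > runLen + 1e-9)
    stop(sprintf(paste0(
      "protocol cannot fit: %d trials of %g s plus %d rests of at least %g s ",
      "need %.1f s, but the run is %.1f s (%d volumes at TR = %g s)"),
      nT, dur, nR, minRest, minLen, runLen, protocol@volumesPerRun,
      protocol@tr))
  if (nR > 1L && nR - 1L > nT - 1L)
    stop("restsPerRun - 1 interior rests cannot exceed trialsPerRun - 1 gaps")
  evAll <- list()
  restAll <- list()
  for (r in seq_len(protocol@nRuns)) {
    gapHasRest <- logical(max(nT - 1L, 0L))
    if (nR > 1L)
      gapHasRest[sample.int(nT - 1L, nR - 1L)] <- TRUE
    onsets <- numeric(nT)
    rests <- data.frame(run = integer(), onset = numeric(), duration = numeric())
    elapsed <- 0
    for (i in seq_len(nT)) {
      onsets[i] <- elapsed
      elapsed <- elapsed + dur
      if (i < nT && gapHasRest[i]) {
        remTrials <- nT - i
        remRests <- sum(gapHasRest[seq(i + 1L, length.out = max(nT - 1L - i, 0L))])
        budget <- runLen - elapsed - remTrials * dur - remRests * minRest
        cand <- protocol@restDurations[protocol@restDurations <= budget + 1e-9]
        d <- if (length(cand)) cand[sample.int(length(cand), 1L)] else minRest
        rests <- rbind(rests, data.frame(run = r, onset = elapsed, duration = d))
        elapsed <- elapsed + d
      }
    }
    if (nR > 0L) {
      # final rest: the run tail, padded/truncated to the acquisition length
      rests <- rbind(rests, data.frame(run = r, onset = elapsed,
                                       duration = runLen - elapsed))
    }
    present <- sample(rep(c(TRUE, FALSE), length.out = nT))
    evAll[[r]] <- data.frame(run = r, onset = onsets, duration = dur,
                             response_time = NA_real_, correct = NA,
                             probe_present = present)
    restAll[[r]] <- rests
  }
  new("TrialSchedule", events = do.call(rbind, evAll),
      rests = do.call(rbind, restAll), tr = protocol@tr,
      nVolumes = rep(protocol@volumesPerRun, protocol@nRuns))
}
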