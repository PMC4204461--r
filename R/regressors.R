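# Regressor construction: event sticks on a fine grid, convolution with the
# gamma-variate HRF, sampling at volume acquisition times (volume i at i*TR,
# 0-based frame-onset convention), and least-squares residualization.

# convolve stick functions with the HRF for one run and sample at volume times
.convolveRun <- function(onsets, weights, nVol, tr, dt, b, c, hrfSpan = 32) {
  nFine <- as.integer(round(nVol * tr / dt)) + 1L
  stick <- numeric(nFine)
  idx <- as.integer(round(onsets / dt)) + 1L
  for (j in seq_along(idx)) stick[idx[j]] <- stick[idx[j]] + weights[j]
  kern <- gammaHRF(seq(0, hrfSpan, by = dt), b = b, c = c)
  conv <- stats::convolve(stick, rev(kern), type = "open")[seq_len(nFine)]
  step <- as.integer(round(tr / dt))
  conv[1L + (0:(nVol - 1L)) * step]
}

.buildRegressor <- function(schedule, weightFun, label, which, dt, b, c) {
  stopifnot(is(schedule, "TrialSchedule"))
  tr <- schedule@tr
  if (abs(tr / dt - round(tr / dt)) > 1e-9)
    stop("oversample dt must divide the repetition time")
  ev <- schedule@events
  ev$.row <- seq_len(nrow(ev))
  keep <- switch(which,
    correct   = !is.na(ev$correct) & ev$correct,
    incorrect = is.na(ev$correct) | !ev$correct,
    all       = rep(TRUE, nrow(ev)))
  nVol <- schedule@nVolumes
  values <- numeric(0)
  for (r in seq_along(nVol)) {
    sel <- keep & ev$run == r
    if (!any(sel)) {
      values <- c(values, numeric(nVol[r]))
      next
    }
    w <- weightFun(ev[sel, , drop = FALSE])
    values <- c(values,
                .convolveRun(ev$onset[sel], w, nVol[r], tr, dt, b, c))
  }
  if (all(values == 0))
    warning("no contributing trials: regressor '", label, "' is all zero")
  new("Regressor", label = label, values = values,
      runStarts = c(1L, cumsum(nVol)[-length(nVol)] + 1L), tr = tr)
}

#' Canonical task regressor
#'
#' Superposes one unit-peak gamma-variate HRF at each trial onset (correct
#' trials only, by default), evaluated on a fine time grid and sampled at the
#' volume acquisition times. Overlapping responses add linearly.
#'
#' @param schedule a \linkS4class{TrialSchedule}.
#' @param dt oversampling step, seconds; must divide the TR.
#' @param b,c gamma-variate HRF parameters (see \code{\link{gammaHRF}}).
#' @param which which trials contribute: \code{"correct"} (default),
#'   \code{"incorrect"} (incorrect or no-response trials, used as a nuisance),
#'   or \code{"all"}.
#' @return a \linkS4class{Regressor}.
#' @export
canonicalRegressor <- function(schedule, dt = 0.1, b = 8.6, c = 0.547,
                               which = c("correct", "incorrect", "all")) {
  which <- match.arg(which)
  .buildRegressor(schedule, function(ev) rep(1, nrow(ev)),
                  label = paste0("task_", which), which = which,
                  dt = dt, b = b, c = c)
}

#' RT-modulated task regressor
#'
#' Each correct trial's HRF is proportionally scaled by the trial-level
#' standardized RT, taken as the natural logarithm of the reaction time in
#' milliseconds, before superposition. Optionally the log-RTs are mean
#' centered or z-scored across the session first (both off by default).
#'
#' @inheritParams canonicalRegressor
#' @param center subtract the session mean of log(RT) before scaling.
#' @param zscore divide the (optionally centered) log-RTs by their session SD.
#' @return a \linkS4class{Regressor}.
#' @export
rtModulatedRegressor <- function(schedule, dt = 0.1, b = 8.6, c = 0.547,
                                 center = FALSE, zscore = FALSE) {
  ev <- schedule@events
  use <- !is.na(ev$correct) & ev$correct
  rt <- ev$response_time[use]
  if (any(is.na(rt) | rt <= 0))
    stop("all correct trials must have a positive response time")
  lrt <- log(rt)
  off <- if (center || zscore) mean(lrt) else 0
  scl <- if (zscore) stats::sd(lrt) else 1
  wAll <- rep(NA_real_, nrow(ev))
  wAll[use] <- (lrt - off) / scl
  .buildRegressor(schedule, function(evSub) wAll[evSub$.row],
                  label = "task_rtmod", which = "correct",
                  dt = dt, b = b, c = c)
}

#' Residualize the RT-modulated regressor
#'
#' Least-squares residual of the RT-modulated regressor on the canonical
#' regressor and run-wise intercepts, removing the canonical HRF effects and
#' leaving the trial-level RT time-series. The residual is orthogonal to the
#' canonical regressor and to the constant (and each run's) intercept.
#'
#' @param modulated the RT-modulated \linkS4class{Regressor}.
#' @param canonical the canonical \linkS4class{Regressor}.
#' @return a \linkS4class{Regressor} labelled \code{"rt"}.
#' @export
orthogonalizeRegressor <- function(modulated, canonical) {
  stopifnot(is(modulated, "Regressor"), is(canonical, "Regressor"))
  if (length(modulated@values) != length(canonical@values))
    stop("regressors must have equal length")
  if (!identical(modulated@runStarts, canonical@runStarts))
    stop("regressors must share run boundaries")
  y <- modulated@values
  blocks <- .runBlockFactor(modulated@runStarts, length(y))
  intercepts <- vapply(seq_along(modulated@runStarts),
                       function(r) as.numeric(blocks == r), numeric(length(y)))
  if (all(canonical@values == 0)) {
    warning("canonical regressor is identically zero; returning the ",
            "run-centered modulated regressor")
    res <- y - stats::ave(y, blocks)
  } else {
    X <- cbind(intercepts, canonical@values)
    res <- stats::lm.fit(X, y)$residuals
  }
  new("Regressor", label = "rt", values = as.numeric(res),
      runStarts = modulated@runStarts, tr = modulated@tr)
}

# factor assigning each volume to its run block
.runBlockFactor <- function(runStarts, n) {
  ends <- c(runStarts[-1L] - 1L, n)
  factor(rep(seq_along(runStarts), times = ends - runStarts + 1L))
}

#' Center a regressor within each run
#'
#' Subtracts each run's mean from the regressor values. Used by the synthetic
#' generator so that planted signals leave the per-run temporal mean of the
#' raw series untouched.
#'
#' @param x a \linkS4class{Regressor}.
#' @return a \linkS4class{Regressor}.
#' @export
centerRegressor <- function(x) {
  stopifnot(is(x, "Regressor"))
  blocks <- .runBlockFactor(x@runStarts, length(x@values))
  new("Regressor", label = x@label,
      values = as.numeric(x@values - stats::ave(x@values, blocks)),
      runStarts = x@runStarts, tr = x@tr)
}

#' Write regressors as a plain-text design file
#'
#' One column per regressor, one row per volume, tab separated, for
#' inspection with external tools.
#'
#' @param regressors list of \linkS4class{Regressor} objects.
#' @param path output file.
#' @export
writeRegressors <- function(regressors, path) {
  stopifnot(length(regressors) >= 1L)
  vals <- lapply(regressors, regressorValues)
  if (length(unique(lengths(vals))) != 1L)
    stop("regressors must have equal length")
  df <- as.data.frame(vals, col.names = vapply(regressors, regressorLabel, ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
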