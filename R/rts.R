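#' Construct subject-level generative parameters
#'
#' Defaults place the subject near the behavioural profile the generator
#' emulates: mean RT about 1696 ms with within-subject SD about 380 ms
#' (lognormal law), 94.2% accuracy, 1% AR(1) BOLD noise and 0.5% slow drift.
#'
#' @param meanRT target mean reaction time, ms; converted to the lognormal
#'   location/scale together with \code{sdRT}.
#' @param sdRT target within-subject RT standard deviation, ms.
#' @param accuracyRate probability of a correct response.
#' @param baselineLevel baseline signal intensity, arbitrary units.
#' @param noiseSd AR(1) noise SD, percent of baseline.
#' @param ar1 AR(1) coefficient, |ar1| < 1.
#' @param driftAmplitude slow cosine drift amplitude, percent of baseline.
#' @param rtLocation,rtScale lognormal parameters on the log-ms scale;
#'   when supplied they override \code{meanRT}/\code{sdRT}.
#' @return a \linkS4class{SubjectParams}.
#' @export
SubjectParams <- function(meanRT = 1695.92, sdRT = 379.60,
                          accuracyRate = 0.9422, baselineLevel = 1000,
                          noiseSd = 1, ar1 = 0.3, driftAmplitude = 0.5,
                          rtLocation = NULL, rtScale = NULL) {
  if (is.null(rtLocation) || is.null(rtScale)) {
    p <- lognormalFromMoments(meanRT, sdRT)
    rtLocation <- p[["location"]]
    rtScale <- p[["scale"]]
  }
  new("SubjectParams", rtLocation = rtLocation, rtScale = rtScale,
      accuracyRate = accuracyRate, baselineLevel = baselineLevel,
      noiseSd = noiseSd, ar1 = ar1, driftAmplitude = driftAmplitude)
}

#' Lognormal parameters from mean and SD
#'
#' Moment inversion for the lognormal RT law: given a target mean m and SD s,
#' scale^2 = log(1 + (s/m)^2) and location = log(m) - scale^2 / 2.
#'
#' @param meanRT target mean, ms.
#' @param sdRT target SD, ms.
#' @return named vector with \code{location} and \code{scale} (log-ms).
#' @export
lognormalFromMoments <- function(meanRT, sdRT) {
  stopifnot(meanRT > 0, sdRT >= 0)
  s2 <- log1p((sdRT / meanRT)^2)
  c(location = log(meanRT) - s2 / 2, scale = sqrt(s2))
}

#' Simulate trial reaction times and correctness
#'
#' Draws per-trial RTs from the subject's lognormal law. RTs exceeding the
#' response window (the trial duration) are treated as no-response trials:
#' the response time is set to \code{NA} and the trial is marked incorrect.
#' Correctness of responded trials is Bernoulli with the subject's accuracy
#' rate.
#'
#' @param params a \linkS4class{SubjectParams}.
#' @param schedule a \linkS4class{TrialSchedule}.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return the schedule with \code{response_time} (ms) and \code{correct}
#'   filled in.
#' @export
simulateRTs <- function(params, schedule, seed = NULL) {
  stopifnot(is(params, "SubjectParams"), is(schedule, "TrialSchedule"))
  if (!is.null(seed)) set.seed(seed)
  ev <- schedule@events
  n <- nrow(ev)
  rt <- exp(stats::rnorm(n, params@rtLocation, params@rtScale))
  window <- ev$duration * 1000          # response window in ms
  responded <- rt <= window
  correct <- responded &
    (stats::runif(n) < params@accuracyRate)
  ev$response_time <- ifelse(responded, rt, NA_real_)
  ev$correct <- correct
  schedule@events <- ev
  validObject(schedule)
  schedule
}

#' Draw a cohort of subject parameter sets
#'
#' Subject mean and SD RT are drawn from a bivariate normal whose moments
#' emulate the behavioural profile the generator targets: cohort mean RT
#' about 1696 ms (between-subject SD 273 ms), within-subject RT SD about
#' 380 ms (SD 96 ms), and a strong positive coupling (r = 0.84) between a
#' subject's mean and SD. Accuracy is normal around 94.2% (SD 2.25%),
#' clipped to [0.5, 1].
#'
#' @param nSubjects cohort size.
#' @param meanRT,sdMeanRT cohort mean and between-subject SD of subject mean
#'   RT, ms.
#' @param meanSdRT,sdSdRT cohort mean and SD of the within-subject RT SD, ms.
#' @param corMeanSd correlation between subject mean RT and subject SD RT.
#' @param meanAccuracy,sdAccuracy accuracy distribution across subjects.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @param ... further arguments passed to \code{\link{SubjectParams}}
#'   (noise, drift, baseline).
#' @return list of \linkS4class{SubjectParams}, one per subject.
#' @export
sampleCohortParams <- function(nSubjects, meanRT = 1695.92, sdMeanRT = 272.94,
                               meanSdRT = 379.60, sdSdRT = 96.38,
                               corMeanSd = 0.84, meanAccuracy = 0.9422,
                               sdAccuracy = 0.0225, seed = NULL, ...) {
  stopifnot(nSubjects >= 1L, abs(corMeanSd) <= 1)
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(nSubjects)
  z2 <- corMeanSd * z1 + sqrt(1 - corMeanSd^2) * stats::rnorm(nSubjects)
  m <- pmax(meanRT + sdMeanRT * z1, 400)
  s <- pmax(meanSdRT + sdSdRT * z2, 40)
  acc <- pmin(pmax(stats::rnorm(nSubjects, meanAccuracy, sdAccuracy), 0.5), 1)
  lapply(seq_len(nSubjects), function(i)
    SubjectParams(meanRT = m[i], sdRT = s[i], accuracyRate = acc[i], ...))
}
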