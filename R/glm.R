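# Per-voxel deconvolution GLM: design assembly and ordinary least squares.

# Legendre polynomials P1..Pord evaluated on n points spanning [-1, 1]
.legendreDrift <- function(n, order) {
  if (order < 1L) return(matrix(0, n, 0))
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1L)
  P[, 1L] <- 1
  if (order >= 1L) P[, 2L] <- x
  if (order >= 2L)
    for (k in 2:order)
      P[, k + 1L] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1L]) / k
  P[, -1L, drop = FALSE]
}

#' Assemble the deconvolution design matrix
#'
#' Columns are, in order: one intercept per run, per-run Legendre polynomial
#' drift up to \code{driftOrder}, the six motion nuisances (roll, pitch,
#' yaw, x, y, z) when supplied, any extra nuisance regressors, and the
#' effect regressors of interest. Constant motion columns (e.g. all-zero
#' motion) duplicate the intercepts and are dropped with a message. Any
#' remaining rank deficiency is an error naming the offending columns.
#'
#' @param regressors list of effect \linkS4class{Regressor} objects
#'   (canonical task and residual RT, typically).
#' @param runLengths volumes per run.
#' @param motion volumes x 6 motion matrix spanning all runs, or \code{NULL}.
#' @param driftOrder per-run polynomial drift order (0 = intercept only).
#' @param nuisance optional list of nuisance \linkS4class{Regressor}s (e.g.
#'   the incorrect-trial regressor).
#' @return a \linkS4class{DesignMatrix}.
#' @export
buildDesignMatrix <- function(regressors, runLengths, motion = NULL,
                              driftOrder = 2L, nuisance = list()) {
  runLengths <- as.integer(runLengths)
  nVol <- sum(runLengths)
  for (rg in c(regressors, nuisance)) {
    stopifnot(is(rg, "Regressor"))
    if (length(regressorValues(rg)) != nVol)
      stop("regressor '", regressorLabel(rg), "' length does not match the ",
           "total volume count")
  }
  nR <- length(runLengths)
  cols <- list()
  for (r in seq_len(nR)) {
    ind <- numeric(nVol)
    ind[sum(runLengths[seq_len(r - 1L)]) + seq_len(runLengths[r])] <- 1
    cols[[sprintf("intercept_run%d", r)]] <- ind
    if (driftOrder >= 1L) {
      D <- .legendreDrift(runLengths[r], driftOrder)
      for (k in seq_len(ncol(D))) {
        dcol <- numeric(nVol)
        dcol[ind == 1] <- D[, k]
        cols[[sprintf("drift%d_run%d", k, r)]] <- dcol
      }
    }
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6L)
      stop("motion must have 6 columns (roll, pitch, yaw, x, y, z)")
    if (nrow(motion) != nVol)
      stop("motion rows (", nrow(motion), ") do not match total volumes (",
           nVol, ")")
    mnames <- colnames(motion)
    if (is.null(mnames)) mnames <- c("roll", "pitch", "yaw", "x", "y", "z")
    keep <- apply(motion, 2, function(v) stats::sd(v) > 0)
    if (any(!keep))
      message("dropping constant motion column(s): ",
              paste(mnames[!keep], collapse = ", "))
    for (k in which(keep)) cols[[paste0("motion_", mnames[k])]] <- motion[, k]
  }
  for (rg in nuisance)
    cols[[paste0("nuisance_", regressorLabel(rg))]] <- regressorValues(rg)
  effectNames <- character()
  for (rg in regressors) {
    cols[[regressorLabel(rg)]] <- regressorValues(rg)
    effectNames <- c(effectNames, regressorLabel(rg))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[seq(q$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  new("DesignMatrix", X = X, effectColumns = effectNames,
      runLengths = runLengths, kappa = kappa(X, exact = FALSE))
}

#' Fit the voxel-wise GLM
#'
#' Ordinary least squares of each in-mask voxel's percent-signal-change
#' time-series on the design. Betas for the canonical column are the task
#' effects; betas for the residual RT column are the trial-level RT effects,
#' both in percent-signal-change units per unit regressor. The residual
#' variance map and residual degrees of freedom (volumes minus design rank)
#' are returned alongside.
#'
#' @param data a \linkS4class{VolumeSeries} in percent-signal-change units,
#'   all runs concatenated.
#' @param design a \linkS4class{DesignMatrix}.
#' @param mask logical 3D array; defaults to the series' own mask, else all
#'   voxels.
#' @return a \linkS4class{BetaMaps} holding one 3D map per effect column.
#' @export
fitVoxelwiseGLM <- function(data, design, mask = NULL) {
  stopifnot(is(data, "VolumeSeries"), is(design, "DesignMatrix"))
  d <- dim(data@data)
  X <- designMatrix(design)
  if (nrow(X) != d[4])
    stop("design rows (", nrow(X), ") do not match volumes (", d[4], ")")
  if (is.null(mask)) mask <- data@mask
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(dim(mask), d[1:3])) stop("mask grid mismatch")
  Y <- t(matrix(data@data, prod(d[1:3]), d[4])[as.vector(mask), , drop = FALSE])
  nbad <- sum(!is.finite(Y))
  if (nbad > 0L)
    stop(nbad, " non-finite data value(s) inside the mask")
  q <- qr(X)
  coefs <- qr.coef(q, Y)
  res <- qr.resid(q, Y)
  df <- nrow(X) - q$rank
  sigma2v <- colSums(res^2) / df
  labels <- effectColumns(design)
  betas <- array(0, c(d[1:3], length(labels)),
                 dimnames = list(NULL, NULL, NULL, labels))
  mv <- as.vector(mask)
  for (k in seq_along(labels)) {
    b <- array(NA_real_, d[1:3])
    b[mv] <- coefs[match(labels[k], colnames(X)), ]
    b[!mv] <- 0
    betas[, , , k] <- b
  }
  sigma2 <- array(0, d[1:3])
  sigma2[mv] <- sigma2v
  new("BetaMaps", betas = betas, labels = labels, sigma2 = sigma2,
      df = df, mask = mask)
}

#' Fit one subject end to end
#'
#' Runs the subject-level pipeline: optional Gaussian smoothing of each run,
#' per-run percent-signal-change conversion with a shared mask, regressor
#' construction (canonical task, residualized RT, and — when any trial is
#' incorrect or unanswered — an incorrect-trial nuisance), design assembly
#' with motion and drift nuisances, and the voxel-wise fit. The effect maps
#' are relabelled \code{"task"} and \code{"rt"}.
#'
#' @param runs list of raw \linkS4class{VolumeSeries}, one per run.
#' @param schedule the subject's \linkS4class{TrialSchedule}.
#' @param motion list of volumes x 6 matrices, one per run, or \code{NULL}.
#' @param fwhm smoothing kernel FWHM, mm (0 disables smoothing).
#' @param driftOrder per-run Legendre drift order.
#' @param modelIncorrect include the incorrect-trial nuisance regressor.
#' @param dt,b,c regressor construction parameters.
#' @param centerLogRT mean-center log(RT) before modulation.
#' @return a \linkS4class{BetaMaps} with effects \code{"task"} and
#'   \code{"rt"}.
#' @export
fitSubject <- function(runs, schedule, motion = NULL, fwhm = 8,
                       driftOrder = 2L, modelIncorrect = TRUE, dt = 0.1,
                       b = 8.6, c = 0.547, centerLogRT = FALSE) {
  stopifnot(is(schedule, "TrialSchedule"),
            length(runs) == nRuns(schedule))
  if (fwhm > 0)
    runs <- lapply(runs, gaussianSmooth, fwhm = fwhm)
  # one intensity mask shared across runs, then PSC per run
  masks <- lapply(runs, intensityMask)
  mask <- Reduce(`&`, masks)
  psc <- lapply(runs, percentSignalChange, mask = mask)
  data <- concatRuns(psc)

  xTask <- canonicalRegressor(schedule, dt = dt, b = b, c = c)
  xMod <- rtModulatedRegressor(schedule, dt = dt, b = b, c = c,
                               center = centerLogRT)
  xRt <- orthogonalizeRegressor(xMod, xTask)
  xTask@label <- "task"
  ev <- events(schedule)
  nuisance <- list()
  if (modelIncorrect && any(is.na(ev$correct) | !ev$correct))
    nuisance <- list(suppressWarnings(
      canonicalRegressor(schedule, dt = dt, b = b, c = c,
                         which = "incorrect")))
  motionMat <- if (!is.null(motion)) do.call(rbind, motion) else NULL
  design <- buildDesignMatrix(list(xTask, xRt), nVolumes(schedule),
                              motion = motionMat, driftOrder = driftOrder,
                              nuisance = nuisance)
  fitVoxelwiseGLM(data, design, mask = analysisMask(data))
}
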