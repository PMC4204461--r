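# Spatial smoothing and per-run percent-signal-change normalization.

# half-sample symmetric reflection of index j into 1..n
.reflectIndex <- function(j, n) {
  while (j < 1L || j > n) {
    if (j < 1L) j <- 1L - j
    if (j > n) j <- 2L * n + 1L - j
  }
  j
}

# n x n smoothing matrix for one axis: discrete Gaussian, reflected boundary.
# Rows sum to 1 (kernel mass) and the matrix is symmetric, so column sums are
# 1 too and the spatial mean of each volume is preserved.
.smoothMatrix <- function(n, sigmaVox) {
  if (sigmaVox <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  w <- stats::dnorm(-r:r, sd = sigmaVox)
  w <- w / sum(w)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (m in -r:r) {
      j <- .reflectIndex(i + m, n)
      S[i, j] <- S[i, j] + w[m + r + 1L]
    }
  }
  S
}

# apply per-axis smoothing matrices to one 3D array
.smooth3D <- function(a, S1, S2, S3) {
  d <- dim(a)
  a <- array(S1 %*% matrix(a, d[1]), d)
  a <- aperm(array(S2 %*% matrix(aperm(a, c(2, 1, 3)), d[2]),
                   c(d[2], d[1], d[3])), c(2, 1, 3))
  aperm(array(S3 %*% matrix(aperm(a, c(3, 1, 2)), d[3]),
              c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Gaussian spatial smoothing
#'
#' Convolves each volume independently with a separable Gaussian kernel of
#' the requested full width at half maximum. The per-axis kernel standard
#' deviation is \code{fwhm / (2 sqrt(2 log 2)) / voxelDim}, so anisotropic
#' voxels are handled. Boundaries are reflected (half-sample symmetric),
#' which preserves both constant volumes and each volume's spatial mean.
#'
#' @param x a \linkS4class{VolumeSeries}, or a 3D/4D array (then
#'   \code{voxelDims} is required).
#' @param fwhm full width at half maximum, mm; 0 is the identity.
#' @param voxelDims voxel size, mm per axis (taken from \code{x} when it is
#'   a \linkS4class{VolumeSeries}).
#' @return object of the same kind as \code{x}.
#' @export
gaussianSmooth <- function(x, fwhm, voxelDims = NULL) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (is(x, "VolumeSeries")) {
    out <- x
    out@data <- gaussianSmooth(x@data, fwhm, voxelDims(x))
    return(out)
  }
  d <- dim(x)
  if (is.null(voxelDims) || length(voxelDims) != 3L)
    stop("voxelDims (mm per axis) is required for array input")
  if (fwhm == 0) return(x)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxelDims
  S1 <- .smoothMatrix(d[1], sigma[1])
  S2 <- .smoothMatrix(d[2], sigma[2])
  S3 <- .smoothMatrix(d[3], sigma[3])
  if (length(d) == 3L) return(.smooth3D(x, S1, S2, S3))
  if (length(d) != 4L) stop("x must be a 3D or 4D array")
  out <- x
  for (t in seq_len(d[4]))
    out[, , , t] <- .smooth3D(x[, , , t], S1, S2, S3)
  out
}

#' Default brain mask from signal intensity
#'
#' Voxels whose raw temporal mean exceeds 10% of the grand mean intensity.
#'
#' @param run a \linkS4class{VolumeSeries}.
#' @param fraction mask threshold as a fraction of the grand mean.
#' @return logical 3D array.
#' @export
intensityMask <- function(run, fraction = 0.1) {
  stopifnot(is(run, "VolumeSeries"))
  d <- dim(run@data)
  M <- rowMeans(matrix(run@data, prod(d[1:3]), d[4]))
  array(M > fraction * mean(M), d[1:3])
}

#' Percent signal change normalization
#'
#' Expresses each voxel's time-series relative to its within-run temporal
#' mean: \code{100 * y_t / M_y}. After conversion every in-mask voxel has
#' temporal mean exactly 100, and the output is invariant to positive
#' rescaling of the raw intensities. Voxels whose mean magnitude falls below
#' \code{meanFloor} are removed from the mask (their count is reported via
#' \code{message}) and set to zero.
#'
#' @param run a \linkS4class{VolumeSeries} holding one run.
#' @param mask logical 3D array; defaults to the run's own mask, or to
#'   \code{\link{intensityMask}} when the run has none.
#' @param meanFloor minimum |temporal mean| for a voxel to stay in the mask;
#'   defaults to a machine-precision-scaled floor.
#' @return a \linkS4class{VolumeSeries} in percent-signal-change units with
#'   the (possibly reduced) mask attached.
#' @export
percentSignalChange <- function(run, mask = NULL, meanFloor = NULL) {
  stopifnot(is(run, "VolumeSeries"))
  d <- dim(run@data)
  nVox <- prod(d[1:3])
  Y <- matrix(run@data, nVox, d[4])
  M <- rowMeans(Y)
  if (is.null(mask)) mask <- if (!is.null(run@mask)) run@mask else intensityMask(run)
  if (!identical(dim(mask), d[1:3])) stop("mask grid mismatch")
  if (is.null(meanFloor))
    meanFloor <- sqrt(.Machine$double.eps) * max(abs(M), 1)
  low <- abs(M) <= meanFloor
  dropped <- sum(mask & low)
  if (dropped > 0L)
    message(dropped, " voxel(s) with near-zero mean removed from the mask")
  mask <- mask & !low
  out <- matrix(0, nVox, d[4])
  mv <- as.vector(mask)
  out[mv, ] <- 100 * Y[mv, , drop = FALSE] / M[mv]
  new("VolumeSeries", data = array(out, d), voxelDims = run@voxelDims,
      tr = run@tr, runId = run@runId, mask = mask)
}

#' Concatenate runs along time
#'
#' Stacks per-run \linkS4class{VolumeSeries} (shared grid, voxel size and
#' TR) into one series; the attached mask is the intersection of the runs'
#' masks.
#'
#' @param runs list of \linkS4class{VolumeSeries}.
#' @return a \linkS4class{VolumeSeries} plus attribute-free run lengths via
#'   \code{\link{nVolumes}} of the originating schedule.
#' @export
concatRuns <- function(runs) {
  stopifnot(length(runs) >= 1L, all(vapply(runs, is, TRUE, "VolumeSeries")))
  d0 <- dim(runs[[1]]@data)[1:3]
  for (r in runs) {
    if (!identical(dim(r@data)[1:3], d0)) stop("runs must share a grid")
    if (r@tr != runs[[1]]@tr) stop("runs must share a TR")
  }
  dat <- array(0, c(d0, sum(vapply(runs, function(r) dim(r@data)[4], 0L))))
  off <- 0L
  mask <- NULL
  for (r in runs) {
    nt <- dim(r@data)[4]
    dat[, , , off + seq_len(nt)] <- r@data
    off <- off + nt
    if (!is.null(r@mask)) mask <- if (is.null(mask)) r@mask else mask & r@mask
  }
  new("VolumeSeries", data = dat, voxelDims = runs[[1]]@voxelDims,
      tr = runs[[1]]@tr, runId = "concat", mask = mask)
}
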