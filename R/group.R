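# Group-level inference: one-sample t maps, connected-component labeling,
# Monte-Carlo cluster-extent calibration and cluster reporting.

# coerce a list of 3D arrays or a 4D array to voxels x subjects matrix
.stackSubjects <- function(maps) {
  if (is.list(maps)) {
    d <- dim(maps[[1]])
    for (m in maps) if (!identical(dim(m), d)) stop("subjects must share a grid")
    return(list(mat = vapply(maps, as.numeric, numeric(prod(d))), dim = d))
  }
  d <- dim(maps)
  if (length(d) != 4L) stop("maps must be a list of 3D arrays or a 4D array")
  list(mat = matrix(maps, prod(d[1:3]), d[4]), dim = d[1:3])
}

#' Voxel-wise one-sample t-test across subjects
#'
#' At each in-mask voxel, \code{t = mean / (sd / sqrt(n))} over subjects,
#' with a two-sided p value from the t distribution on n - 1 degrees of
#' freedom. Voxels with zero across-subject variance get \code{t = +/-Inf}
#' (0 when the mean is also zero); their count is reported via
#' \code{message} and their p is clamped to the smallest representable
#' positive value.
#'
#' @param maps subject effect maps: a list of 3D arrays or a 4D array with
#'   subjects on the 4th dimension.
#' @param mask logical 3D array; defaults to all voxels.
#' @return a \linkS4class{GroupStatMap}.
#' @export
oneSampleT <- function(maps, mask = NULL) {
  st <- .stackSubjects(maps)
  n <- ncol(st$mat)
  if (n < 2L) stop("at least 2 subjects are required")
  if (is.null(mask)) mask <- array(TRUE, st$dim)
  if (!identical(dim(mask), st$dim)) stop("mask grid mismatch")
  mv <- as.vector(mask)
  Y <- st$mat[mv, , drop = FALSE]
  m <- rowMeans(Y)
  s <- sqrt(rowSums((Y - m)^2) / (n - 1L))
  tv <- numeric(length(m))
  zerovar <- s == 0
  if (any(zerovar)) {
    message(sum(zerovar), " voxel(s) with zero across-subject variance")
    tv[zerovar] <- sign(m[zerovar]) * Inf
    tv[zerovar & m == 0] <- 0
  }
  tv[!zerovar] <- m[!zerovar] / (s[!zerovar] / sqrt(n))
  pv <- 2 * stats::pt(-abs(tv), df = n - 1L)
  pv <- pmax(pv, .Machine$double.xmin)
  tMap <- array(0, st$dim); tMap[mv] <- tv
  pMap <- array(1, st$dim); pMap[mv] <- pv
  new("GroupStatMap", tMap = tMap, pMap = pMap, df = n - 1L,
      nSubjects = as.integer(n), mask = mask)
}

# neighbourhood offsets for the three connectivity rules; half set only
.halfOffsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  maxOrd <- switch(connectivity, faces = 1L, edges = 2L, corners = 3L,
                   stop("connectivity must be faces, edges or corners"))
  g <- g[ord >= 1L & ord <= maxOrd, , drop = FALSE]
  # keep one of each +/- pair (lexicographically positive)
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g[keep, , drop = FALSE]
}

#' Label connected clusters in a binary map
#'
#' Connected-component labeling of a 3D binary array under the requested
#' neighbourhood: \code{"faces"} (6 neighbours), \code{"edges"} (18), or
#' \code{"corners"} (26; voxels connected by surfaces, edges or corners).
#'
#' @param bin logical (or 0/1) 3D array.
#' @param connectivity neighbourhood rule; default \code{"corners"}.
#' @return list with \code{labels} (integer 3D array, 0 = background),
#'   \code{sizes} (integer vector of cluster voxel counts),
#'   \code{nClusters}, and \code{indices} (list of linear voxel indices per
#'   cluster).
#' @export
labelClusters <- function(bin, connectivity = c("corners", "edges", "faces")) {
  connectivity <- match.arg(connectivity)
  d <- dim(bin)
  if (length(d) != 3L) stop("bin must be a 3D array")
  bin <- bin != 0
  idx <- which(bin)
  labels <- array(0L, d)
  if (length(idx) == 0L)
    return(list(labels = labels, sizes = integer(0), nClusters = 0L,
                indices = list()))
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  coords <- arrayInd(idx, d)
  offs <- .halfOffsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[o, ], nrow(coords), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
      nb[, 3] >= 1L & nb[, 3] <= d[3]
    if (!any(ok)) next
    nbLin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    nbPos <- pos[nbLin]
    hit <- nbPos > 0L
    from <- c(from, pos[idx[ok][hit]])
    to <- c(to, nbPos[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  labels[idx] <- as.integer(memb)
  sizes <- as.integer(tabulate(memb))
  list(labels = labels, sizes = sizes, nClusters = length(sizes),
       indices = split(idx, memb))
}

#' Construct a Monte-Carlo cluster-threshold specification
#'
#' @param mask logical 3D analysis mask.
#' @param voxelDims voxel size, mm per axis.
#' @param fwhm applied Gaussian smoothness of the data, mm (0 = unsmoothed).
#' @param voxelP voxel-wise two-sided p threshold.
#' @param alphaFwe familywise type-1 error target.
#' @param connectivity neighbourhood rule.
#' @param nIterations Monte-Carlo iterations.
#' @param seed integer seed.
#' @return a \linkS4class{ClusterThresholdSpec}.
#' @export
clusterThresholdSpec <- function(mask, voxelDims = c(4, 4, 4), fwhm = 8,
                                 voxelP = 0.005, alphaFwe = 0.05,
                                 connectivity = "corners",
                                 nIterations = 2000L, seed = 1L) {
  new("ClusterThresholdSpec", mask = mask, voxelDims = voxelDims,
      fwhm = fwhm, voxelP = voxelP, alphaFwe = alphaFwe,
      connectivity = connectivity, nIterations = as.integer(nIterations),
      seed = as.integer(seed))
}

#' Monte-Carlo cluster-extent threshold
#'
#' Calibrates the cluster-extent threshold controlling familywise error:
#' each iteration fills the mask's bounding grid with unit Gaussian noise,
#' smooths it to the stated FWHM, re-standardizes within the mask,
#' thresholds two-sided at \code{voxelP}, labels positive and negative
#' excursions separately, and records the largest cluster. The returned
#' extent is the smallest k such that the fraction of iterations whose
#' maximum cluster reaches k is at most \code{alphaFwe}; clusters of at
#' least k voxels are then familywise significant.
#'
#' @param spec a \linkS4class{ClusterThresholdSpec}.
#' @return list with \code{threshold} (voxels), \code{maxClusterSizes}
#'   (the empirical null distribution of the per-iteration maximum), and
#'   \code{alphaAchieved} (the attained tail fraction at the threshold).
#' @export
monteCarloClusterThreshold <- function(spec) {
  stopifnot(is(spec, "ClusterThresholdSpec"))
  if (spec@alphaFwe < 1 / spec@nIterations)
    stop("alphaFwe below 1/nIterations: the tail cannot be resolved; ",
         "increase nIterations")
  set.seed(spec@seed)
  d <- dim(spec@mask)
  mv <- as.vector(spec@mask)
  zcrit <- stats::qnorm(1 - spec@voxelP / 2)
  smooth <- spec@fwhm > 0
  if (smooth) {
    sigma <- spec@fwhm / (2 * sqrt(2 * log(2))) / spec@voxelDims
    S1 <- .smoothMatrix(d[1], sigma[1])
    S2 <- .smoothMatrix(d[2], sigma[2])
    S3 <- .smoothMatrix(d[3], sigma[3])
  }
  maxSizes <- integer(spec@nIterations)
  for (it in seq_len(spec@nIterations)) {
    noise <- array(stats::rnorm(prod(d)), d)
    if (smooth) noise <- .smooth3D(noise, S1, S2, S3)
    v <- noise[mv]
    v <- (v - mean(v)) / stats::sd(v)
    z <- array(0, d)
    z[mv] <- v
    mx <- 0L
    for (sgn in c(1, -1)) {
      ex <- array(FALSE, d)
      ex[mv] <- sgn * z[mv] >= zcrit
      if (any(ex)) {
        lab <- labelClusters(ex, spec@connectivity)
        mx <- max(mx, lab$sizes)
      }
    }
    maxSizes[it] <- mx
  }
  kmax <- max(maxSizes)
  threshold <- kmax + 1L          # fallback: larger than anything observed
  for (k in seq_len(kmax)) {
    if (mean(maxSizes >= k) <= spec@alphaFwe) {
      threshold <- k
      break
    }
  }
  list(threshold = threshold, maxClusterSizes = maxSizes,
       alphaAchieved = mean(maxSizes >= threshold))
}

#' Cluster table from a thresholded group map
#'
#' Thresholds the group t map voxel-wise (two-sided at \code{voxelP}), forms
#' clusters separately within positive and negative excursions, discards
#' clusters below the extent threshold, and reports one row per surviving
#' cluster: sign, peak coordinate (mm in the grid's own space, voxel
#' \code{(1,1,1)} at the origin), voxel count, peak t, and the
#' across-subject mean (and SD) of the within-cluster mean effect.
#'
#' @param stat a \linkS4class{GroupStatMap}.
#' @param subjectMaps the subject effect maps the t map was computed from
#'   (list of 3D arrays or 4D array).
#' @param extentThreshold minimum cluster size, voxels (e.g. from
#'   \code{\link{monteCarloClusterThreshold}}).
#' @param voxelP voxel-wise two-sided p threshold.
#' @param connectivity neighbourhood rule.
#' @param voxelDims voxel size, mm per axis, for peak coordinates.
#' @return \code{data.frame} with columns \code{sign}, \code{peak_x},
#'   \code{peak_y}, \code{peak_z} (mm), \code{n_voxels}, \code{peak_t},
#'   \code{mean_effect}, \code{sd_effect}; zero rows when nothing survives.
#' @export
clusterReport <- function(stat, subjectMaps, extentThreshold, voxelP = 0.005,
                          connectivity = "corners", voxelDims = c(4, 4, 4)) {
  stopifnot(is(stat, "GroupStatMap"))
  st <- .stackSubjects(subjectMaps)
  if (!identical(st$dim, dim(stat@tMap))) stop("subject map grid mismatch")
  tcrit <- stats::qt(1 - voxelP / 2, df = stat@df)
  rows <- list()
  for (sgn in c(1, -1)) {
    ex <- stat@mask & (sgn * stat@tMap >= tcrit)
    if (!any(ex)) next
    lab <- labelClusters(ex, connectivity)
    for (ci in seq_len(lab$nClusters)) {
      vox <- lab$indices[[ci]]
      if (length(vox) < extentThreshold) next
      tv <- stat@tMap[vox]
      peak <- vox[which.max(sgn * tv)]
      pc <- (arrayInd(peak, st$dim) - 1L) * voxelDims
      subjMeans <- colMeans(st$mat[vox, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        sign = if (sgn > 0) "positive" else "negative",
        peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
        n_voxels = length(vox), peak_t = stat@tMap[peak],
        mean_effect = mean(subjMeans), sd_effect = stats::sd(subjMeans))
    }
  }
  if (!length(rows))
    return(data.frame(sign = character(), peak_x = numeric(),
                      peak_y = numeric(), peak_z = numeric(),
                      n_voxels = integer(), peak_t = numeric(),
                      mean_effect = numeric(), sd_effect = numeric()))
  out <- do.call(rbind, rows)
  out[order(-out$n_voxels), , drop = FALSE]
}

#' Write a cluster table as tab-separated text
#'
#' @param table a cluster \code{data.frame} from \code{\link{clusterReport}}.
#' @param path output file.
#' @export
writeClusterTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
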