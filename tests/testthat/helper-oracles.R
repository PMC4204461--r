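# Independent oracles and small fixtures, kept deliberately naive so they
# share no code path with the implementation they check.

# Brute-force regressor: directly evaluate the HRF superposition at the
# volume acquisition times, one trial at a time, no fine grid or convolution.
bruteForceRegressor <- function(onsets, weights, nVol, tr,
                                b = 8.6, cc = 0.547) {
  tv <- (seq_len(nVol) - 1) * tr
  out <- numeric(nVol)
  peak <- (b * cc)^b * exp(-b)
  for (k in seq_along(onsets)) {
    dtk <- tv - onsets[k]
    h <- ifelse(dtk > 0, dtk^b * exp(-dtk / cc) / peak, 0)
    out <- out + weights[k] * h
  }
  out
}

# Brute-force OLS via explicit normal equations
normalEquationBetas <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# Recursive-free flood fill over all neighbours allowed by the connectivity
floodFillLabels <- function(bin, connectivity = "corners") {
  d <- dim(bin)
  maxOrd <- switch(connectivity, faces = 1L, edges = 2L, corners = 3L)
  labels <- array(0L, d)
  nextLab <- 0L
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!bin[x, y, z] || labels[x, y, z] > 0L) next
    nextLab <- nextLab + 1L
    stack <- list(c(x, y, z))
    labels[x, y, z] <- nextLab
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        ord <- abs(dx) + abs(dy) + abs(dz)
        if (ord < 1L || ord > maxOrd) next
        n <- v + c(dx, dy, dz)
        if (any(n < 1L) || any(n > d)) next
        if (bin[n[1], n[2], n[3]] && labels[n[1], n[2], n[3]] == 0L) {
          labels[n[1], n[2], n[3]] <- nextLab
          stack[[length(stack) + 1L]] <- n
        }
      }
    }
  }
  labels
}

# Two labelings agree iff they induce the same partition of the active voxels
samePartition <- function(lab1, lab2) {
  act1 <- which(lab1 > 0L)
  act2 <- which(lab2 > 0L)
  if (!identical(act1, act2)) return(FALSE)
  key <- paste(lab1[act1], lab2[act2])
  length(unique(lab1[act1])) == length(unique(key)) &&
    length(unique(lab2[act2])) == length(unique(key))
}

# A naive, self-contained simulator of the max-cluster-size null distribution
# for unsmoothed noise (cross-check for the Monte-Carlo threshold).
naiveMaxClusterThreshold <- function(maskDim, voxelP, alpha, nIter,
                                     connectivity = "corners") {
  zc <- qnorm(1 - voxelP / 2)
  mx <- integer(nIter)
  for (i in seq_len(nIter)) {
    z <- array(rnorm(prod(maskDim)), maskDim)
    z <- (z - mean(z)) / sd(z)
    best <- 0L
    for (sgn in c(1, -1)) {
      lab <- floodFillLabels(sgn * z >= zc, connectivity)
      if (max(lab) > 0L) best <- max(best, max(tabulate(lab[lab > 0L])))
    }
    mx[i] <- best
  }
  k <- max(mx) + 1L
  for (kk in seq_len(max(mx))) if (mean(mx >= kk) <= alpha) { k <- kk; break }
  k
}

# Small schedule with fully specified trials, for regressor unit tests
makeSchedule <- function(onsets, rts, correct = NULL, tr = 2, nVol = 40,
                         duration = 3.5, runs = NULL) {
  n <- length(onsets)
  if (is.null(correct)) correct <- rep(TRUE, n)
  if (is.null(runs)) runs <- rep(1L, n)
  new("TrialSchedule",
      events = data.frame(run = runs, onset = onsets, duration = duration,
                          response_time = rts, correct = correct,
                          probe_present = rep(c(TRUE, FALSE), length.out = n)),
      rests = data.frame(run = integer(), onset = numeric(),
                         duration = numeric()),
      tr = tr, nVolumes = rep(as.integer(nVol), max(runs)))
}

# Desk-scale protocol used by several suites
tinyProtocol <- function(grid = c(8L, 8L, 8L)) {
  ProtocolSpec(nRuns = 2L, trialsPerRun = 8L, trialDuration = 3.5,
               restDurations = c(0.5, 4.5, 8.5), restsPerRun = 4L,
               tr = 2, volumesPerRun = 40L, gridShape = grid,
               voxelDims = c(4, 4, 4))
}
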