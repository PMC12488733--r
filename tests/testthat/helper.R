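# Shared fixtures and independent oracles for the suite.

# A small wavelength grid keeps cube fixtures light while spanning the
# visible/NIR landmarks the segmentation defaults use.
smallGrid <- function(n = 80) wavelengthGrid(n)

# Independent flood-fill component counter (recursive-free BFS, 8-neighbour),
# used as the oracle for connected-component selection.
floodFillAreas <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  areas <- integer(0)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    queue <- matrix(c(r0, c0), 1L)
    seen[r0, c0] <- TRUE
    area <- 0L
    while (nrow(queue) > 0L) {
      r <- queue[1, 1]; cc <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      area <- area + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
            mask[rr, c2] && !seen[rr, c2]) {
          seen[rr, c2] <- TRUE
          queue <- rbind(queue, c(rr, c2))
        }
      }
    }
    areas <- c(areas, area)
  }
  areas
}

# Shoelace polygon area for contour checks.
shoelace <- function(pts) {
  n <- nrow(pts)
  x <- pts[, 2]; y <- pts[, 1]
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

# Brute-force PRESS search over all subsets of sizes kMin..kMax (oracle for
# the SPA winner on tiny instances).
bruteForcePress <- function(Xcal, ycal, Xval, yval, kMin, kMax) {
  p <- ncol(Xcal)
  best <- list(press = Inf, vars = integer(0))
  for (k in kMin:kMax) {
    for (vars in asplit(utils::combn(p, k), 2L)) {
      A <- cbind(1, Xcal[, vars, drop = FALSE])
      fit <- lm.fit(A, ycal)
      if (fit$rank < ncol(A)) next
      pred <- cbind(1, Xval[, vars, drop = FALSE]) %*% fit$coefficients
      pr <- sum((yval - pred)^2)
      if (pr < best$press) best <- list(press = pr, vars = as.integer(vars))
    }
  }
  best
}

# Planted soluble-protein band indices on a grid.
plantedSpIndices <- function(wl) {
  vapply(c(403, 430, 551, 617, 846),
         function(p) which.min(abs(wl - p)), integer(1))
}
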