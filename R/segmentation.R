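# Fruit ROI extraction: spectral-contrast enhancement -> Otsu binarization ->
# largest 8-connected component -> hole filling -> boundary trace -> periodic
# B-spline fit -> rasterized smooth mask -> mean ROI spectrum.

#' Spectral-contrast score image
#'
#' Enhances the fruit/background boundary as a two-band difference image:
#' reflectance at the band nearest `hiNm` minus reflectance at the band
#' nearest `loNm`, per pixel. Fruit tissue is bright in the NIR and dark in
#' the blue, so the default 800 - 450 nm contrast is large on fruit and near
#' zero on typical dark backgrounds.
#'
#' @param cube a reflectance [HyperCube-class].
#' @param hiNm,loNm wavelengths (nm) of the high- and low-reflectance bands.
#' @return rows x cols numeric score matrix.
#' @export
enhanceCube <- function(cube, hiNm = 800, loNm = 450) {
  hi <- nearestBand(cube@grid, hiNm)
  lo <- nearestBand(cube@grid, loNm)
  cube@data[, , hi] - cube@data[, , lo]
}

# 8-connected component labeling by iterative label propagation. Each
# foreground pixel starts with a unique label; every sweep replaces a label by
# the maximum over its 8-neighbourhood (foreground only) until a fixed point.
labelComponents <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    nb <- lab
    for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                   c(0, 1), c(1, -1), c(1, 0), c(1, 1)))
      nb <- pmax(nb, shift(lab, d[1], d[2]))
    nb[!mask] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  # compact labels to 1..k
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

#' Binarize a score image and keep the largest component
#'
#' Applies Otsu's threshold to the score image, labels the foreground with
#' 8-connectivity, keeps the maximum-area component and fills its interior
#' holes, so the returned ROI is simply connected.
#'
#' @param score rows x cols numeric matrix (from [enhanceCube()]).
#' @param minArea minimum acceptable foreground area in pixels.
#' @return A [RoiMask-class].
#' @export
binarizeLargest <- function(score, minArea = 9L) {
  if (!all(is.finite(score))) stop("score image must be finite")
  rng <- range(score)
  if (diff(rng) == 0) stop("constant score image: no threshold exists")
  sc01 <- (score - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(sc01))
  fg <- sc01 > th
  if (!any(fg)) stop("empty foreground after thresholding")
  lab <- labelComponents(fg)
  areas <- tabulate(lab[lab > 0L])
  keep <- which.max(areas)
  mask <- lab == keep
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0
  mask <- matrix(as.logical(mask), nrow(score), ncol(score))
  if (sum(mask) < minArea)
    stop(sprintf("largest component (%d px) below minimum area %d",
                 sum(mask), minArea))
  roiMask(mask)
}

# Trace the outer boundary of the mask as an ordered closed polyline of
# (row, col) coordinates (EBImage's contour tracer, converted to 1-based).
traceBoundary <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image((mask * 1)))
  if (length(oc) < 1L) stop("no boundary found")
  pts <- oc[[which.max(vapply(oc, nrow, 0L))]] + 1
  rbind(pts, pts[1, , drop = FALSE])   # close
}

# Displace an open ring of contour samples along its outward normal.
displaceOutward <- function(q, offset) {
  n <- nrow(q)
  tang <- q[c(2:n, 1L), ] - q[c(n, 1:(n - 1L)), ]
  nrm <- cbind(tang[, 2], -tang[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  ctr <- colMeans(q)
  flip <- rowSums(nrm * sweep(q, 2L, ctr)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  q + offset * nrm
}

# Periodic B-spline basis of given degree with nCtrl control points,
# evaluated at parameters t in [0, 1). Built from an open uniform design via
# splines::splineDesign, folding the wrapped trailing columns onto the head.
periodicBsplineBasis <- function(t, nCtrl, degree) {
  ord <- degree + 1L
  knots <- seq(-degree, nCtrl + degree) / nCtrl
  B <- splines::splineDesign(knots, t, ord = ord, outer.ok = TRUE)
  P <- B[, seq_len(nCtrl), drop = FALSE]
  if (degree > 0)
    P[, seq_len(degree)] <- P[, seq_len(degree)] +
      B[, nCtrl + seq_len(degree), drop = FALSE]
  P
}

#' Fit a smooth periodic B-spline to a mask boundary
#'
#' Traces the mask's outer boundary, parameterizes it by normalized chord
#' length, and least-squares fits a closed (periodic) B-spline with
#' `nControl` control points. The smoothed contour is sampled at the
#' boundary's own resolution.
#'
#' Because traced boundary points are pixel centers — half a pixel inside
#' the true region edge — the fitted samples are displaced outward along the
#' curve normal by `offset` pixels, so the returned contour approximates the
#' region edge itself.
#'
#' @param mask a [RoiMask-class].
#' @param nControl number of control points (default 40).
#' @param degree spline degree (default 3, cubic).
#' @param offset outward boundary-center correction in pixels (default 0.5).
#' @return A [SpectralContour-class].
#' @export
fitContour <- function(mask, nControl = 40L, degree = 3L, offset = 0.5) {
  bd <- traceBoundary(mask@mask)
  m <- nrow(bd) - 1L                 # unique boundary points
  if (m <= degree + 1L)
    stop(sprintf("degenerate boundary: %d points for degree %d", m, degree))
  if (m < nControl)
    stop(sprintf("boundary length %d below nControl = %d", m, nControl))
  pts <- bd[seq_len(m), , drop = FALSE]
  seg <- sqrt(rowSums((pts - pts[c(2:m, 1), ])^2))
  t <- c(0, cumsum(seg))[seq_len(m)] / sum(seg)
  B <- periodicBsplineBasis(t, nControl, degree)
  ctrl <- qr.solve(qr(B, LAPACK = TRUE), pts)
  fitted <- B %*% ctrl
  if (offset != 0) fitted <- displaceOutward(fitted, offset)
  new("SpectralContour",
      points = rbind(fitted, fitted[1, , drop = FALSE]),
      boundary = bd, control = ctrl, degree = as.integer(degree))
}

#' Rasterize a closed contour to a mask
#'
#' Even-odd (scanline parity) polygon fill of the smoothed contour on a pixel
#' grid: a pixel center belongs to the ROI when a horizontal ray crosses the
#' polygon an odd number of times.
#'
#' @param contour a [SpectralContour-class] (already carrying the
#'   boundary-center correction from [fitContour()]).
#' @param dims image dimensions `c(rows, cols)`.
#' @param offset additional outward normal displacement in pixels
#'   (default 0).
#' @return A [RoiMask-class].
#' @export
contourToMask <- function(contour, dims, offset = 0) {
  p <- contour@points
  n <- nrow(p) - 1L
  if (offset != 0 && n > 2L) {
    q <- displaceOutward(p[seq_len(n), , drop = FALSE], offset)
    p <- rbind(q, q[1L, , drop = FALSE])
  }
  mask <- matrix(FALSE, dims[1], dims[2])
  xs <- vector("list", dims[1])
  for (k in seq_len(n)) {
    r1 <- p[k, 1]; c1 <- p[k, 2]; r2 <- p[k + 1, 1]; c2 <- p[k + 1, 2]
    if (r1 == r2) next
    lo <- ceiling(min(r1, r2)); hi <- ceiling(max(r1, r2)) - 1L
    if (hi < lo) next
    rows <- lo:hi
    rows <- rows[rows >= 1 & rows <= dims[1]]
    if (!length(rows)) next
    xint <- c1 + (rows - r1) * (c2 - c1) / (r2 - r1)
    for (i in seq_along(rows))
      xs[[rows[i]]] <- c(xs[[rows[i]]], xint[i])
  }
  for (r in seq_len(dims[1])) {
    x <- sort(xs[[r]])
    if (length(x) < 2L) next
    for (k in seq(1L, length(x) - 1L, by = 2L)) {
      c1 <- ceiling(x[k]); c2 <- floor(x[k + 1])
      if (c2 >= c1)
        mask[r, max(1L, c1):min(dims[2], c2)] <- TRUE
    }
  }
  if (!any(mask)) stop("contour rasterized to an empty mask")
  roiMask(mask)
}

#' Mean ROI spectrum
#'
#' Arithmetic mean reflectance over the masked pixels, per band — the
#' per-fruit "original spectrum" feeding the modeling pipeline.
#'
#' @param cube a [HyperCube-class].
#' @param roi a [RoiMask-class] with the cube's spatial shape.
#' @return numeric vector of length `nbands`.
#' @export
meanSpectrum <- function(cube, roi) {
  d <- dim(cube@data)
  if (!all(dim(roi@mask) == d[1:2]))
    stop("mask shape does not match cube")
  if (roi@area == 0L) stop("empty mask")
  m <- matrix(cube@data, d[1] * d[2], d[3])
  colMeans(m[as.vector(roi@mask), , drop = FALSE])
}

#' Segment a cube and extract its mean spectrum
#'
#' The full chain: enhancement, Otsu binarization, largest-component
#' selection with hole filling, boundary tracing, periodic B-spline
#' smoothing, rasterization, and ROI averaging.
#'
#' @inheritParams enhanceCube
#' @inheritParams fitContour
#' @param minArea minimum foreground area for [binarizeLargest()].
#' @return list with elements `mask` ([RoiMask-class], the smoothed-contour
#'   mask), `rawMask` (pre-smoothing component), `contour`
#'   ([SpectralContour-class]) and `spectrum` (per-band mean reflectance).
#' @examples
#' g <- wavelengthGrid(60)
#' syn <- generateCube(48, 48, g, opticalModel(g), seed = 7)
#' seg <- segmentCube(syn$cube)
#' length(seg$spectrum)
#' @export
segmentCube <- function(cube, hiNm = 800, loNm = 450, nControl = 40L,
                        degree = 3L, minArea = 9L) {
  score <- enhanceCube(cube, hiNm, loNm)
  raw <- binarizeLargest(score, minArea = minArea)
  contour <- fitContour(raw, nControl = nControl, degree = degree)
  mask <- contourToMask(contour, dim(score))
  list(mask = mask, rawMask = raw, contour = contour,
       spectrum = meanSpectrum(cube, mask))
}

#' Intersection-over-union of two masks
#'
#' @param a,b [RoiMask-class] objects or logical matrices of equal shape.
#' @return IoU in `[0, 1]`.
#' @export
maskIoU <- function(a, b) {
  if (is(a, "RoiMask")) a <- a@mask
  if (is(b, "RoiMask")) b <- b@mask
  sum(a & b) / sum(a | b)
}

#' Export a mask as run-length-encoded JSON or PNG-style text
#'
#' @param roi a [RoiMask-class].
#' @param path output file; `.json` gives column-major run-length encoding.
#' @return `path`, invisibly.
#' @export
writeMask <- function(roi, path) {
  r <- rle(as.vector(roi@mask))
  jsonlite::write_json(
    list(dims = dim(roi@mask), lengths = r$lengths, values = r$values),
    path, auto_unbox = FALSE)
  invisible(path)
}
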