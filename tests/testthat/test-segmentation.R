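# ROI extraction chain: enhancement, binarization, component selection,
# B-spline contour smoothing, rasterization, mean spectra.

# cube with constant spectra: fruit block bright in NIR, background flat
blockCube <- function(grid = smallGrid(), fruit = NULL) {
  wl <- wavelengths(grid)
  nb <- length(wl)
  fruitSpec <- 0.1 + 0.6 / (1 + exp(-(wl - 640) / 30))
  bgSpec <- rep(0.1, nb)
  cube <- array(rep(bgSpec, each = 20 * 20), c(20, 20, nb))
  if (is.null(fruit)) { fruit <- matrix(FALSE, 20, 20); fruit[6:15, 6:15] <- TRUE }
  for (b in seq_len(nb)) {
    plane <- cube[, , b]
    plane[fruit] <- fruitSpec[b]
    cube[, , b] <- plane
  }
  list(cube = hyperCube(cube, grid, kind = "reflectance"), fruit = fruit)
}

test_that("enhancement is the two-band reflectance difference", {
  bc <- blockCube()
  sc <- enhanceCube(bc$cube, 800, 450)
  wl <- wavelengths(bc$cube)
  hi <- which.min(abs(wl - 800)); lo <- which.min(abs(wl - 450))
  expTrue <- cubeData(bc$cube)[1, 1, hi] - cubeData(bc$cube)[1, 1, lo]
  # by construction: fruit pixels carry the sigmoid contrast, background zero
  expect_equal(sc[6, 6], (0.1 + 0.6 / (1 + exp(-(wl[hi] - 640) / 30))) -
                          (0.1 + 0.6 / (1 + exp(-(wl[lo] - 640) / 30))))
  expect_equal(sc[1, 1], 0)
  # hi == lo wavelength -> identically zero image
  expect_equal(enhanceCube(bc$cube, 700, 700), matrix(0, 20, 20))
  expect_error(enhanceCube(bc$cube, 2000, 450), "outside grid")
})

test_that("binarization keeps the largest 8-connected component and fills holes", {
  score <- matrix(0, 30, 30)
  score[3:12, 3:7] <- 1        # 50-pixel blob
  score[20:23, 20:24] <- 1     # 20-pixel blob
  roi <- binarizeLargest(score)
  areas <- floodFillAreas(score > 0.5)
  expect_setequal(areas, c(50, 20))
  expect_equal(roi@area, max(areas))
  expect_true(all(maskMatrix(roi)[3:12, 3:7]))
  expect_false(any(maskMatrix(roi)[20:23, 20:24]))

  # interior hole is filled: area incremented by exactly the hole size
  score2 <- matrix(0, 15, 15)
  score2[4:10, 4:10] <- 1
  score2[7, 7] <- 0
  roi2 <- binarizeLargest(score2)
  expect_equal(roi2@area, 49L)
  expect_true(maskMatrix(roi2)[7, 7])

  expect_error(binarizeLargest(matrix(1, 5, 5)), "constant")
})

test_that("component labeling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[cbind(1:4, 1:4)] <- TRUE          # diagonal chain
  lab <- fruithsi:::labelComponents(m)
  expect_equal(max(lab), 1L)          # one component under 8-connectivity
  expect_length(floodFillAreas(m), 1L)
  # two blobs separated by a full gap agree with EBImage labeling
  m2 <- matrix(FALSE, 8, 8)
  m2[1:2, 1:2] <- TRUE; m2[6:8, 6:8] <- TRUE
  expect_equal(max(fruithsi:::labelComponents(m2)),
               max(EBImage::bwlabel(m2 * 1)))
})

test_that("B-spline contour fit recovers a disk to sub-pixel accuracy", {
  nr <- 60
  rr <- matrix(seq_len(nr), nr, nr)
  cc <- t(rr)
  mask <- (rr - 30.5)^2 + (cc - 30.5)^2 <= 20^2
  ct <- fitContour(roiMask <- binarizeLargest(mask + 0), nControl = 30)
  pts <- ct@points
  radii <- sqrt((pts[, 1] - 30.5)^2 + (pts[, 2] - 30.5)^2)
  expect_lt(sqrt(mean((radii - 20)^2)), 0.5)
  # periodicity: first sample equals last
  expect_equal(pts[1, ], pts[nrow(pts), ])
})

test_that("contour fit preserves area and does not inflate the perimeter", {
  mask <- matrix(FALSE, 50, 50)
  mask[11:40, 11:40] <- TRUE
  ct <- fitContour(roiMask(mask), nControl = 40)
  # enclosed area within 2% of the mask area (shoelace on the sampled curve)
  expect_lt(abs(shoelace(ct@points) - sum(mask)) / sum(mask), 0.02)
  # smoothing itself contracts wiggles: compare perimeters with the
  # boundary-center offset disabled so both curves share one convention
  ct0 <- fitContour(roiMask(mask), nControl = 40, offset = 0)
  perim <- function(p) sum(sqrt(rowSums((p[-1, ] - p[-nrow(p), ])^2)))
  expect_lt(perim(ct0@points), 1.01 * perim(ct0@boundary))
  expect_error(fitContour(roiMask(mask), nControl = 4000), "nControl")
})

test_that("rasterized contour mask matches the source square", {
  mask <- matrix(FALSE, 40, 40)
  mask[11:30, 11:30] <- TRUE
  ct <- fitContour(roiMask(mask), nControl = 40)
  back <- contourToMask(ct, c(40, 40))
  expect_gt(maskIoU(back, roiMask(mask)), 0.95)
})

test_that("mean spectrum equals the naive masked average", {
  bc <- blockCube()
  roi <- roiMask(bc$fruit)
  # all masked pixels share one spectrum -> the mean is that spectrum
  sp <- meanSpectrum(bc$cube, roi)
  expect_equal(sp, cubeData(bc$cube)[6, 6, ])
  # two masked pixels at 0.2 / 0.6 -> 0.4
  cube2 <- hyperCube(array(c(0.2, 0.6), c(2, 1, 1)), 500,
                     kind = "reflectance")
  m2 <- roiMask(matrix(TRUE, 2, 1))
  expect_equal(meanSpectrum(cube2, m2), 0.4)
  # random 5-pixel mask against an explicit loop
  withr::with_seed(11, {
    cube3 <- hyperCube(array(runif(6 * 6 * 4), c(6, 6, 4)),
                       c(500, 600, 700, 800), kind = "reflectance")
    sel <- matrix(FALSE, 6, 6)
    sel[sample(36, 5)] <- TRUE
  })
  loopMean <- numeric(4)
  for (b in 1:4) {
    tot <- 0
    for (r in 1:6) for (cc in 1:6) if (sel[r, cc])
      tot <- tot + cubeData(cube3)[r, cc, b]
    loopMean[b] <- tot / 5
  }
  expect_equal(meanSpectrum(cube3, roiMask(sel)), loopMean)
  expect_error(meanSpectrum(bc$cube, roiMask(matrix(TRUE, 3, 3))), "shape")
})

test_that("mean spectrum is invariant to pixel order", {
  withr::with_seed(3, {
    a <- array(runif(5 * 5 * 3), c(5, 5, 3))
    perm <- sample(25)
  })
  grid <- c(500, 600, 700)
  m <- matrix(FALSE, 5, 5); m[c(2, 9, 14, 21)] <- TRUE
  ap <- array(apply(a, 3, function(pl) pl[matrix(perm, 5)]), c(5, 5, 3))
  mp <- matrix(m[matrix(perm, 5)], 5)
  expect_equal(
    meanSpectrum(hyperCube(a, grid, kind = "reflectance"), roiMask(m)),
    meanSpectrum(hyperCube(ap, grid, kind = "reflectance"), roiMask(mp)))
})
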