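# ENVI input/output and white-reference correction.

fixtureCube <- function(seed = 1, dims = c(4, 4, 5)) {
  withr::with_seed(seed, {
    # values representable exactly in 32-bit floats so write/read round-trips
    # bit-exactly
    v <- sample(0:4096, prod(dims), replace = TRUE) / 256
    hyperCube(array(v, dims), seq(500, 900, length.out = dims[3]))
  })
}

test_that("default wavelength grid spans 395-1008 nm with 360 bands", {
  g <- wavelengthGrid()
  wl <- wavelengths(g)
  expect_length(wl, 360)
  expect_equal(wl[1], 395)
  expect_equal(wl[360], 1008)
  expect_true(all(diff(wl) > 0))
  expect_error(wavelengthGrid(values = c(500, 500, 600)), "increasing")
})

test_that("write/read round-trips bit-exactly for all three interleaves", {
  cube <- fixtureCube()
  for (il in c("bsq", "bil", "bip")) {
    path <- file.path(withr::local_tempdir(), paste0("cube_", il))
    writeENVI(cube, path, interleave = il)
    back <- readENVI(paste0(path, ".hdr"))
    expect_identical(cubeData(back), cubeData(cube), label = il)
    expect_equal(wavelengths(back), wavelengths(cube))
  }
})

test_that("interleave decoding matches a manual de-interleave of a 2x2x3 cube", {
  # BIL layout written by hand: for each row (line), bands x samples
  vals <- array(1:12, c(2, 2, 3))        # rows x cols x bands
  dir <- withr::local_tempdir()
  bin <- file.path(dir, "manual")
  con <- file(bin, "wb")
  for (r in 1:2) for (b in 1:3) for (cc in 1:2)
    writeBin(as.numeric(vals[r, cc, b]), con, size = 4, endian = "little")
  close(con)
  writeLines(c("ENVI", "samples = 2", "lines = 2", "bands = 3",
               "header offset = 0", "data type = 4", "interleave = bil",
               "byte order = 0", "wavelength = { 500, 600, 700 }"),
             paste0(bin, ".hdr"))
  back <- readENVI(paste0(bin, ".hdr"))
  expect_equal(cubeData(back), vals + 0)
})

test_that("header errors are informative", {
  cube <- fixtureCube()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cube")
  writeENVI(cube, path)
  # drop the wavelength line
  hdr <- readLines(paste0(path, ".hdr"))
  writeLines(hdr[!grepl("^wavelength", hdr)], paste0(path, ".hdr"))
  expect_error(readENVI(paste0(path, ".hdr")), "wavelength")
  # header advertising more bands than the binary holds
  writeLines(sub("bands = 5", "bands = 6",
                 sub("wavelength = \\{", "wavelength = { 999,", hdr)),
             paste0(path, ".hdr"))
  expect_error(readENVI(paste0(path, ".hdr")), "bytes")
})

test_that("white correction follows (raw - dark) / (white - dark)", {
  grid <- c(500, 600, 700)
  # raw pixel equal to the white spectrum -> reflectance exactly 1
  white <- c(90, 100, 110)
  raw1 <- hyperCube(aperm(array(white, c(3, 2, 2)), c(2, 3, 1)), grid)
  expect_equal(as.vector(cubeData(whiteCorrect(raw1, whiteReference(white)))),
               rep(1, 12))
  # all-zero raw -> reflectance 0
  raw0 <- hyperCube(array(0, c(2, 2, 3)), grid)
  expect_equal(as.vector(cubeData(whiteCorrect(raw0, whiteReference(white)))),
               rep(0, 12))
  # hand arithmetic with a dark term: (60 - 10) / (110 - 10) = 0.5
  raw <- hyperCube(array(60, c(1, 1, 3)), grid)
  ref <- whiteReference(rep(110, 3), dark = 10)
  expect_equal(as.vector(cubeData(whiteCorrect(raw, ref))), rep(0.5, 3))
})

test_that("white correction is scale-invariant and clips to the headroom", {
  withr::with_seed(7, {
    raw <- array(runif(2 * 2 * 4, 10, 200), c(2, 2, 4))
    white <- runif(4, 150, 250)
  })
  grid <- c(500, 600, 700, 800)
  r1 <- whiteCorrect(hyperCube(raw, grid), whiteReference(white))
  r2 <- whiteCorrect(hyperCube(raw * 3.7, grid), whiteReference(white * 3.7))
  expect_equal(cubeData(r1), cubeData(r2))
  # specular pixel beyond the panel gets clipped at 1 + headroom
  hot <- hyperCube(array(white[1] * 2, c(1, 1, 4)), grid, headroom = 0.1)
  expect_equal(max(cubeData(whiteCorrect(hot, whiteReference(rep(white[1], 4))))),
               1.1)
})

test_that("degenerate references are rejected", {
  expect_error(whiteReference(c(10, 0, 10)), "exceed dark")
  raw <- hyperCube(array(1, c(1, 1, 2)), c(500, 600))
  expect_error(whiteCorrect(raw, whiteReference(c(5, 5), dark = c(0, 5))),
               "exceed dark")
  refl <- whiteCorrect(raw, whiteReference(c(2, 2)))
  expect_error(whiteCorrect(refl, whiteReference(c(2, 2))), "already")
})
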