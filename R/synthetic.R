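# Synthetic apple reflectance generator. Emulates the structure the pipeline
# assumes: smooth Vis-NIR reflectance in [0,1] over 395-1008 nm with
# cultivar-modulated pigment absorption in the visible, a chlorophyll dip
# near 680 nm, a water feature near 970 nm, and narrow analyte-linked
# absorption features (Beer-Lambert-style additive Gaussians). Analyte panels
# span the measured ranges: VC 1.08-3.27 mg/100 g, SSC 8.48-11.92 %,
# SP 0.32-0.51 mg/g.

#' Optical forward model for synthetic spectra
#'
#' @slot grid the [WavelengthGrid-class] spectra are generated on.
#' @slot baseline per-band cultivar-neutral reflectance curve.
#' @slot features data.frame with one analyte-linked Gaussian absorption per
#'   row: `center` (nm), `width` (nm, Gaussian sigma), `analyte`
#'   (`"vc"`/`"ssc"`/`"sp"`), `strength` (max depth in reflectance units) and
#'   `depth_sd` (SD of the band-specific sub-pool deviation: each absorption
#'   band reflects its own chemical sub-fraction whose load is the analyte
#'   load plus a centered deviation, so the analyte equals the average band
#'   load and every planted band carries necessary, recoverable
#'   information).
#' @slot noiseSd band-wise iid Gaussian noise SD (reflectance units).
#' @slot smoothAmp coefficient SD of the per-sample smooth baseline
#'   perturbation (broad Gaussian basis), emulating fruit-to-fruit continuum
#'   variation.
#' @slot scatter length-2 numeric `(multiplicative SD, additive SD)`;
#'   `c(0, 0)` disables per-sample scatter distortion (the default).
#' @slot analyteRanges named list of `c(min, max)` per analyte.
#' @slot cultivarDepths named numeric, visible-pigment depth per cultivar.
#' @export
setClass("OpticalModel", representation(
  grid = "WavelengthGrid", baseline = "numeric", features = "data.frame",
  noiseSd = "numeric", smoothAmp = "numeric", scatter = "numeric",
  analyteRanges = "list", cultivarDepths = "numeric"
))

setValidity("OpticalModel", function(object) {
  wl <- object@grid@values
  f <- object@features
  if (nrow(f) && (any(f$center < min(wl)) || any(f$center > max(wl))))
    return("feature centers must lie inside the wavelength grid")
  if (length(object@baseline) != length(wl))
    return("baseline must have one value per band")
  TRUE
})

#' Default analyte-linked absorption features
#'
#' Narrow features for vitamin C at 409/577/679/700/757 nm and for soluble
#' protein at 403/430/551/617/846 nm; broad soluble-solids features across
#' 700-950 nm.
#'
#' @param strength peak absorption depth (reflectance units).
#' @param depthSd SD of the centered band-specific sub-pool deviation.
#' @return data.frame of feature rows (see [OpticalModel-class]).
#' @export
defaultFeatures <- function(strength = 0.07, depthSd = 0.18) {
  rbind(
    data.frame(center = c(409, 577, 679, 700, 757), width = 8,
               analyte = "vc", strength = strength, depth_sd = depthSd),
    data.frame(center = c(730, 790, 840, 910), width = c(40, 45, 50, 45),
               analyte = "ssc", strength = strength, depth_sd = depthSd),
    data.frame(center = c(403, 430, 551, 617, 846), width = 7,
               analyte = "sp", strength = strength, depth_sd = depthSd)
  )
}

#' Construct the synthetic optical model
#'
#' @param grid a [WavelengthGrid-class] (default: 360 bands, 395-1008 nm).
#' @param features feature table (default [defaultFeatures()]).
#' @param noiseSd iid noise SD (default 0.005 reflectance units).
#' @param smoothAmp per-sample smooth continuum perturbation SD
#'   (default 0.012).
#' @param scatter `c(multiplicative SD, additive SD)` per-sample scatter;
#'   off by default.
#' @return An [OpticalModel-class].
#' @export
opticalModel <- function(grid = wavelengthGrid(), features = defaultFeatures(),
                         noiseSd = 0.005, smoothAmp = 0.012,
                         scatter = c(0, 0)) {
  wl <- grid@values
  base <- 0.32 + 0.40 / (1 + exp(-(wl - 640) / 45))
  new("OpticalModel", grid = grid, baseline = base, features = features,
      noiseSd = noiseSd, smoothAmp = smoothAmp, scatter = scatter,
      analyteRanges = list(vc = c(1.08, 3.27), ssc = c(8.48, 11.92),
                           sp = c(0.32, 0.51)),
      cultivarDepths = c(AKS = 0.08, SPFS = 0.11, YTFS = 0.13, YT = 0.15,
                         GG = 0.18, HN = 0.22))
}

# Gaussian absorption profile over the grid.
gaussBand <- function(wl, center, width) exp(-(wl - center)^2 / (2 * width^2))

# Map analyte values to the normalized [0, 1] load driving band depths.
analyteLoad <- function(x, range) (x - range[1]) / (range[2] - range[1])

#' Generate a labeled synthetic spectral dataset
#'
#' Draws analyte panels uniformly from the measured ranges, assigns cultivar
#' labels, and renders reflectance as
#' `baseline - pigment - chlorophyll - water - sum(features) + smooth + noise`,
#' clipped to `[0, 1]`. Every analyte-linked feature depth is affine in its
#' analyte (exactly affine when `noiseSd = 0` and `depth_sd = 0`).
#'
#' @param n number of samples (>= 10).
#' @param grid a [WavelengthGrid-class]; must match `model@grid`.
#' @param model an [OpticalModel-class].
#' @param seed RNG seed; identical `(seed, model)` reproduce the dataset
#'   exactly.
#' @return A [SpectralSet-class] with colData columns `vc`, `ssc`, `sp`,
#'   `cultivar`.
#' @examples
#' g <- wavelengthGrid(90)
#' ds <- generateDataset(20, g, opticalModel(g), seed = 1)
#' dim(spectra(ds))
#' @export
generateDataset <- function(n, grid = wavelengthGrid(),
                            model = opticalModel(grid), seed = 1L) {
  stopifnot(n >= 10L)
  if (!isTRUE(all.equal(grid@values, model@grid@values)))
    stop("grid does not match model@grid")
  validObject(model)
  wl <- grid@values
  nb <- length(wl)
  withSeed(seed, {
    rng <- model@analyteRanges
    panel <- data.frame(
      vc = runif(n, rng$vc[1], rng$vc[2]),
      ssc = runif(n, rng$ssc[1], rng$ssc[2]),
      sp = runif(n, rng$sp[1], rng$sp[2]),
      cultivar = sample(names(model@cultivarDepths), n, replace = TRUE))
    R <- matrix(rep(model@baseline, each = n), n, nb)
    # cultivar-level pigment absorption in the visible (400-675 nm)
    pig <- gaussBand(wl, 530, 90)
    depth <- unname(model@cultivarDepths[panel$cultivar]) *
      (1 + 0.10 * rnorm(n))
    R <- R - depth %o% pig
    # chlorophyll dip near 680 nm and water feature near 970 nm
    R <- R - (0.05 * (1 + 0.3 * rnorm(n))) %o% gaussBand(wl, 680, 12)
    R <- R - (0.10 * (1 + 0.2 * rnorm(n))) %o% gaussBand(wl, 970, 25)
    # Analyte-linked absorption features. Each analyte aggregates one
    # chemical sub-pool per band (e.g. distinct protein fractions with their
    # own vibrational bands): band k carries load u + d_k where the d_k are
    # centered across the analyte's bands, so the panel value is exactly the
    # average band load and every band holds necessary information.
    f <- model@features
    for (a in unique(f$analyte)) {
      rows <- which(f$analyte == a)
      u <- analyteLoad(panel[[a]], rng[[a]])
      D <- vapply(rows, function(k) f$depth_sd[k] * rnorm(n),
                  numeric(n))
      if (length(rows) > 1L) D <- D - rowMeans(D)
      for (j in seq_along(rows)) {
        k <- rows[j]
        R <- R - (f$strength[k] * (u + D[, j])) %o%
          gaussBand(wl, f$center[k], f$width[k])
      }
    }
    # per-sample smooth continuum perturbation
    basis <- vapply(c(430, 550, 700, 850, 980),
                    function(cc) gaussBand(wl, cc, 130), numeric(nb))
    R <- R + (matrix(rnorm(n * ncol(basis), sd = model@smoothAmp),
                     n) %*% t(basis))
    R <- R + rnorm(n, sd = model@smoothAmp * 0.7)   # flat offset
    if (any(model@scatter > 0)) {
      m <- 1 + rnorm(n, sd = model@scatter[1])
      aadd <- rnorm(n, sd = model@scatter[2])
      R <- R * m + aadd
    }
    if (model@noiseSd > 0) R <- R + matrix(rnorm(n * nb, sd = model@noiseSd), n)
    R <- pmin(pmax(R, 0), 1)
    spectralSet(R, wl, panel)
  })
}

#' Generate a synthetic fruit cube with ground truth
#'
#' Renders a single "apple" — an ellipse with harmonic boundary
#' perturbation — carrying one generated reflectance spectrum modulated by a
#' smooth spatial gain field in [0.9, 1.1], over a dark low-NIR background.
#' Returns the true mask for IoU testing and the true analyte panel.
#'
#' @param rows,cols image dimensions.
#' @param grid a [WavelengthGrid-class].
#' @param model an [OpticalModel-class].
#' @param seed RNG seed (shape and spectrum).
#' @param gain logical; `FALSE` sets the spatial gain field to exactly 1.
#' @return list with `cube` ([HyperCube-class], reflectance), `mask`
#'   ([RoiMask-class], ground truth) and `panel` (1-row analyte data.frame).
#' @export
generateCube <- function(rows, cols, grid = wavelengthGrid(),
                         model = opticalModel(grid), seed = 1L, gain = TRUE) {
  ds <- generateDataset(10L, grid, model, seed = seed)
  spec <- spectra(ds)[1L, ]
  panel <- analytes(ds)[1L, , drop = FALSE]
  nb <- length(spec)
  withSeed(seed + 1000L, {
    cy <- rows / 2 + runif(1, -rows * 0.05, rows * 0.05)
    cx <- cols / 2 + runif(1, -cols * 0.05, cols * 0.05)
    ry <- rows * runif(1, 0.26, 0.32)
    rx <- cols * runif(1, 0.26, 0.32)
    if (cy - ry < 2 || cy + ry > rows - 1 || cx - rx < 2 || cx + rx > cols - 1)
      stop("degenerate geometry: fruit does not fit with a 2-pixel margin")
    eps <- runif(3, 0, 0.04)
    phi <- runif(3, 0, 2 * pi)
    rr <- matrix(seq_len(rows), rows, cols)
    cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    theta <- atan2((rr - cy) / ry, (cc - cx) / rx)
    rad <- sqrt(((rr - cy) / ry)^2 + ((cc - cx) / rx)^2)
    bnd <- 1 + eps[1] * cos(2 * theta + phi[1]) +
      eps[2] * cos(3 * theta + phi[2]) + eps[3] * cos(4 * theta + phi[3])
    mask <- rad <= bnd
    g <- if (gain) {
      1 + 0.06 * sin(2 * pi * rr / rows + runif(1, 0, 2 * pi)) *
        cos(2 * pi * cc / cols + runif(1, 0, 2 * pi)) +
        0.04 * (rr - cy) / rows
    } else matrix(1, rows, cols)
    g <- pmin(pmax(g, 0.9), 1.1)
    # dark background, slightly brighter in the blue than the NIR
    wl <- grid@values
    bg <- 0.07 - 0.03 / (1 + exp(-(wl - 640) / 45))
    cube <- array(0, c(rows, cols, nb))
    for (b in seq_len(nb)) {
      plane <- matrix(bg[b], rows, cols)
      plane[mask] <- spec[b] * g[mask]
      if (model@noiseSd > 0)
        plane <- plane + matrix(rnorm(rows * cols, sd = model@noiseSd), rows)
      cube[, , b] <- plane
    }
    cube <- pmin(pmax(cube, 0), 1)
    list(cube = hyperCube(array(cube, c(rows, cols, nb)), grid,
                          kind = "reflectance"),
         mask = roiMask(mask), panel = panel)
  })
}
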