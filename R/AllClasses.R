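#' @import methods
#' @importFrom stats sd var rnorm runif rbinom qf coef lm.fit setNames
#' @importFrom utils head tail write.csv read.csv
NULL

#' Wavelength grid of a hyperspectral sensor
#'
#' Ordered band-center wavelengths in nanometres. The default grid mirrors a
#' push-broom Vis-NIR imager acquiring 360 contiguous bands spanning
#' 395--1008 nm.
#'
#' @slot values numeric, strictly increasing band centers (nm).
#' @export
setClass("WavelengthGrid", representation(values = "numeric"))

setValidity("WavelengthGrid", function(object) {
  v <- object@values
  if (length(v) < 1L) return("grid must contain at least one band")
  if (any(!is.finite(v))) return("wavelengths must be finite")
  if (is.unsorted(v, strictly = TRUE)) return("wavelengths must be strictly increasing")
  TRUE
})

#' Construct a wavelength grid
#'
#' @param count number of bands.
#' @param range inclusive wavelength range in nm; `count` evenly spaced
#'   centers are placed on it. Ignored when `values` is given.
#' @param values explicit band centers (nm), overriding `count`/`range`.
#' @return A [WavelengthGrid-class] object.
#' @examples
#' g <- wavelengthGrid()          # 360 bands, 395-1008 nm
#' length(wavelengths(g))
#' @export
wavelengthGrid <- function(count = 360L, range = c(395, 1008), values = NULL) {
  if (is.null(values)) values <- seq(range[1], range[2], length.out = count)
  new("WavelengthGrid", values = as.numeric(values))
}

#' Hyperspectral reflectance/intensity cube
#'
#' A rows x cols x bands volume with its wavelength grid. `kind` records
#' whether values are raw sensor intensities or white-reference-corrected
#' reflectance fractions.
#'
#' @slot data numeric array, rows x cols x bands (band-last storage).
#' @slot grid [WavelengthGrid-class] with one entry per band.
#' @slot kind `"raw"` or `"reflectance"`.
#' @slot headroom allowed excess over 1 for reflectance (specular pixels).
#' @export
setClass("HyperCube", representation(
  data = "array", grid = "WavelengthGrid", kind = "character",
  headroom = "numeric"
))

setValidity("HyperCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-D array (rows x cols x bands)")
  if (d[3] != length(object@grid@values))
    return(sprintf("bands dimension (%d) must equal grid size (%d)",
                   d[3], length(object@grid@values)))
  if (!object@kind %in% c("raw", "reflectance"))
    return("kind must be 'raw' or 'reflectance'")
  if (object@kind == "reflectance") {
    v <- object@data
    if (any(!is.finite(v))) return("reflectance cube must be finite")
    if (any(v < 0) || any(v > 1 + object@headroom))
      return(sprintf("reflectance must lie in [0, %g]", 1 + object@headroom))
  }
  TRUE
})

#' Construct a hyperspectral cube
#'
#' @param data rows x cols x bands array of non-negative values.
#' @param grid a [WavelengthGrid-class] (or numeric wavelengths) matching the
#'   third dimension.
#' @param kind `"raw"` (sensor counts) or `"reflectance"`.
#' @param headroom tolerated excess of reflectance over 1 (default 0.1).
#' @return A [HyperCube-class].
#' @export
hyperCube <- function(data, grid, kind = c("raw", "reflectance"),
                      headroom = 0.1) {
  kind <- match.arg(kind)
  if (is.numeric(grid)) grid <- wavelengthGrid(values = grid)
  new("HyperCube", data = data, grid = grid, kind = kind, headroom = headroom)
}

#' White-reference measurement
#'
#' Per-band mean intensity of the white calibration panel, with an optional
#' dark-current spectrum (defaults to zero at every band).
#'
#' @slot spectrum numeric, per-band white-panel intensity.
#' @slot dark numeric, per-band dark current.
#' @export
setClass("WhiteReference", representation(spectrum = "numeric", dark = "numeric"))

setValidity("WhiteReference", function(object) {
  if (length(object@dark) != length(object@spectrum))
    return("dark and spectrum must have the same length")
  if (any(object@spectrum <= object@dark))
    return(sprintf("white spectrum must exceed dark at every band (offending: %s)",
                   paste(which(object@spectrum <= object@dark), collapse = ", ")))
  TRUE
})

#' Construct a white reference
#' @param spectrum per-band white-panel intensity.
#' @param dark per-band dark current; scalar is recycled (default 0).
#' @return A [WhiteReference-class].
#' @export
whiteReference <- function(spectrum, dark = 0) {
  if (length(dark) == 1L) dark <- rep(dark, length(spectrum))
  new("WhiteReference", spectrum = as.numeric(spectrum), dark = as.numeric(dark))
}

#' Region-of-interest mask
#'
#' Boolean fruit mask over the image plane; by construction it holds exactly
#' one connected (8-neighbourhood) foreground component with interior holes
#' filled.
#'
#' @slot mask logical matrix, rows x cols.
#' @slot area foreground pixel count.
#' @export
setClass("RoiMask", representation(mask = "matrix", area = "integer"))

setValidity("RoiMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (object@area != sum(object@mask)) return("area must equal sum(mask)")
  if (object@area < 1L) return("mask must be non-empty")
  TRUE
})

roiMask <- function(mask) new("RoiMask", mask = mask, area = as.integer(sum(mask)))

#' Closed fruit contour with its periodic B-spline model
#'
#' @slot points closed (first row == last row) matrix of (row, col) samples of
#'   the smoothed contour.
#' @slot boundary the raw traced boundary polyline (closed).
#' @slot control B-spline control polygon, one row per control point.
#' @slot degree spline degree.
#' @export
setClass("SpectralContour", representation(
  points = "matrix", boundary = "matrix", control = "matrix", degree = "integer"
))

setValidity("SpectralContour", function(object) {
  p <- object@points
  if (ncol(p) != 2L) return("points must have two columns (row, col)")
  if (!isTRUE(all.equal(p[1, ], p[nrow(p), ]))) return("contour must be closed")
  TRUE
})

#' Successive-projections-algorithm result
#'
#' @slot selected integer indices of the selected bands, in relevance order.
#' @slot wavelengths selected band centers (nm), parallel to `selected`.
#' @slot pressBySize named numeric; best PRESS per candidate subset size.
#' @slot press PRESS of the final subset.
#' @slot relevance relevance index per selected variable of the unpruned
#'   winning subset (|coefficient| x column SD).
#' @slot chainStart index that started the winning projection chain.
#' @export
setClass("SpaResult", representation(
  selected = "integer", wavelengths = "numeric", pressBySize = "numeric",
  press = "numeric", relevance = "numeric", chainStart = "integer"
))

setValidity("SpaResult", function(object) {
  if (anyDuplicated(object@selected)) return("selected indices must be unique")
  TRUE
})

#' Network architecture plan
#'
#' @slot kind `"cnn"`, `"cnn_bigru"` or `"cnn_bigru_attention"`.
#' @slot nBands input spectrum length n (the [n x 1 x 1] reshape).
#' @slot layers list of layer descriptors (type, dimensioning, parameters).
#' @slot nParams total trainable parameter count.
#' @export
setClass("ModelSpec", representation(
  kind = "character", nBands = "integer", layers = "list", nParams = "integer"
))

#' Training schedule
#'
#' @slot kind architecture family the defaults belong to.
#' @slot epochs number of epochs.
#' @slot initialLr initial Adam learning rate.
#' @slot l2 L2 regularization factor on weights.
#' @slot lrDecayFactor multiplicative decay (hybrids: 0.1, applied once).
#' @slot lrDecayEpoch epoch after which the decay applies (0 = never).
#' @slot batchSize mini-batch size.
#' @slot seed RNG seed governing init, shuffling and dropout.
#' @slot dropout dropout rate of the CNN plan's dropout layer (default 0.4;
#'   the hybrid plans have no dropout layer).
#' @slot scaleInputs standardize inputs per band on training data.
#' @export
setClass("TrainConfig", representation(
  kind = "character", epochs = "integer", initialLr = "numeric", l2 = "numeric",
  lrDecayFactor = "numeric", lrDecayEpoch = "integer", batchSize = "integer",
  seed = "integer", dropout = "numeric", scaleInputs = "logical"
))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be positive")
  if (object@initialLr <= 0) return("initialLr must be positive")
  if (object@batchSize < 1L) return("batchSize must be positive")
  TRUE
})

#' Trained regression network
#'
#' @slot spec the [ModelSpec-class] built for the input length.
#' @slot config the [TrainConfig-class] used.
#' @slot params named list of weight matrices/vectors.
#' @slot bnStats frozen batch-norm running statistics.
#' @slot xCenter,xScale per-band input standardization frozen from training.
#' @slot yCenter,yScale response standardization frozen from training.
#' @slot lossCurve per-epoch mean training loss (standardized scale).
#' @slot lrCurve per-epoch learning rate actually applied.
#' @export
setClass("TrainedModel", representation(
  spec = "ModelSpec", config = "TrainConfig", params = "list", bnStats = "list",
  xCenter = "numeric", xScale = "numeric", yCenter = "numeric",
  yScale = "numeric", lossCurve = "numeric", lrCurve = "numeric"
))

#' Prediction quality report
#'
#' Holds the coefficient of determination, root mean squared error, the
#' standard deviation of the measured values, the residual predictive
#' deviation RPD = SD/RMSE and its qualitative band: RPD > 2.0 is "good",
#' RPD <= 1.4 "weak", otherwise "intermediate".
#'
#' @slot r2,rmse,sd,rpd numeric metrics.
#' @slot band qualitative label.
#' @slot n sample count.
#' @slot sdConvention `"sample"` (n-1) or `"population"` (n).
#' @export
setClass("MetricsReport", representation(
  r2 = "numeric", rmse = "numeric", sd = "numeric", rpd = "numeric",
  band = "character", n = "integer", sdConvention = "character"
))

#' Train/test partition plan
#'
#' @slot train,test disjoint, exhaustive sample indices.
#' @slot ratio training fraction.
#' @slot seed shuffle seed.
#' @export
setClass("SplitPlan", representation(
  train = "integer", test = "integer", ratio = "numeric", seed = "integer"
))

setValidity("SplitPlan", function(object) {
  if (length(intersect(object@train, object@test)) > 0L)
    return("train and test indices must be disjoint")
  TRUE
})

#' Spectra-with-analytes container
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose single assay `"reflectance"` stores bands (rows) x samples (columns);
#' `rowData` carries `wavelength_nm` and `colData` the per-sample analyte
#' panel (`vc` mg/100 g, `ssc` percent, `sp` mg/g) plus optional `cultivar`.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("SpectralSet", contains = "SummarizedExperiment")

setValidity("SpectralSet", function(object) {
  if (!"reflectance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'reflectance' is required")
  if (!"wavelength_nm" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData must contain 'wavelength_nm'")
  TRUE
})

#' Construct a SpectralSet
#'
#' @param spectra samples x bands reflectance matrix.
#' @param wavelengths band centers in nm (length = ncol(spectra)) or a
#'   [WavelengthGrid-class].
#' @param analytes data.frame with one row per sample (e.g. columns `vc`,
#'   `ssc`, `sp`); may be `NULL` for unlabeled spectra.
#' @return A [SpectralSet-class].
#' @examples
#' s <- spectralSet(matrix(runif(20), 4, 5), wavelengths = seq(400, 800, 100),
#'                  analytes = data.frame(ssc = runif(4, 8, 12)))
#' dim(spectra(s))
#' @export
spectralSet <- function(spectra, wavelengths, analytes = NULL) {
  if (is(wavelengths, "WavelengthGrid")) wavelengths <- wavelengths@values
  spectra <- as.matrix(spectra)
  stopifnot(ncol(spectra) == length(wavelengths))
  if (is.null(rownames(spectra)))
    rownames(spectra) <- sprintf("sample%03d", seq_len(nrow(spectra)))
  cd <- if (is.null(analytes)) S4Vectors::DataFrame(row.names = rownames(spectra))
        else S4Vectors::DataFrame(analytes, row.names = rownames(spectra))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reflectance = t(spectra)),
    rowData = S4Vectors::DataFrame(wavelength_nm = as.numeric(wavelengths)),
    colData = cd)
  new("SpectralSet", se)
}
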