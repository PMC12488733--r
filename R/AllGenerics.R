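#' Extract wavelengths
#'
#' Band-center wavelengths in nanometres of a grid, cube or spectral set.
#'
#' @param x a [WavelengthGrid-class], [HyperCube-class] or
#'   [SpectralSet-class].
#' @return numeric vector of wavelengths (nm).
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "WavelengthGrid", function(x) x@values)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "HyperCube", function(x) x@grid@values)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectralSet", function(x)
  SummarizedExperiment::rowData(x)$wavelength_nm)

#' Spectra matrix of a SpectralSet
#'
#' @param x a [SpectralSet-class].
#' @return samples x bands numeric matrix.
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname spectra
#' @export
setMethod("spectra", "SpectralSet", function(x)
  t(SummarizedExperiment::assay(x, "reflectance")))

#' Per-sample analyte panel
#'
#' @param x a [SpectralSet-class].
#' @return data.frame, one row per sample.
#' @export
setGeneric("analytes", function(x) standardGeneric("analytes"))

#' @rdname analytes
#' @export
setMethod("analytes", "SpectralSet", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' Cube data array
#' @param x a [HyperCube-class].
#' @return rows x cols x bands array.
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' @rdname cubeData
#' @export
setMethod("cubeData", "HyperCube", function(x) x@data)

#' Cube kind ("raw" or "reflectance")
#' @param x a [HyperCube-class].
#' @export
setGeneric("cubeKind", function(x) standardGeneric("cubeKind"))

#' @rdname cubeKind
#' @export
setMethod("cubeKind", "HyperCube", function(x) x@kind)

#' Mask matrix of an ROI
#' @param x a [RoiMask-class].
#' @return logical rows x cols matrix.
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname maskMatrix
#' @export
setMethod("maskMatrix", "RoiMask", function(x) x@mask)

#' Selected band indices of an SPA result
#' @param x a [SpaResult-class].
#' @export
setGeneric("selectedBands", function(x) standardGeneric("selectedBands"))

#' @rdname selectedBands
#' @export
setMethod("selectedBands", "SpaResult", function(x) x@selected)

setMethod("show", "WavelengthGrid", function(object) {
  v <- object@values
  cat(sprintf("WavelengthGrid: %d bands, %.1f-%.1f nm (step ~%.2f nm)\n",
              length(v), min(v), max(v),
              if (length(v) > 1) mean(diff(v)) else NA_real_))
})

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperCube [%s]: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              object@kind, d[1], d[2], d[3],
              min(object@grid@values), max(object@grid@values)))
})

setMethod("show", "RoiMask", function(object) {
  cat(sprintf("RoiMask: %d x %d image, %d foreground pixels\n",
              nrow(object@mask), ncol(object@mask), object@area))
})

setMethod("show", "SpaResult", function(object) {
  cat(sprintf("SpaResult: %d selected bands (PRESS = %.4g)\n",
              length(object@selected), object@press))
  cat("  wavelengths (nm): ",
      paste(round(object@wavelengths), collapse = ", "), "\n", sep = "")
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec '%s': input [%d x 1 x 1], %d trainable parameters\n",
              object@kind, object@nBands, object@nParams))
  for (l in object@layers)
    cat(sprintf("  %-22s %s (%d params)\n", l$type, l$shape, l$nParams))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel '%s' (%d bands): %d epochs, final loss %.4g\n",
              object@spec@kind, object@spec@nBands, object@config@epochs,
              tail(object@lossCurve, 1)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport (n=%d, %s SD): R2 = %.3f, RMSE = %.4g, SD = %.4g, RPD = %.3f [%s]\n",
    object@n, object@sdConvention, object@r2, object@rmse, object@sd,
    object@rpd, object@band))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d train / %d test (ratio %.2f, seed %d)\n",
              length(object@train), length(object@test), object@ratio,
              object@seed))
})
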