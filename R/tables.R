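# Plain-text spectra/analyte tables — the non-imaging entry point.

#' Write a spectra table as CSV
#'
#' First column `sample`, remaining columns wavelength-labeled reflectance
#' (`wl_<nm>`). An accompanying analyte table can be written next to it.
#'
#' @param x a [SpectralSet-class].
#' @param path output CSV path.
#' @param analytePath optional path for the per-sample analyte table.
#' @return `path`, invisibly.
#' @export
writeSpectraTable <- function(x, path, analytePath = NULL) {
  S <- spectra(x)
  df <- data.frame(sample = rownames(S), S, check.names = FALSE)
  colnames(df)[-1] <- sprintf("wl_%.6f", wavelengths(x))
  write.csv(df, path, row.names = FALSE)
  if (!is.null(analytePath)) {
    an <- analytes(x)
    write.csv(data.frame(sample = rownames(S), an, check.names = FALSE),
              analytePath, row.names = FALSE)
  }
  invisible(path)
}

#' Read a spectra table (plus optional analyte table) from CSV
#'
#' @param path spectra CSV (first column sample id, remaining columns
#'   wavelength-labeled reflectance).
#' @param analytePath optional analyte CSV with a matching `sample` column.
#' @return A [SpectralSet-class].
#' @export
readSpectraTable <- function(path, analytePath = NULL) {
  df <- read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  S <- as.matrix(df[, -1, drop = FALSE])
  rownames(S) <- ids
  wl <- as.numeric(sub("^wl_", "", colnames(df)[-1]))
  if (any(is.na(wl)))
    stop("spectra columns must be wavelength-labeled (wl_<nm>)")
  an <- NULL
  if (!is.null(analytePath)) {
    at <- read.csv(analytePath)
    an <- at[match(ids, as.character(at$sample)), setdiff(names(at), "sample"),
             drop = FALSE]
  }
  spectralSet(S, wl, an)
}
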