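# Savitzky-Golay smoothing — the pipeline's sole spectral preprocessing.
# Scatter corrections (SNV/MSC/derivatives) are deliberately absent: the
# downstream networks carry their own normalization (batch norm, learned
# weights), so extra corrections are redundant.

#' Savitzky-Golay smoothing of spectra
#'
#' Sliding-window local least squares: each band value is replaced by the
#' window-center value of the degree-`order` polynomial fitted to the
#' surrounding `window` bands. The first and last half-windows are handled by
#' evaluating the polynomial of the nearest full window at the edge
#' positions, so the band axis keeps its full length (required by the
#' `[n x 1 x 1]` network reshape downstream).
#'
#' The defaults (window 11, order 2) are the common Vis-NIR choice; both are
#' surfaced here and in the pipeline configuration.
#'
#' @param spectra numeric vector (one spectrum) or samples x bands matrix.
#' @param window odd window width in bands.
#' @param order polynomial degree, `< window`.
#' @return Smoothed object of the same shape.
#' @examples
#' x <- seq(0, 1, length.out = 100)
#' noisy <- sin(6 * x) + rnorm(100, sd = 0.05)
#' sm <- sgSmooth(noisy, window = 11, order = 2)
#' @export
sgSmooth <- function(spectra, window = 11L, order = 2L) {
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L) stop("window must be odd")
  if (order >= window) stop("order must be smaller than window")
  vec <- is.null(dim(spectra))
  X <- if (vec) matrix(spectra, nrow = 1L) else as.matrix(spectra)
  if (ncol(X) < window)
    stop(sprintf("window (%d) exceeds band count (%d)", window, ncol(X)))
  out <- t(apply(X, 1L, function(s)
    signal::sgolayfilt(s, p = order, n = window)))
  if (vec) drop(out) else {
    dimnames(out) <- dimnames(X)
    out
  }
}

#' Savitzky-Golay filter weights (window-center row)
#'
#' Convolution coefficients applied at interior bands; they sum to one
#' (constants are preserved exactly).
#'
#' @inheritParams sgSmooth
#' @return numeric vector of length `window`.
#' @export
sgKernel <- function(window = 11L, order = 2L) {
  S <- signal::sgolay(p = order, n = window)
  as.numeric(S[(window + 1L) %/% 2L, ])
}
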