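# ENVI cube input/output and white-reference correction.
#
# ENVI stores a plain-text header (.hdr) next to a flat binary file. The
# writer emits BSQ interleave, 32-bit little-endian float; the reader accepts
# BIL, BIP and BSQ and the common numeric data types.

.enviTypes <- list(
  `1` = list(what = "integer", size = 1L, signed = FALSE),
  `2` = list(what = "integer", size = 2L, signed = TRUE),
  `4` = list(what = "numeric", size = 4L, signed = TRUE),
  `5` = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

# Parse an ENVI header into a named list; brace-delimited values may span
# lines.
parseEnviHeader <- function(headerPath) {
  txt <- paste(readLines(headerPath, warn = FALSE), collapse = "\n")
  out <- list()
  lines <- strsplit(txt, "\n")[[1]]
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("=", ln, fixed = TRUE)) {
      key <- tolower(trimws(sub("=.*$", "", ln)))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (startsWith(val, "{")) {
        while (!grepl("\\}", val) && i < length(lines)) {
          i <- i + 1L
          val <- paste(val, trimws(lines[i]))
        }
        val <- gsub("[{}]", "", val)
      }
      out[[key]] <- trimws(val)
    }
    i <- i + 1L
  }
  out
}

#' Read an ENVI hyperspectral cube
#'
#' Reads the header/binary pair and returns a raw [HyperCube-class] with the
#' wavelength list parsed from the header. BIL, BIP and BSQ interleaves are
#' supported.
#'
#' @param headerPath path to the `.hdr` file; the binary is the same path
#'   without the extension (or with `.img`/`.dat` appended).
#' @param headroom passed to [hyperCube()] for downstream reflectance checks.
#' @return A [HyperCube-class] with `kind = "raw"` (or `"reflectance"` if the
#'   header carries `reflectance = 1`, as written by [writeENVI()]).
#' @seealso [writeENVI()], [whiteCorrect()]
#' @export
readENVI <- function(headerPath, headroom = 0.1) {
  if (!file.exists(headerPath)) stop("header not found: ", headerPath)
  h <- parseEnviHeader(headerPath)
  for (k in c("samples", "lines", "bands", "interleave", "data type"))
    if (is.null(h[[k]]))
      stop(sprintf("ENVI header '%s' lacks required field '%s'", headerPath, k))
  if (is.null(h[["wavelength"]]))
    stop(sprintf("ENVI header '%s' has no wavelength field", headerPath))
  samples <- as.integer(h$samples)   # pixels per line (columns)
  lines   <- as.integer(h$lines)     # rows
  bands   <- as.integer(h$bands)
  wl <- as.numeric(strsplit(h$wavelength, ",")[[1]])
  if (length(wl) != bands)
    stop(sprintf("header lists %d wavelengths for %d bands", length(wl), bands))
  interleave <- tolower(h$interleave)
  typ <- .enviTypes[[h[["data type"]]]]
  if (is.null(typ)) stop("unsupported ENVI data type: ", h[["data type"]])
  endian <- if (!is.null(h[["byte order"]]) && h[["byte order"]] == "1")
    "big" else "little"

  binPath <- sub("\\.hdr$", "", headerPath)
  if (!file.exists(binPath)) {
    alt <- paste0(binPath, c(".img", ".dat", ".raw"))
    binPath <- alt[file.exists(alt)][1]
    if (is.na(binPath)) stop("binary file for header not found: ", headerPath)
  }
  nExpect <- as.double(samples) * lines * bands
  nBytes <- file.info(binPath)$size
  if (nBytes != nExpect * typ$size)
    stop(sprintf("binary '%s' holds %.0f bytes but header implies %.0f",
                 binPath, nBytes, nExpect * typ$size))
  con <- file(binPath, "rb"); on.exit(close(con))
  v <- readBin(con, what = typ$what, n = nExpect, size = typ$size,
               signed = typ$signed, endian = endian)
  # De-interleave into rows x cols x bands (band-last storage).
  # ENVI is row-major per record: sample index varies fastest.
  arr <- switch(interleave,
    bsq = aperm(array(v, c(samples, lines, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(samples, bands, lines)), c(3L, 1L, 2L)),
    bip = aperm(array(v, c(bands, samples, lines)), c(3L, 2L, 1L)),
    stop("unsupported interleave: ", interleave))
  kind <- if (!is.null(h$reflectance) && h$reflectance == "1")
    "reflectance" else "raw"
  hyperCube(arr, wavelengthGrid(values = wl), kind = kind,
            headroom = headroom)
}

#' Write a cube in ENVI format
#'
#' Emits a `.hdr` header plus a flat binary in the requested interleave,
#' 32-bit float little-endian (ENVI data type 4).
#'
#' @param cube a [HyperCube-class].
#' @param path output path without extension; `<path>.hdr` and `<path>` are
#'   written.
#' @param interleave `"bsq"` (default), `"bil"` or `"bip"`.
#' @return `path`, invisibly.
#' @export
writeENVI <- function(cube, path, interleave = c("bsq", "bil", "bip")) {
  interleave <- match.arg(interleave)
  d <- dim(cube@data)
  hdr <- c(
    "ENVI",
    "description = { fruithsi cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("reflectance = %d", as.integer(cube@kind == "reflectance")),
    sprintf("wavelength = { %s }",
            paste(format(cube@grid@values, digits = 12, trim = TRUE),
                  collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  v <- switch(interleave,
    bsq = as.vector(aperm(cube@data, c(2L, 1L, 3L))),
    bil = as.vector(aperm(cube@data, c(2L, 3L, 1L))),
    bip = as.vector(aperm(cube@data, c(3L, 2L, 1L))))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  invisible(path)
}

#' White-reference correction
#'
#' Converts raw intensities to relative reflectance against a white panel:
#' `R[p, b] = (raw[p, b] - dark[b]) / (white[b] - dark[b])`, clipped to
#' `[0, 1 + headroom]` (specular pixels on glossy fruit commonly exceed the
#' panel slightly).
#'
#' @param raw a raw [HyperCube-class].
#' @param ref a [WhiteReference-class] on the same band grid.
#' @param headroom clip ceiling above 1 (default: the cube's own headroom).
#' @return A reflectance [HyperCube-class].
#' @examples
#' cube <- hyperCube(array(60, c(2, 2, 3)), c(500, 600, 700))
#' ref <- whiteReference(rep(110, 3), dark = 10)
#' range(cubeData(whiteCorrect(cube, ref)))   # (60-10)/(110-10) = 0.5
#' @export
whiteCorrect <- function(raw, ref, headroom = raw@headroom) {
  if (raw@kind != "raw") stop("cube is already reflectance")
  nb <- dim(raw@data)[3]
  if (length(ref@spectrum) != nb)
    stop(sprintf("white reference has %d bands, cube has %d",
                 length(ref@spectrum), nb))
  denom <- ref@spectrum - ref@dark
  bad <- which(denom == 0)
  if (length(bad))
    stop("zero white-minus-dark denominator at band(s): ",
         paste(bad, collapse = ", "))
  dk <- rep(ref@dark, each = prod(dim(raw@data)[1:2]))
  dn <- rep(denom, each = prod(dim(raw@data)[1:2]))
  refl <- (raw@data - dk) / dn
  refl <- pmin(pmax(refl, 0), 1 + headroom)
  hyperCube(array(refl, dim(raw@data)), raw@grid, kind = "reflectance",
            headroom = headroom)
}
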