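# Metric framework: coefficient of determination, RMSE, residual predictive
# deviation (RPD = SD/RMSE with its qualitative bands), 7:3 partitioning, and
# the internal-vs-external degradation percentage.

#' Coefficient of determination
#'
#' `R^2 = 1 - SSE/SST`, with SST taken about the mean of the measured values.
#'
#' @param y measured values.
#' @param yHat predicted values, same length.
#' @return numeric scalar (at most 1; can be negative for poor models).
#' @examples
#' rSquared(c(1, 2, 3), c(2, 2, 2))   # SSE = SST = 2 -> 0
#' @export
rSquared <- function(y, yHat) {
  stopifnot(length(y) == length(yHat))
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("measured values are all equal: R^2 undefined")
  1 - sum((y - yHat)^2) / sst
}

#' Root mean squared error
#'
#' `RMSE = sqrt(mean((y - yHat)^2))`, in the analyte's own units.
#'
#' @inheritParams rSquared
#' @return numeric scalar.
#' @export
rmse <- function(y, yHat) {
  stopifnot(length(y) == length(yHat), length(y) >= 1L)
  sqrt(mean((y - yHat)^2))
}

#' Residual predictive deviation
#'
#' `RPD = SD / RMSE`, the standard deviation of the measured values divided
#' by the prediction RMSE. RPD > 2.0 indicates good predictive performance;
#' RPD <= 1.4 indicates weak prediction. Under the population SD convention
#' the identity `RPD = 1 / sqrt(1 - R^2)` holds exactly.
#'
#' @inheritParams rSquared
#' @param sdConvention `"sample"` (n-1 denominator, default) or
#'   `"population"` (n).
#' @return numeric scalar.
#' @export
rpd <- function(y, yHat, sdConvention = c("sample", "population")) {
  sdConvention <- match.arg(sdConvention)
  e <- rmse(y, yHat)
  if (e == 0)
    stop("RMSE is zero (perfect predictions): RPD is undefined; report the fit as perfect instead")
  s <- if (sdConvention == "sample") sd(y)
       else sqrt(mean((y - mean(y))^2))
  s / e
}

#' Qualitative RPD band
#' @param rpd numeric RPD value.
#' @return `"good"` (> 2.0), `"weak"` (<= 1.4) or `"intermediate"`.
#' @export
rpdBand <- function(rpd) {
  if (rpd > 2.0) "good" else if (rpd <= 1.4) "weak" else "intermediate"
}

#' Build a metrics report for one prediction set
#'
#' @inheritParams rpd
#' @return A [MetricsReport-class].
#' @export
metricsReport <- function(y, yHat, sdConvention = c("sample", "population")) {
  sdConvention <- match.arg(sdConvention)
  stopifnot(length(y) == length(yHat), length(y) >= 3L)
  r <- rpd(y, yHat, sdConvention)
  s <- if (sdConvention == "sample") sd(y) else sqrt(mean((y - mean(y))^2))
  new("MetricsReport", r2 = rSquared(y, yHat), rmse = rmse(y, yHat),
      sd = s, rpd = r, band = rpdBand(r), n = length(y),
      sdConvention = sdConvention)
}

#' Seeded 7:3 train/test split
#'
#' Shuffles the sample indices under `seed` and assigns `round(ratio * n)`
#' samples to training. With `stratify` (e.g. cultivar labels) the split is
#' performed within each class, preserving per-class ratios to within one
#' sample.
#'
#' @param n sample count (>= 10).
#' @param seed shuffle seed.
#' @param ratio training fraction (default 0.7).
#' @param stratify optional length-`n` class labels.
#' @return A [SplitPlan-class].
#' @examples
#' splitTrainTest(96, seed = 1)   # 67 train / 29 test
#' @export
splitTrainTest <- function(n, seed, ratio = 0.7, stratify = NULL) {
  stopifnot(n >= 10L)
  if (is.null(stratify)) {
    idx <- withSeed(seed, sample.int(n))
    nTrain <- round(ratio * n)
    train <- sort(idx[seq_len(nTrain)])
    test <- sort(idx[-seq_len(nTrain)])
  } else {
    stopifnot(length(stratify) == n)
    tab <- table(stratify)
    if (any(tab < 2L))
      stop("every stratum needs at least 2 samples; offending: ",
           paste(names(tab)[tab < 2L], collapse = ", "))
    train <- integer(0L)
    for (cl in names(tab)) {
      ids <- which(stratify == cl)
      ids <- withSeed(seed + match(cl, names(tab)), sample(ids))
      train <- c(train, ids[seq_len(round(ratio * length(ids)))])
    }
    train <- sort(train)
    test <- setdiff(seq_len(n), train)
  }
  new("SplitPlan", train = as.integer(train), test = as.integer(test),
      ratio = ratio, seed = as.integer(seed))
}

#' Internal-to-external degradation percentage
#'
#' Percentage reduction of a metric from the internal test set to the
#' external validation set: `100 * (internal - external) / internal`,
#' rounded half-up to two decimals (the convention used when reporting
#' cross-year robustness).
#'
#' @param internal metric on the internal test set (> 0).
#' @param external metric on the external validation set.
#' @return numeric percentage, two decimals.
#' @examples
#' degradation(2.337, 2.150)   # 8.00 (% RPD reduction)
#' degradation(0.848, 0.835)   # 1.53 (% R^2 reduction)
#' @export
degradation <- function(internal, external) {
  if (!is.finite(internal) || internal <= 0)
    stop("internal metric must be positive")
  roundHalfUp(100 * (internal - external) / internal, 2)
}

#' Write metric reports to CSV/JSON
#'
#' @param reports named list of [MetricsReport-class] objects (names label
#'   the rows, e.g. "vc/test").
#' @param path output path; extension `.json` selects JSON, anything else
#'   CSV.
#' @return `path`, invisibly.
#' @export
writeMetrics <- function(reports, path) {
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    m <- reports[[nm]]
    data.frame(label = nm, n = m@n, r2 = m@r2, rmse = m@rmse, sd = m@sd,
               rpd = m@rpd, band = m@band, sd_convention = m@sdConvention)
  }))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
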