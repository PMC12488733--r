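# Successive projections algorithm (SPA) wavelength selection, in three
# phases:
#   1. standardize bands; grow one greedy orthogonal-projection chain per
#      starting variable (candidate subsets are chain prefixes);
#   2. score every prefix of size k_min..k_max by PRESS of an OLS fit on an
#      independent validation split; keep the global PRESS minimizer;
#   3. rank the winner's variables by a relevance index |b_j| * s_j and keep
#      the smallest prefix whose PRESS is not significantly worse than the
#      minimum under a one-sided F-test (default alpha = 0.25).

#' Standardize a spectra matrix
#'
#' Centers every band to zero mean and scales to unit variance. The variance
#' convention is population (divide by n), recorded in the result.
#'
#' @param X samples x bands matrix.
#' @return list with `Z` (standardized matrix), `center`, `scale` and
#'   `convention = "population"`.
#' @export
spaStandardize <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  scl <- sqrt(colMeans(Xc^2))
  bad <- which(scl == 0)
  if (length(bad))
    stop("zero-variance band(s): ", paste(bad, collapse = ", "))
  list(Z = sweep(Xc, 2L, scl, "/"), center = ctr, scale = scl,
       convention = "population")
}

#' Greedy orthogonal projection chain
#'
#' Starting from one column, repeatedly projects all unselected columns onto
#' the orthogonal complement of the span of the selected ones and appends the
#' column with the largest residual norm. Columns whose residual norm falls
#' to (numerical) zero — exact collinearity — are never selected; if the
#' residual space is exhausted the chain is truncated.
#'
#' @param Z samples x bands (typically standardized) matrix.
#' @param start index of the initial column.
#' @param kMax maximum chain length.
#' @param tol residual-norm cutoff, relative to the starting norms.
#' @return integer vector of column indices, `start` first.
#' @export
projectionChain <- function(Z, start, kMax, tol = 1e-9) {
  Z <- as.matrix(Z)
  p <- ncol(Z)
  stopifnot(start >= 1L, start <= p, kMax >= 1L, kMax <= p)
  R <- Z                      # residuals of every column
  norm0 <- sqrt(colSums(Z^2))
  chain <- integer(0L)
  current <- as.integer(start)
  for (k in seq_len(kMax)) {
    chain <- c(chain, current)
    v <- R[, current]
    nv2 <- sum(v^2)
    if (nv2 > 0) R <- R - v %*% crossprod(v, R) / nv2
    R[, chain] <- 0
    if (k == kMax) break
    norms <- sqrt(colSums(R^2))
    norms[chain] <- -Inf
    nxt <- which.max(norms)
    if (!is.finite(norms[nxt]) || norms[nxt] <= tol * max(norm0)) {
      # residual space exhausted: every remaining column is (numerically)
      # inside the selected span
      break
    }
    current <- nxt
  }
  chain
}

# PRESS of an intercept OLS fit of y on X[, vars]; NA when rank-deficient.
olsPress <- function(vars, Xcal, ycal, Xval, yval) {
  A <- cbind(1, Xcal[, vars, drop = FALSE])
  fit <- lm.fit(A, ycal)
  if (fit$rank < ncol(A)) return(NA_real_)
  pred <- cbind(1, Xval[, vars, drop = FALSE]) %*% fit$coefficients
  sum((yval - pred)^2)
}

#' PRESS evaluation of projection-chain prefixes
#'
#' Fits ordinary least squares (with intercept) of the calibration response
#' on every chain prefix of size `kMin..kMax` and scores it by the prediction
#' residual error sum of squares on the validation set. The winner is the
#' global PRESS minimum over all chains and sizes; rank-deficient prefixes
#' are skipped with a warning.
#'
#' @param chains list of integer index chains (from [projectionChain()]).
#' @param Xcal,ycal calibration spectra and response.
#' @param Xval,yval independent validation spectra and response (disjoint
#'   from calibration).
#' @param kMin,kMax candidate subset-size range.
#' @param grid optional wavelengths (nm) to attach to the result.
#' @return A [SpaResult-class]; `selected` is the winning prefix (chain
#'   order), `pressBySize` the best PRESS per size.
#' @export
pressEvaluate <- function(chains, Xcal, ycal, Xval, yval,
                          kMin = 5L, kMax = NULL, grid = NULL) {
  Xcal <- as.matrix(Xcal); Xval <- as.matrix(Xval)
  if (is.null(kMax)) kMax <- ncol(Xcal)
  kMax <- min(kMax, ncol(Xcal), nrow(Xcal) - 2L)
  kMin <- min(kMin, kMax)
  best <- list(press = Inf, vars = integer(0L), chain = NA_integer_)
  pressBySize <- setNames(rep(Inf, kMax - kMin + 1L),
                          as.character(kMin:kMax))
  skipped <- 0L
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    if (length(ch) < kMin) next
    for (k in kMin:min(kMax, length(ch))) {
      pr <- olsPress(ch[seq_len(k)], Xcal, ycal, Xval, yval)
      if (is.na(pr)) { skipped <- skipped + 1L; next }
      key <- as.character(k)
      if (pr < pressBySize[[key]]) pressBySize[[key]] <- pr
      if (pr < best$press)
        best <- list(press = pr, vars = ch[seq_len(k)], chain = ch[1L])
    }
  }
  if (skipped > 0L)
    warning(sprintf("%d rank-deficient prefixes skipped", skipped))
  if (!length(best$vars)) stop("no admissible subset found")
  pressBySize <- pressBySize[is.finite(pressBySize)]
  # relevance index on the winning subset: |coefficient| x column SD
  A <- cbind(1, Xcal[, best$vars, drop = FALSE])
  b <- lm.fit(A, ycal)$coefficients[-1L]
  rel <- abs(b) * apply(Xcal[, best$vars, drop = FALSE], 2L, sd)
  wl <- if (is.null(grid)) as.numeric(best$vars) else grid[best$vars]
  new("SpaResult", selected = as.integer(best$vars), wavelengths = wl,
      pressBySize = pressBySize, press = best$press,
      relevance = as.numeric(rel), chainStart = as.integer(best$chain))
}

#' F-test pruning of an SPA subset
#'
#' Ranks the winning subset's variables by relevance index (descending) and
#' returns the smallest prefix whose PRESS is not significantly worse than
#' the global minimum PRESS: keep the first size m with
#' `PRESS_m / PRESS_min <= F(1 - alpha; n_val, n_val)` (one-sided ratio test
#' with equal validation degrees of freedom).
#'
#' @param result a [SpaResult-class] from [pressEvaluate()].
#' @param Xcal,ycal,Xval,yval as in [pressEvaluate()].
#' @param alpha significance level (default 0.25).
#' @param grid optional wavelengths (nm).
#' @param minSize smallest admissible pruned subset (default 1; [runSPA()]
#'   passes its `kMin` so phase 3 never undercuts the candidate-size floor).
#' @return A pruned [SpaResult-class]; `selected` is in relevance order.
#' @export
ftestPrune <- function(result, Xcal, ycal, Xval, yval, alpha = 0.25,
                       grid = NULL, minSize = 1L) {
  if (!length(result@selected)) stop("empty SPA subset")
  nval <- length(yval)
  if (nval < 3L) stop("validation set too small for the F-test (n < 3)")
  Xcal <- as.matrix(Xcal); Xval <- as.matrix(Xval)
  ord <- order(result@relevance, decreasing = TRUE)
  ranked <- result@selected[ord]
  fcrit <- qf(1 - alpha, nval, nval)
  pressMin <- result@press
  final <- ranked
  finalPress <- NA_real_
  for (m in seq(min(minSize, length(ranked)), length(ranked))) {
    pr <- olsPress(ranked[seq_len(m)], Xcal, ycal, Xval, yval)
    if (is.na(pr)) next
    if (pr / pressMin <= fcrit) {
      final <- ranked[seq_len(m)]
      finalPress <- pr
      break
    }
  }
  if (is.na(finalPress))
    finalPress <- olsPress(final, Xcal, ycal, Xval, yval)
  wl <- if (is.null(grid)) as.numeric(final) else grid[final]
  new("SpaResult", selected = as.integer(final), wavelengths = wl,
      pressBySize = result@pressBySize, press = finalPress,
      relevance = result@relevance[ord][seq_along(final)],
      chainStart = result@chainStart)
}

#' Run the full three-phase SPA
#'
#' Splits the supplied (training) data into calibration and validation
#' shares, standardizes the calibration bands, grows projection chains
#' (one per starting variable by default), scores chain prefixes by PRESS,
#' and prunes the winner with the relevance-index F-test. The held-out test
#' partition of a study must never be passed here: the validation share is
#' carved out of the training data.
#'
#' @param X training spectra, samples x bands.
#' @param y training response (one analyte).
#' @param kMin,kMax subset-size range (defaults 5 and the band count).
#' @param alpha F-test significance level (default 0.25).
#' @param validationFraction share of the rows reserved for PRESS
#'   (default 0.3).
#' @param seed seed for the calibration/validation split.
#' @param allStarts grow one chain per starting variable (default); when
#'   `FALSE`, only the maximum-variance start is used.
#' @param grid optional wavelengths (nm) mapped onto selected indices.
#' @return A pruned [SpaResult-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(600), 60, 10)
#' y <- 2 * X[, 3] - X[, 8] + rnorm(60, sd = 0.01)
#' runSPA(X, y, kMin = 1, kMax = 4, seed = 1)
#' @export
runSPA <- function(X, y, kMin = 5L, kMax = ncol(X), alpha = 0.25,
                   validationFraction = 0.3, seed = 1L, allStarts = TRUE,
                   grid = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 10L)
  idx <- withSeed(seed, sample.int(n))
  nVal <- max(3L, round(validationFraction * n))
  val <- idx[seq_len(nVal)]
  cal <- idx[-seq_len(nVal)]
  Xcal <- X[cal, , drop = FALSE]; ycal <- y[cal]
  Xval <- X[val, , drop = FALSE]; yval <- y[val]
  kMax <- min(kMax, ncol(X), length(cal) - 2L)
  kMin <- min(kMin, kMax)
  std <- spaStandardize(Xcal)
  starts <- if (allStarts) seq_len(ncol(X)) else
    which.max(apply(Xcal, 2L, var))
  chains <- lapply(starts, function(s) projectionChain(std$Z, s, kMax))
  res <- pressEvaluate(chains, Xcal, ycal, Xval, yval,
                       kMin = kMin, kMax = kMax, grid = grid)
  ftestPrune(res, Xcal, ycal, Xval, yval, alpha = alpha, grid = grid,
             minSize = kMin)
}

#' Serialize an SPA result to JSON
#'
#' @param result a [SpaResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpaResult <- function(result, path) {
  jsonlite::write_json(list(
    selected_indices = result@selected,
    wavelengths_nm = result@wavelengths,
    press = result@press,
    press_by_size = as.list(result@pressBySize),
    relevance = result@relevance
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
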