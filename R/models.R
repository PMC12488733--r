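# Public model API: architecture plans with parameter accounting, training
# schedules, Adam training with seeded reproducibility, and prediction.
#
# The three architectures ingest a spectrum reshaped to [n x 1 x 1]:
#   cnn                 conv(8,3x1)-BN-ReLU-pool(2x1) -> conv(32,3x1)-BN-ReLU-
#                       pool(2x1) -> dropout(0.4) -> dense(32) -> dense(1)
#   cnn_bigru           parallel CNN branch (conv 16,3x1 + BN + ReLU +
#                       pool(3x1) + dense 25) and BiGRU branch (two GRU
#                       layers, 35 hidden units, one on the band sequence and
#                       one on its flip; final states concatenated -> 70),
#                       merged (95 features) -> regression output
#   cnn_bigru_attention cnn_bigru + single-head dot-product self-attention
#                       (key/query dimension 50) over the 95 concatenated
#                       features, before the output layer
# Convolutions use same-padding; pooling uses stride = window with floor
# semantics, so flatten widths are reproducible from n alone.

.modelKinds <- c("cnn", "cnn_bigru", "cnn_bigru_attention")

#' Build a fully dimensioned architecture plan
#'
#' @param kind `"cnn"`, `"cnn_bigru"` or `"cnn_bigru_attention"`.
#' @param nBands input spectrum length n.
#' @return A [ModelSpec-class] with a per-layer plan and the total trainable
#'   parameter count (conv: `3*in*out + out`; dense: `in*out + out`; batch
#'   norm: `2*channels`; GRU: `3*(in*h + h*h + h)` per direction; attention:
#'   `4*50` for query/key weights and biases).
#' @examples
#' buildModelSpec("cnn", 5)    # SPA-subset input
#' buildModelSpec("cnn_bigru_attention", 360)
#' @export
buildModelSpec <- function(kind = .modelKinds, nBands) {
  kind <- match.arg(kind)
  nBands <- as.integer(nBands)
  minN <- if (kind == "cnn") 4L else 3L
  if (nBands < minN)
    stop(sprintf("%s needs at least %d bands (pooling would collapse the axis); got %d",
                 kind, minN, nBands))
  layer <- function(type, shape, nParams)
    list(type = type, shape = shape, nParams = as.integer(nParams))
  if (kind == "cnn") {
    L1 <- nBands %/% 2L
    L2 <- L1 %/% 2L
    layers <- list(
      layer("input", sprintf("[%d x 1 x 1]", nBands), 0),
      layer("conv 3x1, 8 filters", sprintf("[%d x 1 x 8]", nBands), 3 * 1 * 8 + 8),
      layer("batch norm", "8 channels", 2 * 8),
      layer("relu + maxpool 2x1", sprintf("[%d x 1 x 8]", L1), 0),
      layer("conv 3x1, 32 filters", sprintf("[%d x 1 x 32]", L1), 3 * 8 * 32 + 32),
      layer("batch norm", "32 channels", 2 * 32),
      layer("relu + maxpool 2x1", sprintf("[%d x 1 x 32]", L2), 0),
      layer("dropout 0.4", sprintf("[%d x 1 x 32]", L2), 0),
      layer("dense 32", sprintf("%d -> 32", L2 * 32), L2 * 32 * 32 + 32),
      layer("dense 1 (regression)", "32 -> 1", 32 + 1))
  } else {
    Lc <- nBands %/% 3L
    layers <- list(
      layer("input", sprintf("[%d x 1 x 1]", nBands), 0),
      layer("conv 3x1, 16 filters", sprintf("[%d x 1 x 16]", nBands), 3 * 1 * 16 + 16),
      layer("batch norm", "16 channels", 2 * 16),
      layer("relu + maxpool 3x1", sprintf("[%d x 1 x 16]", Lc), 0),
      layer("dense 25 (CNN branch)", sprintf("%d -> 25", Lc * 16), Lc * 16 * 25 + 25),
      layer("GRU 35 (forward)", sprintf("%d steps -> 35", nBands), 3 * (35 + 35 * 35 + 35)),
      layer("GRU 35 (flipped)", sprintf("%d steps -> 35", nBands), 3 * (35 + 35 * 35 + 35)),
      layer("concat", "25 + 70 -> 95", 0))
    if (kind == "cnn_bigru_attention")
      layers <- c(layers, list(
        layer("self-attention (dk=50)", "95 tokens", 4 * 50)))
    layers <- c(layers, list(layer("dense 1 (regression)", "95 -> 1", 95 + 1)))
  }
  new("ModelSpec", kind = kind, nBands = nBands, layers = layers,
      nParams = sum(vapply(layers, `[[`, 0L, "nParams")))
}

#' Default training schedule for an architecture family
#'
#' The CNN trains for 500 epochs at learning rate 0.001 with an L2 factor of
#' 0.01; the hybrids train for 1000 epochs starting at 0.01 with a single
#' x0.1 decay applied after `lrDecayEpoch` (default 700, inside the 600-800
#' window).
#'
#' @param kind architecture family.
#' @param epochs,initialLr,l2,lrDecayFactor,lrDecayEpoch,batchSize,seed
#'   overrides of the family defaults.
#' @param dropout dropout rate of the CNN plan's dropout layer (default 0.4;
#'   ignored by the hybrids, whose plans have no dropout layer).
#' @param scaleInputs standardize inputs per band on training data
#'   (default TRUE).
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(kind = .modelKinds, epochs = NULL, initialLr = NULL,
                        l2 = NULL, lrDecayFactor = NULL, lrDecayEpoch = NULL,
                        batchSize = 16L, seed = 1L, dropout = 0.4,
                        scaleInputs = TRUE) {
  kind <- match.arg(kind)
  cnn <- kind == "cnn"
  if (!is.null(lrDecayEpoch) && !cnn &&
      lrDecayEpoch != 0L && (lrDecayEpoch < 600L || lrDecayEpoch > 800L))
    warning("hybrid decay epoch outside the standard 600-800 window")
  new("TrainConfig", kind = kind,
      epochs = as.integer(epochs %||% if (cnn) 500L else 1000L),
      initialLr = initialLr %||% if (cnn) 0.001 else 0.01,
      l2 = l2 %||% if (cnn) 0.01 else 0,
      lrDecayFactor = lrDecayFactor %||% if (cnn) 1 else 0.1,
      lrDecayEpoch = as.integer(lrDecayEpoch %||% if (cnn) 0L else 700L),
      batchSize = as.integer(batchSize), seed = as.integer(seed),
      dropout = dropout, scaleInputs = isTRUE(scaleInputs))
}

#' Per-epoch learning rates implied by a schedule
#'
#' @param cfg a [TrainConfig-class].
#' @return numeric vector of length `cfg@epochs`.
#' @export
learningRateSchedule <- function(cfg) {
  ep <- seq_len(cfg@epochs)
  lr <- rep(cfg@initialLr, cfg@epochs)
  if (cfg@lrDecayEpoch > 0L)
    lr[ep > cfg@lrDecayEpoch] <- cfg@initialLr * cfg@lrDecayFactor
  lr
}

#' Train a regression network
#'
#' Minimizes mean squared error with Adam under the schedule in `cfg`.
#' Inputs are standardized per band and the response is centered/scaled, all
#' on the training data only; both transforms are frozen into the model.
#' A fixed seed makes initialization, shuffling and dropout — and therefore
#' the weights — bit-reproducible on one machine.
#'
#' @param spec a [ModelSpec-class] (its `nBands` must equal `ncol(X)`).
#' @param cfg a [TrainConfig-class].
#' @param X training spectra, samples x bands.
#' @param y training response (one analyte).
#' @return A [TrainedModel-class].
#' @examples
#' set.seed(3)
#' X <- matrix(runif(200), 40, 5)
#' y <- 3 * X[, 2] + rnorm(40, sd = 0.01)
#' m <- trainModel(buildModelSpec("cnn", 5), trainConfig("cnn", epochs = 50),
#'                 X, y)
#' cor(predict(m, X), y)
#' @export
trainModel <- function(spec, cfg, X, y) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == spec@nBands, nrow(X) == length(y))
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite training inputs")
  n <- nrow(X)
  xc <- colMeans(X)
  xs <- apply(X, 2L, sd); xs[xs == 0 | !is.finite(xs)] <- 1
  if (!cfg@scaleInputs) { xc <- rep(0, ncol(X)); xs <- rep(1, ncol(X)) }
  Xs <- sweep(sweep(X, 2L, xc), 2L, xs, "/")
  yc <- mean(y); ys <- sd(y); if (!is.finite(ys) || ys == 0) ys <- 1
  yn <- (y - yc) / ys
  lrs <- learningRateSchedule(cfg)
  withSeed(cfg@seed, {
    ini <- initParams(spec@kind, spec@nBands)
    params <- ini$params
    bn <- ini$bn
    opt <- adamInit(params)
    lossCurve <- numeric(cfg@epochs)
    for (ep in seq_len(cfg@epochs)) {
      ord <- sample.int(n)
      lr <- lrs[ep]
      tot <- 0
      nb <- 0L
      for (b0 in seq(1L, n, by = cfg@batchSize)) {
        ix <- ord[b0:min(n, b0 + cfg@batchSize - 1L)]
        out <- networkPass(spec@kind, params, bn,
                           Xs[ix, , drop = FALSE], yn[ix], training = TRUE,
                           dropout = cfg@dropout)
        if (!is.finite(out$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
        bn <- out$bn
        grads <- addDecay(out$grads, params, spec@kind, cfg@l2)
        grads <- grads[names(params)]
        st <- adamStep(params, grads, opt, lr)
        params <- st$params
        opt <- st$state
        tot <- tot + out$loss
        nb <- nb + 1L
      }
      lossCurve[ep] <- tot / nb
    }
    new("TrainedModel", spec = spec, config = cfg, params = params,
        bnStats = bn, xCenter = xc, xScale = xs, yCenter = yc, yScale = ys,
        lossCurve = lossCurve, lrCurve = lrs)
  })
}

#' Predict from a trained network
#'
#' Deterministic inference: dropout is disabled and batch normalization uses
#' the frozen running statistics, so repeated calls are bit-identical.
#'
#' @param object a [TrainedModel-class].
#' @param newdata samples x bands matrix on the model's band grid.
#' @param ... ignored.
#' @return numeric predictions, one per row, in analyte units.
#' @export
setMethod("predict", "TrainedModel", function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object@spec@nBands)
    stop(sprintf("model expects %d bands, got %d",
                 object@spec@nBands, ncol(X)))
  Xs <- sweep(sweep(X, 2L, object@xCenter), 2L, object@xScale, "/")
  out <- networkPass(object@spec@kind, object@params, object@bnStats, Xs,
                     training = FALSE)
  as.numeric(out$pred) * object@yScale + object@yCenter
})

#' Write a training log as CSV (epoch, lr, loss)
#'
#' @param model a [TrainedModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrainingLog <- function(model, path) {
  write.csv(data.frame(epoch = seq_along(model@lossCurve),
                       lr = model@lrCurve, loss = model@lossCurve),
            path, row.names = FALSE)
  invisible(path)
}
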