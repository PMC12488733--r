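# End-to-end orchestration: ingest (or simulate) -> preprocess (RAW or SG)
# -> select (full spectrum or SPA) -> train -> evaluate on the internal test
# split and, optionally, on a frozen external set. The test partition and
# the external set never influence standardization, SPA or training.

#' Assemble a pipeline run configuration
#'
#' @param data a [SpectralSet-class] (training-year data).
#' @param analyte `"vc"`, `"ssc"` or `"sp"`.
#' @param preprocessing `"RAW"` or `"SG"`.
#' @param selection `"full"` (all bands) or `"SPA"`.
#' @param model architecture kind (see [buildModelSpec()]).
#' @param splitSeed seed of the 7:3 partition.
#' @param external optional [SpectralSet-class] evaluated with the frozen
#'   model (no refit) — the cross-year protocol.
#' @param sg list of Savitzky-Golay settings (`window`, `order`).
#' @param spa list of SPA settings (`kMin`, `kMax`, `alpha`,
#'   `validationFraction`, `seed`, `allStarts`).
#' @param train list of training overrides passed to [trainConfig()]
#'   (e.g. `epochs`, `seed`).
#' @param outDir optional output directory; when given, [runPipeline()]
#'   writes metrics, SPA result, checkpoint, loss curve and provenance there.
#' @return A `RunConfig` list (class `"fruithsi_run_config"`).
#' @export
runConfig <- function(data, analyte = c("vc", "ssc", "sp"),
                      preprocessing = c("RAW", "SG"),
                      selection = c("full", "SPA"),
                      model = c("cnn_bigru_attention", "cnn", "cnn_bigru"),
                      splitSeed = 1L, external = NULL,
                      sg = list(window = 11L, order = 2L),
                      spa = list(kMin = 5L, kMax = 25L, alpha = 0.25,
                                 validationFraction = 0.3, seed = 1L,
                                 allStarts = TRUE),
                      train = list(), outDir = NULL) {
  structure(list(
    data = data, analyte = match.arg(analyte),
    preprocessing = match.arg(preprocessing),
    selection = match.arg(selection), model = match.arg(model),
    splitSeed = as.integer(splitSeed), external = external, sg = sg,
    spa = spa, train = train, outDir = outDir),
    class = "fruithsi_run_config")
}

#' Run the end-to-end pipeline
#'
#' Splits the data 7:3, applies the configured preprocessing, performs SPA
#' band selection on the training partition only (when requested), trains
#' the configured network on the training partition, and evaluates on the
#' internal test partition and any external set with the frozen model.
#'
#' @param config a [runConfig()] object.
#' @return list with `split`, `bands` (selected indices), `spa`
#'   ([SpaResult-class] or NULL), `model` ([TrainedModel-class]), `metrics`
#'   (named list of [MetricsReport-class]: `train`, `test`, optionally
#'   `external`), `degradation` (when an external set is present) and
#'   `predictions`.
#' @examples
#' g <- wavelengthGrid(60)
#' ds <- generateDataset(40, g, opticalModel(g), seed = 1)
#' cfg <- runConfig(ds, analyte = "ssc", selection = "SPA", model = "cnn",
#'                  spa = list(kMin = 2, kMax = 6), train = list(epochs = 30))
#' res <- runPipeline(cfg)
#' res$metrics$test
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "fruithsi_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  ds <- config$data
  X <- stage("ingest", spectra(ds))
  y <- stage("ingest", analytes(ds)[[config$analyte]])
  wl <- wavelengths(ds)
  if (is.null(y)) stop("analyte '", config$analyte, "' not found in data")

  split <- stage("split", splitTrainTest(nrow(X), seed = config$splitSeed))

  if (config$preprocessing == "SG")
    X <- stage("preprocess",
               sgSmooth(X, window = config$sg$window %||% 11L,
                        order = config$sg$order %||% 2L))

  Xtr <- X[split@train, , drop = FALSE]; ytr <- y[split@train]
  Xte <- X[split@test, , drop = FALSE]; yte <- y[split@test]

  spaRes <- NULL
  bands <- seq_len(ncol(X))
  if (config$selection == "SPA") {
    sp <- config$spa
    spaRes <- stage("select", runSPA(
      Xtr, ytr, kMin = sp$kMin %||% 5L, kMax = sp$kMax %||% ncol(X),
      alpha = sp$alpha %||% 0.25,
      validationFraction = sp$validationFraction %||% 0.3,
      seed = sp$seed %||% 1L, allStarts = sp$allStarts %||% TRUE,
      grid = wl))
    bands <- sort(spaRes@selected)
  }

  spec <- stage("build", buildModelSpec(config$model, length(bands)))
  tcfg <- stage("build", do.call(trainConfig,
                                 c(list(kind = config$model), config$train)))
  model <- stage("train",
                 trainModel(spec, tcfg, Xtr[, bands, drop = FALSE], ytr))

  predTr <- stage("evaluate", predict(model, Xtr[, bands, drop = FALSE]))
  predTe <- stage("evaluate", predict(model, Xte[, bands, drop = FALSE]))
  metrics <- list(train = metricsReport(ytr, predTr),
                  test = metricsReport(yte, predTe))
  predictions <- list(train = predTr, test = predTe)
  degr <- NULL
  if (!is.null(config$external)) {
    Xe <- spectra(config$external)
    if (config$preprocessing == "SG")
      Xe <- sgSmooth(Xe, window = config$sg$window %||% 11L,
                     order = config$sg$order %||% 2L)
    ye <- analytes(config$external)[[config$analyte]]
    predEx <- stage("external", predict(model, Xe[, bands, drop = FALSE]))
    metrics$external <- metricsReport(ye, predEx)
    predictions$external <- predEx
    degr <- list(
      r2 = degradation(metrics$test@r2, metrics$external@r2),
      rpd = degradation(metrics$test@rpd, metrics$external@rpd))
  }
  result <- list(split = split, bands = bands, spa = spaRes, model = model,
                 metrics = metrics, degradation = degr,
                 predictions = predictions, config = config)
  if (!is.null(config$outDir)) writeRunArtifacts(result, config$outDir)
  result
}

# Persist metrics/SPA/checkpoint/loss-curve/provenance for a finished run.
writeRunArtifacts <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeMetrics(result$metrics, file.path(outDir, "metrics.csv"))
  writeMetrics(result$metrics, file.path(outDir, "metrics.json"))
  if (!is.null(result$spa))
    writeSpaResult(result$spa, file.path(outDir, "spa.json"))
  writeTrainingLog(result$model, file.path(outDir, "training_log.csv"))
  saveRDS(result$model, file.path(outDir, "checkpoint.rds"))
  cfg <- result$config
  jsonlite::write_json(list(
    analyte = cfg$analyte, preprocessing = cfg$preprocessing,
    selection = cfg$selection, model = cfg$model,
    split_seed = cfg$splitSeed, train_seed = result$model@config@seed,
    bands = result$bands,
    package_version = as.character(utils::packageVersion("fruithsi")),
    r_version = R.version.string
  ), file.path(outDir, "provenance.json"), auto_unbox = TRUE)
  invisible(outDir)
}

#' Run the 3-model x 4-input comparison grid
#'
#' Evaluates every architecture under the four spectral input
#' configurations (RAW, SG, SPA+RAW, SPA+SG) for one analyte and returns a
#' 12-row comparison table.
#'
#' @inheritParams runConfig
#' @param ... further arguments forwarded to [runConfig()] (e.g. `spa`,
#'   `train`, `splitSeed`).
#' @return data.frame with model, preprocessing, selection, nBands and the
#'   test-set metrics.
#' @export
runComparisonGrid <- function(data, analyte, ...) {
  rows <- list()
  for (model in .modelKinds)
    for (pp in c("RAW", "SG"))
      for (sel in c("full", "SPA")) {
        res <- runPipeline(runConfig(data, analyte = analyte,
                                     preprocessing = pp, selection = sel,
                                     model = model, ...))
        m <- res$metrics$test
        rows[[length(rows) + 1L]] <- data.frame(
          analyte = analyte, model = model,
          input = if (sel == "SPA") paste0("SPA+", pp) else pp,
          nBands = length(res$bands), r2 = m@r2, rmse = m@rmse, rpd = m@rpd,
          band = m@band)
      }
  do.call(rbind, rows)
}
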