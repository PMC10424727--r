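# End-to-end runs tying the tracks together: data (synthetic or on-disk),
# split, train, evaluate, profile; every artifact lands in the run
# directory together with the config and its hash.

validTracks <- list(
  poincare = c("densenet121", "resnet50"),
  raw1d = c("resnet1d", "cnn1d"),
  features = "xgboost")

#' Default run configuration
#'
#' @param track \code{"raw1d"}, \code{"poincare"} or \code{"features"}.
#' @param model Model name valid for the track.
#' @param seed Master seed (split, init, training, tuning).
#' @param outDir Output directory.
#' @param ... Overrides merged into the config list.
#' @return A validated config list.
#' @export
pipelineConfig <- function(track = "raw1d", model = "resnet1d", seed = 1L,
                           outDir = tempfile("run"), ...) {
  cfg <- list(
    track = track, model = model, seed = as.integer(seed), outDir = outDir,
    synth = list(classes = c(sinus = 150, af = 150, tachy = 150,
                             brady = 150),
                 dialect = "synthetic", durationS = 10, noiseSd = 0.05),
    dataDir = NULL, dialect = "synthetic", stratify = FALSE,
    epochs = 12L, batchSize = 32L, lr = 1e-3, patience = 5L,
    baseWidth = 16L, widthMult = 0.25, inputSize = 64L,
    nTrials = 15L, profileN = 10L, carbonIntensity = 0.4, cpuPowerW = 65)
  over <- list(...)
  cfg[names(over)] <- over
  validateConfig(cfg)
  cfg
}

validateConfig <- function(cfg) {
  errs <- character()
  if (!cfg$track %in% names(validTracks))
    errs <- c(errs, paste0("unknown track: ", cfg$track))
  else if (!cfg$model %in% validTracks[[cfg$track]])
    errs <- c(errs, paste0("model '", cfg$model, "' is not valid for track '",
                           cfg$track, "'"))
  if (is.null(cfg$synth) && is.null(cfg$dataDir))
    errs <- c(errs, "either synth or dataDir must be given")
  if (!is.null(cfg$dataDir) && !dir.exists(cfg$dataDir))
    errs <- c(errs, paste0("dataDir does not exist: ", cfg$dataDir))
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  invisible(TRUE)
}

#' Read every WFDB-dialect record in a directory
#' @param dir Directory holding \code{.hea}/\code{.dat} pairs.
#' @param dialect Passed to [readRecord()].
#' @return List of \linkS4class{EcgRecord}.
#' @export
loadDataset <- function(dir, dialect = "synthetic") {
  heas <- sort(list.files(dir, pattern = "\\.hea$", full.names = TRUE))
  lapply(heas, readRecord, dialect = dialect)
}

configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run one full pipeline
#'
#' Generates (or loads) the dataset, draws the 60/20/20 split, trains the
#' track's model, evaluates it on the held-out test set, profiles
#' inference, and writes all artifacts (split manifest, model description,
#' evaluation and efficiency reports, training history, config with hash)
#' into the run directory. Re-running with an identical config and seed
#' reproduces the split manifest and the test decisions exactly.
#'
#' @param config From [pipelineConfig()].
#' @param verbose Print progress.
#' @return List with the trained model/fit, reports, split and artifact
#'   paths.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  validateConfig(config)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$dataDir)) {
    records <- loadDataset(config$dataDir, config$dialect)
  } else {
    ds <- simulateDataset(config$synth$classes,
                          dialect = config$synth$dialect,
                          seed = config$seed,
                          durationS = config$synth$durationS,
                          noiseSd = config$synth$noiseSd)
    records <- ds$records
  }
  ids <- vapply(records, recordId, character(1))
  labs <- lapply(records, recordLabels)
  firstLab <- vapply(labs, function(l) l[1], character(1))
  split <- makeSplit(ids, seed = config$seed,
                     strata = if (isTRUE(config$stratify)) firstLab)
  manifest <- file.path(config$outDir, "split.json")
  writeSplitManifest(split, manifest)
  byId <- stats::setNames(records, ids)
  trainRec <- byId[split@trainIds]
  valRec <- byId[split@valIds]
  testRec <- byId[split@testIds]
  classes <- sort(unique(firstLab))
  scheme <- new("LabelScheme", mode = "multiclass", classes = classes,
                codeMap = stats::setNames(classes, classes))
  testTruth <- firstLab[match(split@testIds, ids)]

  if (config$track == "features") {
    featAll <- extractFeatures(records)
    trIx <- match(c(split@trainIds, split@valIds), ids)
    teIx <- match(split@testIds, ids)
    featTr <- imputeAndFilter(featAll[trIx, , drop = FALSE])
    cols <- attr(featTr, "retainedColumns")
    featTe <- imputeAndFilter(featAll[teIx, , drop = FALSE],
                              columns = cols)
    fit <- tuneAndFit(featTr, firstLab[trIx], nTrials = config$nTrials,
                      seed = config$seed)
    utils::write.csv(fit$trials,
                     file.path(config$outDir, "trials.csv"),
                     row.names = FALSE)
    jsonlite::write_json(fit$params,
                         file.path(config$outDir, "best_config.json"),
                         auto_unbox = TRUE, digits = NA)
    pred <- predictTsBoost(fit, featTe)$decisions
    procFun <- function(rec) imputeAndFilter(extractFeatures(list(rec)),
                                             columns = cols)
    predFun <- function(tab) predictTsBoost(fit, tab)$decisions
    modelOut <- fit
  } else {
    model <- switch(config$model,
      resnet1d = buildResnet1d(length(classes), nLeads = 1L,
                               inputLen = round(config$synth$durationS * 300) - 1L,
                               baseWidth = config$baseWidth,
                               classes = classes, seed = config$seed),
      cnn1d = buildCnn1d(length(classes), nLeads = 1L,
                         inputLen = max(round(config$synth$durationS * 300) - 1L,
                                        cnn1dMinLen()),
                         widthMult = config$widthMult,
                         classes = classes, seed = config$seed),
      buildImage2d(config$model, length(classes),
                   inputSize = config$inputSize,
                   widthMult = config$widthMult, classes = classes,
                   seed = config$seed))
    toInput <- if (config$track == "poincare") {
      function(rec) recordToPoincare(rec, size = config$inputSize)
    } else identity
    prep <- function(recs) lapply(recs, toInput)
    trIn <- prep(trainRec)
    vaIn <- prep(valRec)
    teIn <- prep(testRec)
    model <- trainModel(model, trIn, vaIn,
                        trainLabels = lapply(trainRec, recordLabels),
                        valLabels = lapply(valRec, recordLabels),
                        epochs = config$epochs, batchSize = config$batchSize,
                        lr = config$lr, patience = config$patience,
                        seed = config$seed, verbose = verbose)
    writeModelDescription(model,
                          file.path(config$outDir, "model_description.json"))
    saveModelWeights(model, file.path(config$outDir, "weights.rds"))
    utils::write.csv(model@history,
                     file.path(config$outDir, "history.csv"),
                     row.names = FALSE)
    pred <- predictModel(model, teIn)$decisions
    procFun <- function(rec) prepareInputs(model, list(toInput(rec)))
    predFun <- function(x) scoresToDecisions(model, forwardScores(model, x))
    modelOut <- model
  }

  evalRep <- computeMetrics(testTruth, pred, scheme)
  evalRep@perSource <- perSourceReport(testRec, testTruth, pred, scheme)
  profRec <- testRec[seq_len(min(config$profileN, length(testRec)))]
  effRep <- profilePipeline(procFun, predFun, profRec,
                            carbonIntensity = config$carbonIntensity,
                            cpuPowerW = config$cpuPowerW)
  writeReports(file.path(config$outDir, "report.json"), evalRep, effRep)
  cfgOut <- config
  cfgOut$hash <- configHash(config)
  cfgOut$classes <- classes
  jsonlite::write_json(cfgOut, file.path(config$outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(id = split@testIds, truth = testTruth,
                              predicted = vapply(pred, paste,
                                                 collapse = ",",
                                                 character(1))),
                   file.path(config$outDir, "test_decisions.csv"),
                   row.names = FALSE)
  list(model = modelOut, eval = evalRep, efficiency = effRep,
       split = split, outDir = config$outDir)
}

#' Merge completed runs into a comparison table and cross-plot
#'
#' @param runDirs Character vector of run directories.
#' @param plotPath Optional PNG path for the F1-vs-CO2 cross-plot (x axis:
#'   grams CO2, y axis: test macro-F1); coordinates are also written as
#'   JSON next to it.
#' @return Data frame, one row per run, sorted by test macro-F1.
#' @export
reportRuns <- function(runDirs, plotPath = NULL) {
  rows <- lapply(runDirs, function(d) {
    rep_ <- jsonlite::read_json(file.path(d, "report.json"),
                                simplifyVector = TRUE)
    cfg <- jsonlite::read_json(file.path(d, "config.json"),
                               simplifyVector = TRUE)
    data.frame(run = basename(d), track = cfg$track, model = cfg$model,
               classes = paste(cfg$classes, collapse = ","),
               f1 = rep_$metrics$macro$f1,
               sensitivity = rep_$metrics$macro$sensitivity,
               specificity = rep_$metrics$macro$specificity,
               energy_wh = rep_$efficiency$energy_wh,
               co2_g = rep_$efficiency$co2_g,
               time_total_ms = rep_$efficiency$time_total_ms)
  })
  tab <- do.call(rbind, rows)
  if (length(unique(tab$classes)) > 1)
    stop("runs use different label schemes and cannot be merged")
  tab <- tab[order(-tab$f1), ]
  rownames(tab) <- NULL
  if (!is.null(plotPath)) {
    crossPlot(tab$co2_g, tab$f1, tab$model, plotPath)
    jsonlite::write_json(
      list(x_axis = "co2_g", y_axis = "test_f1",
           points = data.frame(model = tab$model, x = tab$co2_g,
                               y = tab$f1)),
      paste0(plotPath, ".json"), auto_unbox = TRUE, digits = NA)
  }
  tab
}

# minimal device-free scatter rendering (white canvas, dark markers)
crossPlot <- function(x, y, labels, path, size = 400L) {
  img <- array(1, c(size, size, 3))
  img[size - 39L, 40:(size - 10), ] <- 0      # x axis
  img[10:(size - 40L), 40L, ] <- 0            # y axis
  xr <- range(x); if (diff(xr) == 0) xr <- xr + c(-1, 1)
  yr <- range(y); if (diff(yr) == 0) yr <- yr + c(-0.1, 0.1)
  px <- 40L + round((x - xr[1]) / diff(xr) * (size - 60L))
  py <- (size - 40L) - round((y - yr[1]) / diff(yr) * (size - 60L))
  for (k in seq_along(x)) {
    rows <- pmax(pmin(py[k] + (-3:3), size), 1)
    cols <- pmax(pmin(px[k] + (-3:3), size), 1)
    img[rows, cols, 1] <- 0.8
    img[rows, cols, 2] <- 0.1
    img[rows, cols, 3] <- 0.1
  }
  png::writePNG(img, path)
  invisible(path)
}
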