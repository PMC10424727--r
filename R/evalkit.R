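# Metrics and the efficiency harness. "Average" means macro (unweighted
# per-class) averaging; micro aggregation is available via `micro = TRUE`.
# Zero-division convention (needed for rare classes under heavy imbalance):
# a metric with a zero denominator is 1 when the class never occurs and is
# never predicted (nothing to get wrong), and 0 otherwise.

#' One-vs-rest confusion counts
#'
#' @param truth,predicted Character vectors (multiclass) or lists of
#'   character vectors (multilabel), aligned by record.
#' @param classes Class identifiers to count over.
#' @return Data frame with one row per class: tp, fp, tn, fn.
#' @export
confusionCounts <- function(truth, predicted, classes) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length")
  n <- length(truth)
  asSet <- function(x, i) if (is.list(x)) x[[i]] else x[i]
  out <- data.frame(class = classes, tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (i in seq_len(n)) {
    tset <- asSet(truth, i)
    pset <- asSet(predicted, i)
    inT <- classes %in% tset
    inP <- classes %in% pset
    out$tp <- out$tp + (inT & inP)
    out$fp <- out$fp + (!inT & inP)
    out$fn <- out$fn + (inT & !inP)
    out$tn <- out$tn + (!inT & !inP)
  }
  out
}

safeDiv <- function(num, den, tp, fp, fn) {
  ifelse(den > 0, num / den, ifelse(tp + fp + fn == 0, 1, 0))
}

#' Classification metrics (per class and macro-averaged)
#'
#' Precision = TP/(TP+FP), recall/sensitivity = TP/(TP+FN), specificity =
#' TN/(FP+TN), F1 = the harmonic mean of precision and recall; classes are
#' scored one-vs-rest and averaged without weighting.
#'
#' @param truth,predicted Aligned label vectors (multiclass) or label-set
#'   lists (multilabel).
#' @param scheme A \linkS4class{LabelScheme} fixing the class set.
#' @param micro Also compute micro-averaged (pooled-count) metrics.
#' @return An \linkS4class{EvalReport}.
#' @export
computeMetrics <- function(truth, predicted, scheme, micro = FALSE) {
  cc <- confusionCounts(truth, predicted, scheme@classes)
  prec <- safeDiv(cc$tp, cc$tp + cc$fp, cc$tp, cc$fp, cc$fn)
  rec <- safeDiv(cc$tp, cc$tp + cc$fn, cc$tp, cc$fp, cc$fn)
  spec <- safeDiv(cc$tn, cc$fp + cc$tn, cc$tp, cc$fp, cc$fn)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec),
               ifelse(cc$tp + cc$fp + cc$fn == 0, 1, 0))
  perClass <- data.frame(precision = prec, recall = rec, sensitivity = rec,
                         specificity = spec, f1 = f1, tp = cc$tp,
                         fp = cc$fp, tn = cc$tn, fn = cc$fn,
                         row.names = scheme@classes)
  macro <- c(f1 = mean(f1), sensitivity = mean(rec),
             specificity = mean(spec), precision = mean(prec))
  if (micro) {
    TP <- sum(cc$tp); FP <- sum(cc$fp); TN <- sum(cc$tn); FN <- sum(cc$fn)
    mprec <- if (TP + FP > 0) TP / (TP + FP) else 0
    mrec <- if (TP + FN > 0) TP / (TP + FN) else 0
    macro <- c(macro,
               micro_f1 = if (mprec + mrec > 0)
                 2 * mprec * mrec / (mprec + mrec) else 0,
               micro_sensitivity = mrec,
               micro_specificity = if (FP + TN > 0) TN / (FP + TN) else 0)
  }
  new("EvalReport", perClass = perClass, macro = macro)
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by (first) label -- under heavy class imbalance
#' unstratified folds can lose a class entirely. Fold-wise macro metrics
#' are summarized by their mean and population SD (divisor k).
#'
#' @param records List of labelled inputs.
#' @param modelFactory \code{function(trainRecords, trainLabels)} returning
#'   a prediction function \code{function(newRecords) -> decisions}.
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param scheme A \linkS4class{LabelScheme}.
#' @param labels Optional label list; defaults to the records' labels.
#' @return An \linkS4class{EvalReport} whose \code{cv} slot holds fold-wise
#'   metrics plus their mean and SD.
#' @export
crossValidate <- function(records, modelFactory, k = 5L, seed = 1L,
                          scheme, labels = NULL) {
  if (is.null(labels)) labels <- recordLabelList(records)
  n <- length(records)
  if (k < 2 || n < k) stop("need k >= 2 and at least k records")
  first <- vapply(labels, function(l) l[1], character(1))
  fold <- integer(n)
  withSeed(as.integer(seed), {
    for (cl in unique(first)) {
      ix <- sample(which(first == cl))
      fold[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  foldRows <- list()
  missedClasses <- character()
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    va <- which(fold == f)
    trCls <- unique(unlist(labels[tr]))
    gone <- setdiff(scheme@classes, trCls)
    if (length(gone)) missedClasses <- union(missedClasses, gone)
    predictor <- modelFactory(records[tr], labels[tr])
    pred <- predictor(records[va])
    truth <- if (scheme@mode == "multiclass") first[va] else labels[va]
    rep_ <- computeMetrics(truth, pred, scheme)
    foldRows[[f]] <- data.frame(fold = f, t(rep_@macro))
  }
  if (length(missedClasses))
    warning("class(es) missing from at least one training fold: ",
            paste(missedClasses, collapse = ", "))
  folds <- do.call(rbind, foldRows)
  mcols <- setdiff(names(folds), "fold")
  popSD <- function(v) sqrt(mean((v - mean(v))^2))
  cv <- list(folds = folds,
             mean = vapply(folds[mcols], mean, 1),
             sd = vapply(folds[mcols], popSD, 1),
             fold_assignment = fold)
  macro <- cv$mean
  new("EvalReport", perClass = data.frame(), macro = macro, cv = cv)
}

#' Per-source performance breakdown
#'
#' Macro-F1 per source tag, plus the mean signal length per source (the
#' l-bar column of a per-source table).
#'
#' @param records List of \linkS4class{EcgRecord}.
#' @param truth,predicted Aligned labels and decisions.
#' @param scheme A \linkS4class{LabelScheme}.
#' @return Data frame keyed by source with n, mean_length_s and f1.
#' @export
perSourceReport <- function(records, truth, predicted, scheme) {
  src <- vapply(records, recordSource, character(1))
  lens <- vapply(records, durationS, 1)
  rows <- lapply(unique(src), function(s) {
    ix <- which(src == s)
    sub <- computeMetrics(
      if (is.list(truth)) truth[ix] else truth[ix],
      if (is.list(predicted)) predicted[ix] else predicted[ix], scheme)
    data.frame(source = s, n = length(ix),
               mean_length_s = mean(lens[ix]),
               f1 = unname(sub@macro["f1"]))
  })
  do.call(rbind, rows)
}

#' Profile a two-phase inference pipeline
#'
#' Times the pre-processing phase and the prediction phase separately per
#' record and reports the averages, together with an energy estimate.
#' Hardware power counters are not read; energy is a documented TDP-share
#' estimate, \code{cpuPowerW x elapsed hours}, flagged as such in the
#' report, and CO2 grams are energy x carbon intensity.
#'
#' @param processFun \code{function(record)} -> model-ready input.
#' @param predictFun \code{function(processed)} -> prediction.
#' @param records List of records to profile.
#' @param carbonIntensity Grams CO2 per watt-hour (default 0.4, a typical
#'   grid-average figure).
#' @param cpuPowerW Assumed CPU package power draw in watts.
#' @return An \linkS4class{EfficiencyReport}.
#' @export
profilePipeline <- function(processFun, predictFun, records,
                            carbonIntensity = 0.4, cpuPowerW = 65) {
  n <- length(records)
  tProc <- numeric(n)
  tPred <- numeric(n)
  for (i in seq_len(n)) {
    t0 <- proc.time()[["elapsed"]]
    processed <- processFun(records[[i]])
    t1 <- proc.time()[["elapsed"]]
    predictFun(processed)
    t2 <- proc.time()[["elapsed"]]
    tProc[i] <- t1 - t0
    tPred[i] <- t2 - t1
  }
  totalS <- sum(tProc) + sum(tPred)
  energyWh <- cpuPowerW * totalS / 3600
  new("EfficiencyReport",
      energyWh = energyWh, co2G = energyWh * carbonIntensity,
      timeProcessingMs = mean(tProc) * 1000,
      timePredictingMs = mean(tPred) * 1000,
      timeTotalMs = mean(tProc) * 1000 + mean(tPred) * 1000,
      estimator = TRUE, nRecords = n)
}

#' Serialize reports to JSON
#' @param evalReport,efficiencyReport Report objects (either may be NULL).
#' @param path Output path.
#' @export
writeReports <- function(path, evalReport = NULL, efficiencyReport = NULL) {
  out <- list()
  if (!is.null(evalReport)) {
    out$metrics <- list(macro = as.list(evalReport@macro),
                        per_class = evalReport@perClass)
    if (length(evalReport@cv))
      out$cv <- list(mean = as.list(evalReport@cv$mean),
                     sd = as.list(evalReport@cv$sd))
    if (nrow(evalReport@perSource)) out$per_source <- evalReport@perSource
  }
  if (!is.null(efficiencyReport))
    out$efficiency <- as.list(reportAsRow(efficiencyReport))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
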