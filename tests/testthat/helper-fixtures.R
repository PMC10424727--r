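# Shared fixtures, built lazily once per session.

.fixtures <- new.env(parent = emptyenv())

getFixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

schemeFor <- function(classes, mode = "multiclass") {
  new("LabelScheme", mode = mode, classes = classes,
      codeMap = stats::setNames(classes, classes))
}

firstLabels <- function(records) {
  vapply(records, function(r) recordLabels(r)[1], character(1))
}

recordIds <- function(records) vapply(records, recordId, character(1))

# match detections to ground truth at a time tolerance (seconds)
detectorScores <- function(records, truths, fs = 300, tol = 0.05) {
  tp <- fn <- fp <- 0
  for (i in seq_along(records)) {
    b <- suppressWarnings(detectRPeaks(records[[i]]))
    det <- (rPeaks(b) - 1) / samplingRate(records[[i]])
    tr <- truths[[i]]@rPeakTimes
    hit <- vapply(tr, function(t) any(abs(det - t) <= tol), TRUE)
    hitP <- vapply(det, function(t) any(abs(tr - t) <= tol), TRUE)
    tp <- tp + sum(hit)
    fn <- fn + sum(!hit)
    fp <- fp + sum(!hitP)
  }
  c(sensitivity = tp / (tp + fn), ppv = tp / (tp + fp))
}

# count connected components (4-neighborhood) of nonzero pixels
countComponents <- function(px) {
  seen <- matrix(FALSE, nrow(px), ncol(px))
  comp <- 0L
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    if (px[i, j] > 0 && !seen[i, j]) {
      comp <- comp + 1L
      queue <- list(c(i, j))
      seen[i, j] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(px) && q[2] >= 1 &&
              q[2] <= ncol(px) && px[q[1], q[2]] > 0 && !seen[q[1], q[2]]) {
            seen[q[1], q[2]] <- TRUE
            queue[[length(queue) + 1]] <- q
          }
        }
      }
    }
  }
  comp
}

# independent brute-force metric oracle: enumerate every record into the
# one-vs-rest confusion cells, then apply the textbook formulas
bruteForceMetrics <- function(truth, predicted, classes) {
  perClass <- lapply(classes, function(cl) {
    tp <- fp <- tn <- fn <- 0L
    for (i in seq_along(truth)) {
      inT <- cl %in% (if (is.list(truth)) truth[[i]] else truth[i])
      inP <- cl %in% (if (is.list(predicted)) predicted[[i]]
                      else predicted[i])
      if (inT && inP) tp <- tp + 1L
      else if (!inT && inP) fp <- fp + 1L
      else if (inT && !inP) fn <- fn + 1L
      else tn <- tn + 1L
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else if (tp + fp + fn == 0) 1 else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else if (tp + fp + fn == 0) 1 else 0
    spec <- if (fp + tn > 0) tn / (fp + tn) else if (tp + fp + fn == 0) 1 else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec)
    else if (tp + fp + fn == 0) 1 else 0
    c(precision = prec, recall = rec, specificity = spec, f1 = f1)
  })
  m <- do.call(rbind, perClass)
  colMeans(m)
}
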