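#' @include AllClasses.R
NULL

#' Construct an EcgRecord
#'
#' @param recordId Record identifier.
#' @param signal Numeric matrix (leads x samples) or a vector for one lead,
#'   in millivolts.
#' @param fs Sampling rate in Hz.
#' @param leadNames Lead names; defaults to \code{"I"}, \code{"II"}, ...
#' @param labels Character vector of class identifiers.
#' @param age,sex Optional demographics.
#' @param source Source tag.
#' @return An \linkS4class{EcgRecord}.
#' @export
EcgRecord <- function(recordId, signal, fs, leadNames = NULL,
                      labels = character(), age = NULL, sex = NULL,
                      source = "unknown") {
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  if (is.null(leadNames))
    leadNames <- standardLeadNames(nrow(signal))
  new("EcgRecord", recordId = as.character(recordId), signal = signal,
      fs = fs, leadNames = leadNames, labels = as.character(labels),
      age = if (is.null(age)) NULL else as.integer(age), sex = sex,
      source = source)
}

standardLeadNames <- function(n) {
  full <- c("I", "II", "III", "aVR", "aVL", "aVF",
            "V1", "V2", "V3", "V4", "V5", "V6")
  if (n <= 12) full[seq_len(n)] else paste0("CH", seq_len(n))
}

#' @rdname EcgRecord
#' @param object,x An object.
#' @export
setGeneric("recordId", function(object) standardGeneric("recordId"))
#' @rdname EcgRecord
#' @export
setGeneric("ecgSignal", function(object) standardGeneric("ecgSignal"))
#' @rdname EcgRecord
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname EcgRecord
#' @export
setGeneric("leadNames", function(object) standardGeneric("leadNames"))
#' @rdname EcgRecord
#' @export
setGeneric("recordLabels", function(object) standardGeneric("recordLabels"))
#' @rdname EcgRecord
#' @export
setGeneric("recordSource", function(object) standardGeneric("recordSource"))
#' @rdname EcgRecord
#' @export
setGeneric("durationS", function(object) standardGeneric("durationS"))

setMethod("recordId", "EcgRecord", function(object) object@recordId)
setMethod("ecgSignal", "EcgRecord", function(object) object@signal)
setMethod("samplingRate", "EcgRecord", function(object) object@fs)
setMethod("leadNames", "EcgRecord", function(object) object@leadNames)
setMethod("recordLabels", "EcgRecord", function(object) object@labels)
setMethod("recordSource", "EcgRecord", function(object) object@source)
setMethod("durationS", "EcgRecord",
          function(object) ncol(object@signal) / object@fs)

setMethod("show", "EcgRecord", function(object) {
  cat(sprintf("EcgRecord '%s': %d lead(s) x %d samples @ %g Hz (%.1f s)\n",
              object@recordId, nrow(object@signal), ncol(object@signal),
              object@fs, durationS(object)))
  cat(sprintf("  labels: %s | source: %s\n",
              if (length(object@labels)) paste(object@labels, collapse = ",")
              else "<none>", object@source))
  if (!is.null(object@age) || !is.null(object@sex))
    cat(sprintf("  demographics: age=%s sex=%s\n",
                ifelse(is.null(object@age), "NA", object@age),
                ifelse(is.null(object@sex), "NA", object@sex)))
  invisible(object)
})

#' Accessors for detected beats
#' @param object A \linkS4class{BeatSeries}.
#' @return \code{rPeaks}: integer sample indices; \code{rrIntervals} and
#'   \code{nnIntervals}: interval vectors in seconds.
#' @export
setGeneric("rPeaks", function(object) standardGeneric("rPeaks"))
#' @rdname rPeaks
#' @export
setGeneric("rrIntervals", function(object) standardGeneric("rrIntervals"))
#' @rdname rPeaks
#' @export
setGeneric("nnIntervals", function(object) standardGeneric("nnIntervals"))

setMethod("rPeaks", "BeatSeries", function(object) object@rPeaks)
setMethod("rrIntervals", "BeatSeries", function(object) object@rr)
setMethod("nnIntervals", "BeatSeries", function(object) object@nn)

setMethod("show", "BeatSeries", function(object) {
  cat(sprintf("BeatSeries: %d peaks, %d RR, %d NN @ %g Hz\n",
              length(object@rPeaks), length(object@rr), length(object@nn),
              object@fs))
  invisible(object)
})

setMethod("show", "LabelScheme", function(object) {
  cat(sprintf("LabelScheme (%s): %s\n", object@mode,
              paste(object@classes, collapse = ", ")))
  invisible(object)
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d train / %d val / %d test (seed %d)\n",
              length(object@trainIds), length(object@valIds),
              length(object@testIds), object@seed))
  invisible(object)
})

setMethod("show", "PoincareImage", function(object) {
  cat(sprintf("PoincareImage %dx%d, axes [%.2f, %.2f] s, marker %d px\n",
              nrow(object@pixels), ncol(object@pixels), object@axisMin,
              object@axisMax, object@markerRadius))
  invisible(object)
})

setMethod("show", "ModelBundle", function(object) {
  cat(sprintf("ModelBundle '%s' (%s, %d classes)%s\n", object@arch,
              object@mode, length(object@classes),
              if (object@trained) " [trained]" else " [untrained]"))
  cat(sprintf("  parameters: %s\n",
              format(countParams(object@net), big.mark = ",")))
  invisible(object)
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n  macro:",
      paste(sprintf("%s=%.3f", names(object@macro), object@macro),
            collapse = " "), "\n")
  if (nrow(object@perClass)) {
    cat("  per-class F1:",
        paste(sprintf("%s=%.3f", rownames(object@perClass),
                      object@perClass$f1), collapse = " "), "\n")
  }
  invisible(object)
})

setMethod("show", "EfficiencyReport", function(object) {
  cat(sprintf(
    "EfficiencyReport: %.3f Wh, %.3f g CO2 | %.1f + %.1f = %.1f ms/record%s\n",
    object@energyWh, object@co2G, object@timeProcessingMs,
    object@timePredictingMs, object@timeTotalMs,
    if (object@estimator) " (TDP-share estimate)" else ""))
  invisible(object)
})

#' Convert an EvalReport or EfficiencyReport to a one-row data frame
#' @param report The report object.
#' @return A data frame suitable for rbinding across runs.
#' @export
reportAsRow <- function(report) {
  if (is(report, "EvalReport")) {
    as.data.frame(as.list(report@macro))
  } else {
    data.frame(energy_wh = report@energyWh, co2_g = report@co2G,
               time_processing_ms = report@timeProcessingMs,
               time_predicting_ms = report@timePredictingMs,
               time_total_ms = report@timeTotalMs,
               estimator = report@estimator)
  }
}
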