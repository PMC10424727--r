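#' @import methods
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))

#' Label scheme for an ECG classification task
#'
#' Describes how raw header diagnosis codes map onto the working class set,
#' and whether the task is multiclass (exactly one label per record, as in
#' single-lead arrhythmia screening) or multilabel (one or more diagnoses per
#' record, as in 12-lead diagnostic ECG).
#'
#' @slot mode Either \code{"multiclass"} or \code{"multilabel"}.
#' @slot classes Ordered character vector of class identifiers.
#' @slot codeMap Named character vector mapping raw codes to class ids.
#' @export
setClass("LabelScheme",
  representation(mode = "character", classes = "character",
                 codeMap = "character"),
  validity = function(object) {
    if (!object@mode %in% c("multiclass", "multilabel"))
      return("mode must be 'multiclass' or 'multilabel'")
    if (anyDuplicated(object@classes))
      return("classes must be unique")
    if (length(object@codeMap) &&
        !all(object@codeMap %in% object@classes))
      return("codeMap values must be members of classes")
    TRUE
  })

#' A single annotated ECG record
#'
#' The central container: a leads-by-samples signal matrix in millivolts plus
#' acquisition metadata (sampling rate, lead names), the diagnostic label set,
#' and optional demographics parsed from the header.
#'
#' @slot recordId Record identifier.
#' @slot signal Numeric matrix, \code{n_leads x n_samples}, millivolts.
#' @slot fs Sampling rate in Hz.
#' @slot leadNames Character vector, one name per lead.
#' @slot labels Character vector of class identifiers (possibly empty for
#'   unlabeled records).
#' @slot age Optional integer age in years (ages over 89 may arrive masked
#'   as 92 in de-identified data and are passed through unchanged).
#' @slot sex Optional \code{"male"}/\code{"female"}.
#' @slot source Free-form source tag (e.g. \code{"CPSC"}, \code{"synthetic"}).
#' @export
setClass("EcgRecord",
  representation(recordId = "character", signal = "matrix", fs = "numeric",
                 leadNames = "character", labels = "character",
                 age = "integerOrNULL", sex = "characterOrNULL",
                 source = "character"),
  prototype(age = NULL, sex = NULL, source = "unknown"),
  validity = function(object) {
    if (length(object@fs) != 1 || object@fs <= 0)
      return("fs must be a single positive number")
    if (nrow(object@signal) != length(object@leadNames))
      return("leadNames length must equal number of signal rows (leads)")
    if (!all(is.finite(object@signal)))
      return("signal values must be finite")
    if (!is.null(object@sex) && !object@sex %in% c("male", "female"))
      return("sex must be 'male' or 'female'")
    TRUE
  })

#' Train/validation/test partition of record ids
#' @slot trainIds,valIds,testIds Disjoint character vectors of record ids.
#' @slot seed Integer seed the partition was drawn with.
#' @export
setClass("DatasetSplit",
  representation(trainIds = "character", valIds = "character",
                 testIds = "character", seed = "integer"),
  validity = function(object) {
    all_ids <- c(object@trainIds, object@valIds, object@testIds)
    if (anyDuplicated(all_ids)) return("subsets must be pairwise disjoint")
    TRUE
  })

#' Rhythm specification for the synthetic ECG generator
#'
#' Each beat of the simulated ECG is a sum of five Gaussian bumps (P, Q, R,
#' S, T) placed relative to the R time; the rhythm class controls the
#' inter-beat (RR) model and whether a P wave is present. Atrial fibrillation
#' is emulated by an irregular (i.i.d. truncated-Gaussian) RR sequence with
#' the P bump removed.
#'
#' @slot classId One of \code{"sinus"}, \code{"af"}, \code{"tachy"},
#'   \code{"brady"}, \code{"noisy"}.
#' @slot meanRR Mean RR interval in seconds (0.3--2.0).
#' @slot rrSd RR standard deviation in seconds.
#' @slot rrModel \code{"gaussian"} (correlated, slowly wandering) or
#'   \code{"irregular"} (i.i.d. draws).
#' @slot pWave Whether a P bump is rendered.
#' @slot noiseSd Additive white-noise SD in millivolts.
#' @slot baselineWanderAmp Amplitude (mV) of the 0.25 Hz baseline sinusoid.
#' @slot seed Integer seed.
#' @export
setClass("RhythmSpec",
  representation(classId = "character", meanRR = "numeric", rrSd = "numeric",
                 rrModel = "character", pWave = "logical", noiseSd = "numeric",
                 baselineWanderAmp = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@meanRR < 0.3 || object@meanRR > 2.0)
      return("meanRR must lie in [0.3, 2.0] seconds")
    if (object@rrSd < 0) return("rrSd must be >= 0")
    if (!object@rrModel %in% c("gaussian", "irregular"))
      return("rrModel must be 'gaussian' or 'irregular'")
    if (object@rrModel == "irregular" && object@rrSd < 0.1 * object@meanRR)
      return("irregular rrModel requires rrSd >= 0.1 * meanRR")
    TRUE
  })

#' Ground truth attached to a synthetic record
#' @slot rPeakTimes Strictly increasing R-bump centers in seconds.
#' @slot rhythmLabel The generating rhythm class.
#' @export
setClass("GroundTruth",
  representation(rPeakTimes = "numeric", rhythmLabel = "character"),
  validity = function(object) {
    if (is.unsorted(object@rPeakTimes, strictly = TRUE))
      return("rPeakTimes must be strictly increasing")
    TRUE
  })

#' Detected beats of one record
#'
#' Holds the detected R-peak sample indices, the raw RR intervals derived
#' from them, and the NN subset that survives the normality filter.
#'
#' @slot rPeaks Strictly increasing integer sample indices.
#' @slot rr RR intervals in seconds (length \code{length(rPeaks) - 1}).
#' @slot nn Accepted ("normal-to-normal") intervals, a subset of \code{rr}
#'   in original order.
#' @slot fs Sampling rate the indices refer to.
#' @export
setClass("BeatSeries",
  representation(rPeaks = "integer", rr = "numeric", nn = "numeric",
                 fs = "numeric"),
  validity = function(object) {
    if (length(object@rPeaks) > 1 &&
        is.unsorted(object@rPeaks, strictly = TRUE))
      return("rPeaks must be strictly increasing")
    if (length(object@rr) && any(object@rr <= 0))
      return("rr intervals must be positive")
    if (length(object@rPeaks) > 1 &&
        length(object@rr) != length(object@rPeaks) - 1)
      return("rr must have length(rPeaks) - 1")
    TRUE
  })

#' Poincare scatter of successive NN intervals
#' @slot points Two-column matrix; row k is (NN_k, NN_{k+1}) in seconds.
#' @export
setClass("PoincarePoints",
  representation(points = "matrix"),
  validity = function(object) {
    if (ncol(object@points) != 2) return("points must have two columns")
    if (nrow(object@points) && any(object@points <= 0))
      return("all coordinates must be positive")
    TRUE
  })

#' Rasterized Poincare diagram
#' @slot pixels Square intensity matrix with values in [0, 1].
#' @slot axisMin,axisMax Axis limits in seconds shared by both axes.
#' @slot markerRadius Disc radius in pixels used for each point.
#' @export
setClass("PoincareImage",
  representation(pixels = "matrix", axisMin = "numeric", axisMax = "numeric",
                 markerRadius = "integer"),
  validity = function(object) {
    if (nrow(object@pixels) != ncol(object@pixels))
      return("pixels must be square")
    if (any(object@pixels < 0) || any(object@pixels > 1))
      return("pixel intensities must lie in [0, 1]")
    if (object@axisMin >= object@axisMax)
      return("axisMin must be < axisMax")
    TRUE
  })

#' A built (possibly trained) classification model
#'
#' Wraps one of the three network families -- the 12-block 1D CNN, the 1D
#' ResNet, or a 2D image backbone (ResNet50 / DenseNet121) applied to
#' Poincare diagrams -- together with its input transform and label space.
#'
#' @slot arch \code{"cnn1d"}, \code{"resnet1d"} or \code{"image2d"}.
#' @slot hyper List of architecture hyperparameters actually used.
#' @slot net The internal network (reference semantics environment).
#' @slot mode \code{"multiclass"} or \code{"multilabel"}.
#' @slot classes Ordered class identifiers the head maps to.
#' @slot inputTransform List describing how records become tensors.
#' @slot trained Whether \code{trainModel} has been run.
#' @slot history Per-epoch training log.
#' @export
setClass("ModelBundle",
  representation(arch = "character", hyper = "list", net = "environment",
                 mode = "character", classes = "character",
                 inputTransform = "list", trained = "logical",
                 history = "data.frame"),
  prototype(trained = FALSE, history = data.frame()),
  validity = function(object) {
    if (!object@arch %in% c("cnn1d", "resnet1d", "image2d"))
      return("unknown arch")
    if (length(object@classes) < 2) return("need at least two classes")
    TRUE
  })

#' Classification performance report
#' @slot perClass Data frame with one row per class: precision, recall
#'   (sensitivity), specificity, F1, and the one-vs-rest counts.
#' @slot macro Named numeric vector of macro-averaged f1, sensitivity,
#'   specificity (micro averages included when requested).
#' @slot cv Optional list with fold-wise metrics and their mean/SD.
#' @slot perSource Optional per-source breakdown table.
#' @export
setClass("EvalReport",
  representation(perClass = "data.frame", macro = "numeric", cv = "list",
                 perSource = "data.frame"),
  prototype(cv = list(), perSource = data.frame()),
  validity = function(object) {
    m <- object@macro
    if (length(m) && (any(m < -1e-9) || any(m > 1 + 1e-9)))
      return("macro metrics must lie in [0, 1]")
    TRUE
  })

#' Inference efficiency report
#' @slot energyWh Energy used over the profiled run, watt-hours.
#' @slot co2G Equivalent CO2 grams (= energyWh x carbon intensity).
#' @slot timeProcessingMs,timePredictingMs,timeTotalMs Per-record averages.
#' @slot estimator TRUE when energy comes from a TDP-share estimate rather
#'   than hardware counters.
#' @slot nRecords Number of records profiled.
#' @export
setClass("EfficiencyReport",
  representation(energyWh = "numeric", co2G = "numeric",
                 timeProcessingMs = "numeric", timePredictingMs = "numeric",
                 timeTotalMs = "numeric", estimator = "logical",
                 nRecords = "integer"),
  validity = function(object) {
    if (object@energyWh < 0 || object@co2G < 0 ||
        object@timeProcessingMs < 0 || object@timePredictingMs < 0)
      return("efficiency quantities must be non-negative")
    if (abs(object@timeTotalMs -
            (object@timeProcessingMs + object@timePredictingMs)) > 1e-6)
      return("timeTotalMs must equal processing + predicting")
    TRUE
  })
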