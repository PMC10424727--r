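# Synthetic annotated ECG. Each beat is a sum of five Gaussian bumps
# (P, Q, R, S, T) placed relative to the R time; rhythm classes differ in
# their RR-interval model and P-wave presence. The generator emulates the
# single-lead 300 Hz dialect and the 12-lead 257-1000 Hz dialect, and always
# returns the exact R-bump centers as ground truth.

# Default bump parameters: amplitude (mV), width sigma (s), offset from R (s)
.beatTemplate <- list(
  P = c(amp = 0.15, sigma = 0.025, offset = -0.16),
  Q = c(amp = -0.10, sigma = 0.010, offset = -0.030),
  R = c(amp = 1.00, sigma = 0.012, offset = 0.000),
  S = c(amp = -0.15, sigma = 0.010, offset = 0.030),
  T = c(amp = 0.30, sigma = 0.060, offset = 0.250))

#' Construct a rhythm specification
#'
#' Class defaults: sinus (mean RR 0.8 s, smooth gaussian variability),
#' af (irregular i.i.d. RR with sd 0.2 x mean and no P wave), tachy
#' (mean RR 0.45 s), brady (mean RR 1.2 s), noisy (sinus timing under heavy
#' additive noise). All defaults can be overridden.
#'
#' @param classId Rhythm class id.
#' @param meanRR,rrSd RR mean / sd in seconds.
#' @param rrModel "gaussian" (AR(1) wander) or "irregular" (i.i.d.).
#' @param pWave Render the P bump?
#' @param noiseSd White-noise sd in mV.
#' @param baselineWanderAmp 0.25 Hz baseline sinusoid amplitude in mV.
#' @param seed Integer seed.
#' @return A \linkS4class{RhythmSpec}.
#' @export
rhythmSpec <- function(classId = c("sinus", "af", "tachy", "brady", "noisy"),
                       meanRR = NULL, rrSd = NULL, rrModel = NULL,
                       pWave = NULL, noiseSd = 0.05,
                       baselineWanderAmp = 0.1, seed = 1L) {
  classId <- match.arg(classId)
  def <- switch(classId,
    sinus = list(meanRR = 0.8, rrSd = 0.04, rrModel = "gaussian",
                 pWave = TRUE, noiseSd = noiseSd),
    af    = list(meanRR = 0.8, rrSd = 0.16, rrModel = "irregular",
                 pWave = FALSE, noiseSd = noiseSd),
    tachy = list(meanRR = 0.45, rrSd = 0.02, rrModel = "gaussian",
                 pWave = TRUE, noiseSd = noiseSd),
    brady = list(meanRR = 1.2, rrSd = 0.05, rrModel = "gaussian",
                 pWave = TRUE, noiseSd = noiseSd),
    noisy = list(meanRR = 0.8, rrSd = 0.06, rrModel = "gaussian",
                 pWave = TRUE, noiseSd = max(noiseSd, 0.35)))
  if (is.null(meanRR)) meanRR <- def$meanRR
  if (is.null(rrSd)) rrSd <- if (identical(rrModel, "irregular"))
    max(def$rrSd, 0.2 * meanRR) else def$rrSd
  if (is.null(rrModel)) rrModel <- def$rrModel
  if (rrModel == "irregular") rrSd <- max(rrSd, 0.2 * meanRR)
  if (is.null(pWave)) pWave <- def$pWave
  new("RhythmSpec", classId = classId, meanRR = meanRR, rrSd = rrSd,
      rrModel = rrModel, pWave = pWave, noiseSd = def$noiseSd,
      baselineWanderAmp = baselineWanderAmp, seed = as.integer(seed))
}

# RR sequence long enough to cover `durationS` starting at t0.
generateRR <- function(spec, durationS, t0) {
  n <- ceiling((durationS - t0) / max(spec@meanRR - 3 * spec@rrSd, 0.3)) + 2
  if (spec@rrSd == 0) return(rep(spec@meanRR, n))
  if (spec@rrModel == "irregular") {
    # i.i.d. truncated gaussian: the AF "spreading cloud" regime
    rr <- stats::rnorm(n, spec@meanRR, spec@rrSd)
    bad <- rr < 0.3
    while (any(bad)) {
      rr[bad] <- stats::rnorm(sum(bad), spec@meanRR, spec@rrSd)
      bad <- rr < 0.3
    }
    rr
  } else {
    # smooth AR(1) wander (respiratory-like modulation)
    phi <- 0.9
    e <- stats::rnorm(n, 0, spec@rrSd * sqrt(1 - phi^2))
    z <- numeric(n)
    z[1] <- stats::rnorm(1, 0, spec@rrSd)
    for (i in 2:n) z[i] <- phi * z[i - 1] + e[i]
    pmax(spec@meanRR + z, 0.3)
  }
}

#' Simulate one annotated ECG record
#'
#' @param spec A \linkS4class{RhythmSpec}.
#' @param durationS Record length in seconds (5--1800).
#' @param fs Sampling rate in Hz (100--1000).
#' @param nLeads Number of leads; leads share timing and differ by a
#'   deterministic per-lead amplitude scale.
#' @param recordId Identifier for the generated record.
#' @param source Source tag stamped on the record.
#' @param label Label(s) to attach; defaults to the rhythm class id.
#' @return A list with elements \code{record} (\linkS4class{EcgRecord}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' r <- simulateRecord(rhythmSpec("af", seed = 7), durationS = 30, fs = 300)
#' r$record
#' @export
simulateRecord <- function(spec, durationS = 10, fs = 300, nLeads = 1L,
                           recordId = "S00001", source = "synthetic",
                           label = NULL) {
  if (durationS < 5 || durationS > 1800)
    stop("durationS must lie in [5, 1800]")
  if (fs < 100 || fs > 1000) stop("fs must lie in [100, 1000]")
  withSeed(spec@seed, {
    t0 <- 0.45
    rr <- generateRR(spec, durationS, t0)
    rTimes <- t0 + c(0, cumsum(rr))
    rTimes <- rTimes[rTimes <= durationS - 0.002]
    n <- round(durationS * fs)
    tt <- (seq_len(n) - 1) / fs
    x <- numeric(n)
    bumps <- .beatTemplate
    if (!spec@pWave) bumps$P <- NULL
    for (tr in rTimes) {
      for (bp in bumps) {
        ctr <- tr + bp[["offset"]]
        lo <- max(1L, floor((ctr - 4 * bp[["sigma"]]) * fs) + 1L)
        hi <- min(n, ceiling((ctr + 4 * bp[["sigma"]]) * fs) + 1L)
        if (lo > hi) next
        win <- lo:hi
        x[win] <- x[win] +
          bp[["amp"]] * exp(-((tt[win] - ctr)^2) / (2 * bp[["sigma"]]^2))
      }
    }
    phase <- stats::runif(1, 0, 2 * pi)
    wander <- spec@baselineWanderAmp * sin(2 * pi * 0.25 * tt + phase)
    leadScale <- if (nLeads == 1L) 1 else
      round(stats::runif(nLeads, 0.5, 1.2), 3)
    sig <- matrix(0, nLeads, n)
    for (l in seq_len(nLeads)) {
      noise <- if (spec@noiseSd > 0) stats::rnorm(n, 0, spec@noiseSd) else 0
      sig[l, ] <- leadScale[l] * x + wander + noise
    }
    rec <- EcgRecord(recordId = recordId, signal = sig, fs = fs,
                     labels = if (is.null(label)) spec@classId else label,
                     source = source)
    list(record = rec,
         truth = new("GroundTruth", rPeakTimes = rTimes,
                     rhythmLabel = spec@classId))
  })
}

#' Simulate a labelled dataset of ECG records
#'
#' @param classMix Named integer vector, class id -> record count, e.g.
#'   \code{c(sinus = 60, af = 10, tachy = 15, brady = 15)}.
#' @param dialect \code{"cinc2017"} (single lead, 300 Hz, labels N/A/O/~),
#'   \code{"cinc2020"} (12 leads, fs drawn from 257/500/1000 Hz, SNOMED-coded
#'   labels) or \code{"synthetic"} (single lead, class ids as labels).
#' @param seed Master seed; per-record seeds are derived from it.
#' @param durationS Record length in seconds.
#' @param noiseSd White-noise sd passed to every spec.
#' @param idPrefix Record-id prefix.
#' @param source Source tag; default varies by record for cinc2020 to mimic
#'   a multi-source collection.
#' @return List with elements \code{records} and \code{truths} (parallel
#'   lists).
#' @export
simulateDataset <- function(classMix, dialect = c("synthetic", "cinc2017",
                                                  "cinc2020"),
                            seed = 1L, durationS = 10, noiseSd = 0.05,
                            idPrefix = "S", source = NULL) {
  dialect <- match.arg(dialect)
  classMix <- classMix[classMix > 0]
  if (!length(classMix)) stop("classMix must request at least one record")
  classes <- rep(names(classMix), times = classMix)
  nrec <- length(classes)
  label2017 <- c(sinus = "N", af = "A", tachy = "O", brady = "O",
                 noisy = "~")
  label2020 <- c(sinus = "SNR", af = "AF", tachy = "STach", brady = "SB",
                 noisy = "SNR")
  fsPool <- c(257, 500, 1000)
  srcPool <- c("CPSC", "PTB-XL", "G12EC", "INCART")
  records <- vector("list", nrec)
  truths <- vector("list", nrec)
  ord <- withSeed(as.integer(seed), sample(nrec))
  classes <- classes[ord]
  for (i in seq_len(nrec)) {
    recSeed <- (as.integer(seed) * 7919L + i * 104729L) %% 2147483647L
    spec <- rhythmSpec(classes[i], noiseSd = noiseSd, seed = recSeed)
    fs <- if (dialect == "cinc2020") fsPool[(i - 1) %% 3 + 1] else 300
    nLeads <- if (dialect == "cinc2020") 12L else 1L
    lbl <- switch(dialect,
                  cinc2017 = label2017[[classes[i]]],
                  cinc2020 = label2020[[classes[i]]],
                  synthetic = classes[i])
    src <- if (!is.null(source)) source
    else if (dialect == "cinc2020") srcPool[(i - 1) %% 4 + 1]
    else "synthetic"
    out <- simulateRecord(spec, durationS = durationS, fs = fs,
                          nLeads = nLeads,
                          recordId = sprintf("%s%05d", idPrefix, i),
                          source = src, label = lbl)
    records[[i]] <- out$record
    truths[[i]] <- out$truth
  }
  list(records = records, truths = truths)
}

#' Write a simulated dataset as WFDB-dialect files plus ground truth
#'
#' @param ds Result of [simulateDataset()].
#' @param dir Output directory.
#' @param dialect Dialect passed to [writeRecord()].
#' @return Invisibly, \code{dir}. Ground truth goes to
#'   \code{groundtruth.json}.
#' @export
writeDataset <- function(ds, dir, dialect = "synthetic") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in ds$records) writeRecord(rec, dir, dialect = dialect)
  gt <- lapply(seq_along(ds$truths), function(i)
    list(id = ds$records[[i]]@recordId,
         r_peak_times = ds$truths[[i]]@rPeakTimes,
         rhythm = ds$truths[[i]]@rhythmLabel))
  jsonlite::write_json(gt, file.path(dir, "groundtruth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
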