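# Signal conditioning and beat detection. The detector follows the classic
# Hamilton pipeline: 3-45 Hz bandpass, differentiation, rectification, 80 ms
# moving-average integration, adaptive thresholding between running
# signal-peak and noise-peak averages with a 200 ms refractory period and a
# half-threshold searchback, and final refinement of each detection to the
# local filtered-signal maximum within +/- 40 ms.

#' Zero-phase 3-45 Hz bandpass
#'
#' Linear-phase FIR bandpass (Hamming-windowed, order 0.3 x fs) applied
#' forward and backward, so the net filter is zero-phase and the output has
#' the input's length.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz; must exceed twice the upper edge.
#' @param low,high Band edges in Hz.
#' @return Filtered vector, same length as \code{x}.
#' @export
bandpassFilter <- function(x, fs, low = 3, high = 45) {
  if (fs <= 2 * high)
    stop("fs must exceed twice the upper band edge (", 2 * high, " Hz)")
  ord <- round(0.3 * fs)
  if (ord %% 2 == 1) ord <- ord + 1
  h <- as.numeric(signal::fir1(ord, c(low, high) / (fs / 2), type = "pass"))
  as.numeric(signal::filtfilt(h, 1, x))
}

#' Detect R peaks (Hamilton algorithm)
#'
#' @param x An \linkS4class{EcgRecord} (first lead is used) or a numeric
#'   vector.
#' @param fs Sampling rate; taken from the record when \code{x} is one.
#' @param thresholdCoef Position of the detection threshold between the
#'   running noise-peak and signal-peak averages (default 0.45).
#' @param refractoryS Minimum inter-detection gap in seconds.
#' @return A \linkS4class{BeatSeries}; \code{nn} is left empty here and
#'   filled by [extractNN()].
#' @export
detectRPeaks <- function(x, fs = NULL, thresholdCoef = 0.45,
                         refractoryS = 0.2) {
  if (is(x, "EcgRecord")) {
    fs <- x@fs
    x <- x@signal[1, ]
  }
  if (is.null(fs)) stop("fs is required for a plain vector input")
  if (length(x) < 2 * fs) {
    warning("input shorter than 2 s; returning empty BeatSeries")
    return(new("BeatSeries", rPeaks = integer(), rr = numeric(),
               nn = numeric(), fs = fs))
  }
  y <- bandpassFilter(x, fs)
  if (all(abs(y) < 1e-12)) {
    return(new("BeatSeries", rPeaks = integer(), rr = numeric(),
               nn = numeric(), fs = fs))
  }
  d <- abs(diff(y))
  w <- max(1L, round(0.08 * fs))
  ma <- as.numeric(stats::filter(d, rep(1 / w, w), sides = 2))
  ma[is.na(ma)] <- 0
  n <- length(ma)
  refr <- round(refractoryS * fs)
  # candidate peaks: local maxima of the integrated signal that dominate
  # their +/- refractory neighborhood (non-maximum suppression)
  locmax <- which(diff(sign(diff(ma))) < 0) + 1L
  locmax <- locmax[ma[locmax] > 0]
  cand <- locmax[vapply(locmax, function(i) {
    lo <- max(1L, i - refr)
    hi <- min(n, i + refr)
    ma[i] >= max(ma[lo:hi])
  }, TRUE)]
  if (!length(cand)) {
    return(new("BeatSeries", rPeaks = integer(), rr = numeric(),
               nn = numeric(), fs = fs))
  }
  slopeAt <- function(i) {
    lo <- max(1L, i - round(0.04 * fs))
    hi <- min(length(d), i + round(0.04 * fs))
    max(d[lo:hi])
  }
  init <- ma[seq_len(min(n, 2 * round(fs)))]
  sHist <- max(init) * 0.7
  nHist <- mean(init)
  peaks <- integer()
  slopes <- numeric()
  rrHist <- numeric()
  lastSkipped <- integer()
  thr <- function() mean(nHist) + thresholdCoef * (mean(sHist) - mean(nHist))
  pushS <- function(v) sHist <<- utils::tail(c(sHist, v), 8)
  pushN <- function(v) nHist <<- utils::tail(c(nHist, v), 8)
  pushRR <- function(rr) {
    # physiologically plausible intervals only, so that a stray detection
    # cannot collapse the searchback expectation
    if (rr >= 0.3 * fs && rr <= 2.0 * fs)
      rrHist <<- utils::tail(c(rrHist, rr), 8)
  }
  accept <- function(i) {
    if (length(peaks)) pushRR(i - peaks[length(peaks)])
    peaks <<- c(peaks, i)
    slopes <<- c(slopes, slopeAt(i))
    pushS(ma[i])
    lastSkipped <<- integer()
  }
  for (i in cand) {
    last <- if (length(peaks)) peaks[length(peaks)] else -Inf
    if (i - last < refr) next
    isTwave <- length(peaks) && (i - last) < round(0.36 * fs) &&
      slopeAt(i) < 0.5 * slopes[length(slopes)]
    if (!isTwave && ma[i] > thr()) {
      accept(i)
    } else {
      # searchback: when the expected beat is overdue, take the best
      # skipped candidate above half the threshold
      if (length(peaks) && length(rrHist) &&
          i - last > 1.5 * mean(rrHist)) {
        pool <- c(lastSkipped, i)
        pool <- pool[pool - last >= refr]
        if (length(pool)) {
          best <- pool[which.max(ma[pool])]
          if (ma[best] > 0.5 * thr()) {
            accept(best)
            next
          }
        }
      }
      lastSkipped <- c(lastSkipped, i)
      pushN(ma[i])
    }
  }
  # refine to the local maximum of the filtered signal within +/- 40 ms
  half <- round(0.04 * fs)
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, as.integer(p) - half)
    hi <- min(length(y), as.integer(p) + half)
    as.integer(lo + which.max(y[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  rr <- diff(refined) / fs
  new("BeatSeries", rPeaks = refined, rr = rr, nn = numeric(), fs = fs)
}

#' Filter RR intervals down to normal-to-normal (NN) intervals
#'
#' An interval is accepted when it lies inside physiological bounds
#' (\code{bounds}, default 0.3--2.0 s) and deviates by no more than
#' \code{maxDeviation} (default 50 percent) from the running median of the
#' last five accepted intervals. Order among retained intervals is
#' preserved.
#'
#' @param beats A \linkS4class{BeatSeries}.
#' @param bounds Length-2 physiological bounds in seconds.
#' @param maxDeviation Maximal relative deviation from the running median.
#' @return The \linkS4class{BeatSeries} with its \code{nn} slot filled.
#' @export
extractNN <- function(beats, bounds = c(0.3, 2.0), maxDeviation = 0.5) {
  if (length(beats@rPeaks) < 3) {
    warning("fewer than 3 peaks; no NN intervals")
    return(new("BeatSeries", rPeaks = beats@rPeaks, rr = beats@rr,
               nn = numeric(), fs = beats@fs))
  }
  acc <- numeric()
  for (v in beats@rr) {
    if (v < bounds[1] || v > bounds[2]) next
    if (length(acc)) {
      med <- stats::median(utils::tail(acc, 5))
      if (abs(v - med) > maxDeviation * med) next
    }
    acc <- c(acc, v)
  }
  new("BeatSeries", rPeaks = beats@rPeaks, rr = beats@rr, nn = acc,
      fs = beats@fs)
}

#' First-order difference + standardization (1D model input)
#'
#' Each lead is differenced once and scaled to zero mean and unit variance;
#' this makes the 1D models invariant to per-lead affine amplitude changes.
#' A constant lead yields zeros (its sd is undefined) with a warning.
#'
#' @param x An \linkS4class{EcgRecord} or a leads-by-samples matrix/vector.
#' @return Matrix of size leads x (samples - 1).
#' @export
transform1d <- function(x) {
  if (is(x, "EcgRecord")) x <- x@signal
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  out <- matrix(0, nrow(x), ncol(x) - 1)
  for (l in seq_len(nrow(x))) {
    d <- diff(x[l, ])
    m <- mean(d)
    s <- sqrt(mean((d - m)^2))  # population SD: a 2-point diff maps to -1, 1
    if (!is.finite(s) || s == 0) {
      warning("constant lead ", l, "; returning zeros")
    } else {
      out[l, ] <- (d - m) / s
    }
  }
  out
}

#' Crop or zero-pad a record to a fixed duration at a fixed rate
#'
#' Variable-length records must be batched for the 1D models; records are
#' linearly resampled to \code{fs} when needed, then center-cropped or
#' zero-padded (at the end) to \code{durationS}.
#'
#' @param record An \linkS4class{EcgRecord}.
#' @param durationS Target duration in seconds.
#' @param fs Target sampling rate in Hz.
#' @return A new \linkS4class{EcgRecord}.
#' @export
standardizeLength <- function(record, durationS = 30, fs = 300) {
  sig <- record@signal
  if (record@fs != fs) {
    nNew <- round(ncol(sig) / record@fs * fs)
    sig <- t(apply(sig, 1, function(v)
      stats::approx(seq_along(v), v, n = nNew)$y))
    if (nrow(record@signal) == 1) sig <- matrix(sig, nrow = 1)
  }
  nTarget <- round(durationS * fs)
  n <- ncol(sig)
  if (n > nTarget) {
    start <- (n - nTarget) %/% 2 + 1
    sig <- sig[, start:(start + nTarget - 1), drop = FALSE]
  } else if (n < nTarget) {
    sig <- cbind(sig, matrix(0, nrow(sig), nTarget - n))
  }
  EcgRecord(recordId = record@recordId, signal = sig, fs = fs,
            leadNames = record@leadNames, labels = record@labels,
            age = record@age, sex = record@sex, source = record@source)
}
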