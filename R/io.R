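# WFDB-dialect record I/O. Records are stored as a text header (<id>.hea)
# plus a 16-bit little-endian signal file (<id>.dat, format 16, samples
# interleaved across leads, physical = digital / gain). Multiclass labels
# (cinc2017 dialect) live in a sidecar REFERENCE.csv; multilabel diagnoses
# (cinc2020/synthetic dialects) in "# Dx:" header comment lines.

#' Built-in label schemes
#'
#' \code{cinc2017Scheme}: the four-class single-lead arrhythmia scheme
#' (N = normal sinus rhythm, A = atrial fibrillation, O = other rhythm,
#' \code{~} = too noisy to classify). \code{cinc2020Scheme}: a multilabel
#' scheme over SNOMED-CT coded diagnoses; the default map covers the rhythm
#' classes the synthetic generator can produce. \code{syntheticScheme}: the
#' generator's own class ids.
#'
#' @return A \linkS4class{LabelScheme}.
#' @export
cinc2017Scheme <- function() {
  cls <- c("N", "A", "O", "~")
  new("LabelScheme", mode = "multiclass", classes = cls,
      codeMap = stats::setNames(cls, cls))
}

#' @rdname cinc2017Scheme
#' @param codeMap Optional named character vector mapping raw diagnosis
#'   codes to class identifiers; unknown codes encountered while reading are
#'   dropped with a warning.
#' @export
cinc2020Scheme <- function(codeMap = NULL) {
  if (is.null(codeMap)) {
    codeMap <- c("426783006" = "SNR",   # sinus rhythm
                 "164889003" = "AF",    # atrial fibrillation
                 "427084000" = "STach", # sinus tachycardia
                 "426177001" = "SB",    # sinus bradycardia
                 "17366009"  = "AF")    # atrial arrhythmia, folded into AF
  }
  new("LabelScheme", mode = "multilabel",
      classes = unique(unname(codeMap)), codeMap = codeMap)
}

#' @rdname cinc2017Scheme
#' @export
syntheticScheme <- function() {
  cls <- c("sinus", "af", "tachy", "brady", "noisy")
  new("LabelScheme", mode = "multiclass",
      classes = cls, codeMap = stats::setNames(cls, cls))
}

defaultScheme <- function(dialect) {
  switch(dialect,
         cinc2017 = cinc2017Scheme(),
         cinc2020 = cinc2020Scheme(),
         synthetic = syntheticScheme(),
         stop("unknown dialect: ", dialect))
}

#' Read a WFDB-dialect ECG record
#'
#' Parses the text header and the paired 16-bit signal file, converts the
#' digital samples to millivolts using the per-lead gain, and attaches
#' labels and demographics. Ages recorded as 92 in de-identified sources may
#' stand for "over 89" and are passed through unchanged.
#'
#' @param path Path to the record, with or without the \code{.hea} suffix.
#' @param dialect One of \code{"cinc2017"}, \code{"cinc2020"},
#'   \code{"synthetic"}; controls where labels are looked up.
#' @param scheme Optional \linkS4class{LabelScheme} overriding the dialect
#'   default.
#' @return An \linkS4class{EcgRecord}.
#' @seealso [writeRecord()]
#' @export
readRecord <- function(path, dialect = c("synthetic", "cinc2017", "cinc2020"),
                       scheme = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(scheme)) scheme <- defaultScheme(dialect)
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop("cannot read header file: ", hea)
  lines <- readLines(hea, warn = FALSE)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) stop("malformed header line in ", hea)
  rid <- top[1]
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  sigLines <- lines[-1][seq_len(nsig)]
  gains <- numeric(nsig)
  leads <- character(nsig)
  datFile <- NULL
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(sigLines[i]), "\\s+")[[1]]
    datFile <- f[1]
    gains[i] <- as.numeric(sub("/.*$", "", sub("\\(.*?\\)", "", f[3])))
    leads[i] <- f[length(f)]
  }
  datPath <- file.path(dirname(hea), datFile)
  if (!file.exists(datPath)) stop("cannot read signal file: ", datPath)
  expect_bytes <- 2L * nsig * nsamp
  if (file.info(datPath)$size != expect_bytes)
    stop("header/sample-count mismatch for ", rid, ": header declares ",
         nsig, " lead(s) x ", nsamp, " samples (", expect_bytes,
         " bytes) but ", basename(datPath), " has ",
         file.info(datPath)$size, " bytes")
  dig <- readBin(datPath, what = "integer", size = 2L, signed = TRUE,
                 endian = "little", n = nsig * nsamp)
  sig <- matrix(as.numeric(dig), nrow = nsig)  # interleaved across leads
  sig <- sig / gains
  comments <- grep("^#", lines, value = TRUE)
  age <- parseComment(comments, "Age")
  sex <- parseComment(comments, "Sex")
  age <- if (is.na(age) || !nzchar(age)) NULL else as.integer(age)
  sex <- normalizeSex(sex)
  labels <- character()
  if (dialect %in% c("cinc2020", "synthetic")) {
    dx <- parseComment(comments, "Dx")
    if (!is.na(dx) && nzchar(dx)) {
      codes <- trimws(strsplit(dx, ",")[[1]])
      labels <- mapCodes(codes, scheme)
    }
  } else {
    ref <- file.path(dirname(hea), "REFERENCE.csv")
    if (file.exists(ref)) {
      tab <- utils::read.csv(ref, header = FALSE,
                             col.names = c("id", "label"),
                             colClasses = "character")
      hit <- tab$label[tab$id == rid]
      if (length(hit) && nzchar(hit[1])) labels <- mapCodes(hit[1], scheme)
    }
  }
  src <- parseComment(comments, "Source")
  EcgRecord(recordId = rid, signal = sig, fs = fs, leadNames = leads,
            labels = labels, age = age, sex = sex,
            source = if (is.na(src)) dialect else src)
}

parseComment <- function(comments, key) {
  pat <- paste0("^#\\s*", key, "\\s*:\\s*(.*)$")
  hit <- grep(pat, comments, value = TRUE)
  if (!length(hit)) return(NA_character_)
  trimws(sub(pat, "\\1", hit[1]))
}

normalizeSex <- function(sx) {
  if (is.na(sx) || !nzchar(sx)) return(NULL)
  s <- tolower(sx)
  if (s %in% c("m", "male")) "male"
  else if (s %in% c("f", "female")) "female"
  else NULL
}

mapCodes <- function(codes, scheme) {
  known <- codes %in% names(scheme@codeMap)
  if (any(!known))
    warning("dropping unknown diagnosis code(s): ",
            paste(codes[!known], collapse = ", "))
  unique(unname(scheme@codeMap[codes[known]]))
}

#' Write a WFDB-dialect ECG record
#'
#' Quantizes the signal to 16-bit integers at the given gain and writes the
#' paired header/signal files. Reading the record back reproduces the signal
#' within one quantization step and all metadata exactly.
#'
#' @param record An \linkS4class{EcgRecord}.
#' @param dir Output directory (created if missing).
#' @param dialect Dialect controlling label placement (see [readRecord()]).
#' @param scheme Optional scheme; labels are written as the raw codes that
#'   map to them (first matching code per label).
#' @param gain Integer units per millivolt (default 1000).
#' @return Invisibly, the paths written.
#' @export
writeRecord <- function(record, dir,
                        dialect = c("synthetic", "cinc2017", "cinc2020"),
                        scheme = NULL, gain = 1000) {
  dialect <- match.arg(dialect)
  if (is.null(scheme)) scheme <- defaultScheme(dialect)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sig <- record@signal
  nsig <- nrow(sig)
  nsamp <- ncol(sig)
  rid <- record@recordId
  dig <- round(sig * gain)
  dig <- pmin(pmax(dig, -32768), 32767)
  datName <- paste0(rid, ".dat")
  writeBin(as.integer(dig), file.path(dir, datName), size = 2L,
           endian = "little")
  hdr <- sprintf("%s %d %g %d", rid, nsig, record@fs, nsamp)
  sigLines <- sprintf("%s 16 %g/mV 16 0 %d 0 0 %s", datName, gain,
                      as.integer(dig[, 1]), record@leadNames)
  comments <- character()
  if (!is.null(record@age)) comments <- c(comments,
                                          paste0("# Age: ", record@age))
  if (!is.null(record@sex)) comments <- c(comments,
                                          paste0("# Sex: ", record@sex))
  comments <- c(comments, paste0("# Source: ", record@source))
  labels <- record@labels
  if (dialect %in% c("cinc2020", "synthetic")) {
    codes <- labelsToCodes(labels, scheme)
    comments <- c(comments, paste0("# Dx: ", paste(codes, collapse = ",")))
  }
  writeLines(c(hdr, sigLines, comments), file.path(dir, paste0(rid, ".hea")))
  if (dialect == "cinc2017") {
    if (!length(labels))
      warning("record ", rid, " has no label; writing empty placeholder")
    updateReference(dir, rid,
                    if (length(labels)) labelsToCodes(labels[1], scheme)
                    else "")
  }
  invisible(file.path(dir, c(paste0(rid, ".hea"), datName)))
}

labelsToCodes <- function(labels, scheme) {
  vapply(labels, function(l) {
    hits <- names(scheme@codeMap)[scheme@codeMap == l]
    if (length(hits)) hits[1] else l
  }, character(1))
}

updateReference <- function(dir, rid, code) {
  ref <- file.path(dir, "REFERENCE.csv")
  tab <- if (file.exists(ref))
    utils::read.csv(ref, header = FALSE, col.names = c("id", "label"),
                    colClasses = "character")
  else data.frame(id = character(), label = character())
  tab <- tab[tab$id != rid, , drop = FALSE]
  tab <- rbind(tab, data.frame(id = rid, label = code))
  utils::write.table(tab, ref, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

#' Randomly partition record ids into train/validation/test
#'
#' Draws a seed-deterministic 60/20/20 (by default) partition; with
#' \code{strata} given, the split is carried out per class so that per-class
#' proportions are preserved within one record.
#'
#' @param ids Unique character vector of record ids.
#' @param ratios Numeric length-3 vector summing to 1.
#' @param seed Integer seed.
#' @param strata Optional vector of per-id class labels (same length as
#'   \code{ids}).
#' @return A \linkS4class{DatasetSplit}.
#' @export
makeSplit <- function(ids, ratios = c(0.6, 0.2, 0.2), seed = 1L,
                      strata = NULL) {
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be three numbers summing to 1")
  assign3 <- function(v) {
    n <- length(v)
    ntr <- round(ratios[1] * n)
    nva <- round(ratios[2] * n)
    nva <- min(nva, n - ntr)
    list(train = v[seq_len(ntr)],
         val = v[ntr + seq_len(nva)],
         test = v[setdiff(seq_len(n), seq_len(ntr + nva))])
  }
  parts <- withSeed(as.integer(seed), {
    if (is.null(strata)) {
      assign3(sample(ids))
    } else {
      stopifnot(length(strata) == length(ids))
      out <- list(train = character(), val = character(),
                  test = character())
      for (cl in unique(strata)) {
        p <- assign3(sample(ids[strata == cl]))
        out$train <- c(out$train, p$train)
        out$val <- c(out$val, p$val)
        out$test <- c(out$test, p$test)
      }
      out
    }
  })
  new("DatasetSplit", trainIds = parts$train, valIds = parts$val,
      testIds = parts$test, seed = as.integer(seed))
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Split manifest I/O
#'
#' The manifest is a JSON object
#' \code{\{train: [...], validation: [...], test: [...], seed: n\}}.
#'
#' @param split A \linkS4class{DatasetSplit}.
#' @param path Output/input JSON path.
#' @export
writeSplitManifest <- function(split, path) {
  jsonlite::write_json(
    list(train = split@trainIds, validation = split@valIds,
         test = split@testIds, seed = split@seed),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSplitManifest
#' @export
readSplitManifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DatasetSplit", trainIds = as.character(x$train),
      valIds = as.character(x$validation),
      testIds = as.character(x$test), seed = as.integer(x$seed))
}
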