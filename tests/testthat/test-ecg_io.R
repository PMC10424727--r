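test_that("write/read round-trip preserves metadata exactly and signal within quantization", {
  r <- simulateRecord(rhythmSpec("sinus", seed = 4), 10, 300,
                      recordId = "R1")$record
  d <- withr::local_tempdir()
  writeRecord(r, d, dialect = "synthetic")
  r2 <- readRecord(file.path(d, "R1.hea"), dialect = "synthetic")
  expect_equal(samplingRate(r2), 300)
  expect_equal(ncol(ecgSignal(r2)), 3000)
  expect_equal(nrow(ecgSignal(r2)), 1)
  expect_identical(recordLabels(r2), "sinus")
  # 16-bit storage at gain 1000 units/mV: half a step is 0.0005 mV
  expect_lt(max(abs(ecgSignal(r2) - ecgSignal(r))), 1 / 1000 + 1e-12)
})

test_that("demographics survive the header: age 92 mask and sex pass through", {
  r <- EcgRecord("R9", matrix(sin(1:600 / 10), 1), fs = 300,
                 labels = "af", age = 92L, sex = "female",
                 source = "synthetic")
  d <- withr::local_tempdir()
  writeRecord(r, d, dialect = "synthetic")
  r2 <- readRecord(file.path(d, "R9"), dialect = "synthetic")
  expect_identical(r2@age, 92L)
  expect_identical(r2@sex, "female")
})

test_that("12-lead record at 257 Hz declares 12 signal specs and parses back", {
  r <- simulateRecord(rhythmSpec("sinus", seed = 6), 6, 257, nLeads = 12L,
                      recordId = "R12", label = "SNR")$record
  d <- withr::local_tempdir()
  writeRecord(r, d, dialect = "cinc2020")
  hea <- readLines(file.path(d, "R12.hea"))
  expect_match(hea[1], "^R12 12 257 ")
  expect_length(grep("\\.dat 16 ", hea), 12)
  r2 <- readRecord(file.path(d, "R12"), dialect = "cinc2020")
  expect_equal(samplingRate(r2), 257)
  expect_equal(nrow(ecgSignal(r2)), 12)
  expect_identical(recordLabels(r2), "SNR")
})

test_that("header/signal mismatch and missing files raise informative errors", {
  r <- simulateRecord(rhythmSpec("sinus", seed = 2), 5, 300,
                      recordId = "RB")$record
  d <- withr::local_tempdir()
  writeRecord(r, d, dialect = "synthetic")
  # truncate the signal file: header no longer matches
  dat <- file.path(d, "RB.dat")
  bytes <- readBin(dat, "raw", n = file.info(dat)$size)
  writeBin(bytes[seq_len(length(bytes) - 100)], dat)
  expect_error(readRecord(file.path(d, "RB"), dialect = "synthetic"),
               "mismatch")
  expect_error(readRecord(file.path(d, "nope"), dialect = "synthetic"),
               "nope")
})

test_that("label handling: sidecar CSV for the multiclass dialect, unknown codes dropped", {
  r <- simulateRecord(rhythmSpec("af", seed = 3), 6, 300,
                      recordId = "RC", label = "A")$record
  d <- withr::local_tempdir()
  writeRecord(r, d, dialect = "cinc2017")
  expect_true(file.exists(file.path(d, "REFERENCE.csv")))
  r2 <- readRecord(file.path(d, "RC"), dialect = "cinc2017")
  expect_identical(recordLabels(r2), "A")
  # a record with no label is written with a placeholder and a warning
  r0 <- EcgRecord("RD", matrix(rnorm(600), 1), fs = 300)
  expect_warning(writeRecord(r0, d, dialect = "cinc2017"), "no label")
  # unknown Dx codes are dropped with a warning, not an error
  hea <- file.path(d, "RE.hea")
  writeRecord(EcgRecord("RE", matrix(rnorm(600), 1), fs = 300,
                        labels = "AF"), d, dialect = "cinc2020")
  txt <- readLines(hea)
  txt[grep("^# Dx:", txt)] <- "# Dx: 164889003,99999999"
  writeLines(txt, hea)
  expect_warning(r3 <- readRecord(hea, dialect = "cinc2020"), "unknown")
  expect_identical(recordLabels(r3), "AF")
})

test_that("makeSplit honors the 60/20/20 ratio and rounding", {
  s <- makeSplit(sprintf("id%03d", 1:100), seed = 0L)
  expect_equal(lengths(list(s@trainIds, s@valIds, s@testIds)),
               c(60L, 20L, 20L))
  s10 <- makeSplit(sprintf("id%02d", 1:10), seed = 0L)
  expect_equal(lengths(list(s10@trainIds, s10@valIds, s10@testIds)),
               c(6L, 2L, 2L))
  expect_error(makeSplit(letters, ratios = c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("splits are disjoint, covering and seed-deterministic (property)", {
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    ids <- sprintf("r%04d", sample(9999, n))
    seed <- sample(1000, 1)
    s1 <- makeSplit(ids, seed = seed)
    s2 <- makeSplit(ids, seed = seed)
    expect_identical(s1@trainIds, s2@trainIds)
    expect_identical(s1@testIds, s2@testIds)
    all_ids <- c(s1@trainIds, s1@valIds, s1@testIds)
    expect_equal(sort(all_ids), sort(ids))
    expect_equal(anyDuplicated(all_ids), 0L)
  }
})

test_that("stratified splits preserve per-class proportions within one record", {
  ids <- sprintf("id%03d", 1:120)
  strata <- rep(c("a", "b", "c"), times = c(72, 36, 12))
  s <- makeSplit(ids, seed = 3L, strata = strata)
  for (cl in c("a", "b", "c")) {
    clIds <- ids[strata == cl]
    nTr <- sum(s@trainIds %in% clIds)
    expect_lte(abs(nTr - 0.6 * length(clIds)), 1)
  }
})

test_that("split manifest JSON round-trips", {
  s <- makeSplit(sprintf("id%02d", 1:20), seed = 7L)
  f <- withr::local_tempfile(fileext = ".json")
  writeSplitManifest(s, f)
  s2 <- readSplitManifest(f)
  expect_identical(s2@trainIds, s@trainIds)
  expect_identical(s2@valIds, s@valIds)
  expect_identical(s2@testIds, s@testIds)
  expect_identical(s2@seed, 7L)
})
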