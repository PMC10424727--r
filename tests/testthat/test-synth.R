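test_that("zero-variance sinus gives uniformly spaced peaks with the exact count", {
  out <- simulateRecord(rhythmSpec("sinus", rrSd = 0, seed = 3), 10, 300)
  tr <- out$truth@rPeakTimes
  t0 <- tr[1]
  expect_equal(length(tr), floor((10 - 0.002 - t0) / 0.8) + 1)
  expect_equal(max(abs(diff(tr) - 0.8)), 0)
  # mean heart rate matches 60 / meanRR
  hr <- 60 / mean(diff(tr))
  expect_lt(abs(hr - 60 / 0.8) / (60 / 0.8), 0.05)
})

test_that("generation is deterministic for a fixed spec and seed", {
  a <- simulateRecord(rhythmSpec("af", seed = 11), 10, 300)
  b <- simulateRecord(rhythmSpec("af", seed = 11), 10, 300)
  expect_identical(ecgSignal(a$record), ecgSignal(b$record))
  expect_identical(a$truth@rPeakTimes, b$truth@rPeakTimes)
  c_ <- simulateRecord(rhythmSpec("af", seed = 12), 10, 300)
  expect_false(identical(ecgSignal(a$record), ecgSignal(c_$record)))
})

test_that("AF RR series is irregular: lag-1 autocorrelation near zero", {
  out <- simulateRecord(rhythmSpec("af", seed = 21), 120, 300)
  rr <- diff(out$truth@rPeakTimes)
  expect_gte(length(rr), 100)
  r1 <- stats::acf(rr, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1), 0.2)
})

test_that("rhythm templates: AF drops the P bump, sinus keeps it", {
  expect_false(rhythmSpec("af")@pWave)
  expect_true(rhythmSpec("sinus")@pWave)
  expect_identical(rhythmSpec("af")@rrModel, "irregular")
  # irregular model enforces rrSd >= 0.2 * meanRR (the spreading-cloud regime)
  expect_gte(rhythmSpec("af", meanRR = 1.0)@rrSd, 0.2)
  expect_equal(rhythmSpec("tachy")@meanRR, 0.45)
  expect_equal(rhythmSpec("brady")@meanRR, 1.2)
})

test_that("parameter bounds are enforced", {
  expect_error(simulateRecord(rhythmSpec("sinus"), 3, 300), "durationS")
  expect_error(simulateRecord(rhythmSpec("sinus"), 10, 50), "fs")
  expect_error(rhythmSpec("sinus", meanRR = 2.5), "meanRR")
  expect_error(new("RhythmSpec", classId = "af", meanRR = 0.8, rrSd = 0.01,
                   rrModel = "irregular", pWave = FALSE, noiseSd = 0,
                   baselineWanderAmp = 0, seed = 1L), "irregular")
})

test_that("simulateDataset delivers the requested class mix with unique ids", {
  ds <- getFixture("mix100", function()
    simulateDataset(c(sinus = 60, af = 10, tachy = 15, brady = 15),
                    dialect = "cinc2017", seed = 7, durationS = 10))
  expect_length(ds$records, 100)
  expect_equal(anyDuplicated(recordIds(ds$records)), 0L)
  rhythms <- vapply(ds$truths, function(t) t@rhythmLabel, character(1))
  expect_equal(sort(table(rhythms)),
               sort(table(c(rep("sinus", 60), rep("af", 10),
                            rep("tachy", 15), rep("brady", 15)))),
               ignore_attr = TRUE)
  # imbalanced mix: AF under 10%, normal near 60%, as requested
  labs <- firstLabels(ds$records)
  expect_equal(mean(labs == "A"), 0.10)
  expect_equal(mean(labs == "N"), 0.60)
  expect_error(simulateDataset(c(sinus = 0)), "at least one")
})

test_that("the 12-lead dialect uses 12 leads and rates from the 257-1000 Hz pool", {
  ds <- simulateDataset(c(sinus = 3, af = 3), dialect = "cinc2020",
                        seed = 9, durationS = 6)
  expect_true(all(vapply(ds$records, function(r) nrow(ecgSignal(r)), 1L) == 12L))
  fss <- vapply(ds$records, samplingRate, 1)
  expect_true(all(fss %in% c(257, 500, 1000)))
  expect_setequal(unique(unlist(lapply(ds$records, recordLabels))),
                  c("SNR", "AF"))
})

test_that("synthetic output passes the I/O round trip", {
  ds <- simulateDataset(c(sinus = 2, af = 2), dialect = "synthetic",
                        seed = 10, durationS = 6)
  d <- withr::local_tempdir()
  writeDataset(ds, d, dialect = "synthetic")
  expect_true(file.exists(file.path(d, "groundtruth.json")))
  back <- loadDataset(d, dialect = "synthetic")
  expect_length(back, 4)
  orig <- ds$records[order(recordIds(ds$records))]
  for (i in seq_along(back)) {
    expect_identical(recordLabels(back[[i]]), recordLabels(orig[[i]]))
    expect_lt(max(abs(ecgSignal(back[[i]]) - ecgSignal(orig[[i]]))), 1e-3)
  }
})
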