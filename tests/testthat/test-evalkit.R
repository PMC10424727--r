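test_that("perfect predictions score 1 on every metric", {
  sch <- schemeFor(c("a", "b", "c"))
  truth <- sample(c("a", "b", "c"), 60, replace = TRUE)
  rep_ <- computeMetrics(truth, truth, sch)
  expect_equal(unname(rep_@macro[c("f1", "sensitivity", "specificity")]),
               c(1, 1, 1))
  expect_true(all(rep_@perClass$f1 == 1))
})

test_that("the textbook formula case: TP=FP=FN=1 gives precision/recall/F1 = 0.5", {
  sch <- schemeFor(c("pos", "neg", "other"))
  truth <- c("pos", "pos", "neg", "other")
  pred <- c("pos", "neg", "pos", "other")
  rep_ <- computeMetrics(truth, pred, sch)
  expect_equal(rep_@perClass["pos", "precision"], 0.5)
  expect_equal(rep_@perClass["pos", "recall"], 0.5)
  expect_equal(rep_@perClass["pos", "f1"], 0.5)
})

test_that("zero-division conventions: absent never-predicted classes score 1, failed ones 0", {
  sch <- schemeFor(c("a", "b", "ghost"))
  truth <- c("a", "a", "b")
  rep_ <- computeMetrics(truth, c("a", "a", "b"), sch)
  expect_equal(rep_@perClass["ghost", "f1"], 1)
  rep2 <- computeMetrics(truth, c("a", "a", "a"), sch)  # b never predicted
  expect_equal(rep2@perClass["b", "precision"], 0)
  expect_equal(rep2@perClass["b", "f1"], 0)
})

test_that("computeMetrics agrees with the brute-force oracle (multiclass and multilabel)", {
  set.seed(42)
  classes <- c("w", "x", "y", "z")
  sch <- schemeFor(classes)
  for (rep_i in 1:5) {
    truth <- sample(classes, 200, replace = TRUE)
    pred <- sample(classes, 200, replace = TRUE)
    ours <- computeMetrics(truth, pred, sch)
    oracle <- bruteForceMetrics(truth, pred, classes)
    expect_equal(unname(ours@macro["f1"]), unname(oracle["f1"]))
    expect_equal(unname(ours@macro["sensitivity"]), unname(oracle["recall"]))
    expect_equal(unname(ours@macro["specificity"]),
                 unname(oracle["specificity"]))
  }
  schM <- schemeFor(classes, mode = "multilabel")
  for (rep_i in 1:5) {
    truth <- lapply(1:150, function(i)
      sample(classes, sample(1:3, 1)))
    pred <- lapply(1:150, function(i)
      sample(classes, sample(0:3, 1)))
    ours <- computeMetrics(truth, pred, schM)
    oracle <- bruteForceMetrics(truth, pred, classes)
    expect_equal(unname(ours@macro["f1"]), unname(oracle["f1"]))
    expect_equal(unname(ours@macro["specificity"]),
                 unname(oracle["specificity"]))
  }
  expect_error(computeMetrics(c("a", "b"), "a", sch), "same length")
})

test_that("macro metrics are invariant to class relabeling", {
  classes <- c("a", "b", "c")
  truth <- sample(classes, 120, replace = TRUE)
  pred <- sample(classes, 120, replace = TRUE)
  swap <- c(a = "c", b = "a", c = "b")
  m1 <- computeMetrics(truth, pred, schemeFor(classes))@macro
  m2 <- computeMetrics(unname(swap[truth]), unname(swap[pred]),
                       schemeFor(classes))@macro
  expect_equal(m1, m2)
})

test_that("cross-validation partitions records and reports mean with population SD", {
  set.seed(3)
  labels <- as.list(sample(rep(c("a", "b"), c(700, 300))))
  records <- as.list(seq_len(1000))  # payload is irrelevant for this factory
  seenVal <- integer()
  factory <- function(trainRecords, trainLabels) {
    maj <- names(which.max(table(unlist(trainLabels))))
    function(newRecords) {
      seenVal <<- c(seenVal, unlist(newRecords))
      rep(maj, length(newRecords))
    }
  }
  rep_ <- crossValidate(records, factory, k = 5, seed = 2,
                        scheme = schemeFor(c("a", "b")), labels = labels)
  # every record appears in exactly one validation fold
  expect_equal(sort(seenVal), 1:1000)
  expect_equal(table(rep_@cv$fold_assignment),
               table(rep(1:5, 200)), ignore_attr = TRUE)
  # constant majority classifier: fold-wise majority-class specificity is 0
  # in every stratified fold, so its SD across folds is 0
  expect_equal(unname(rep_@cv$sd["specificity"]), 0)
  expect_true(all(rep_@cv$sd >= 0))
  # population SD: k in the divisor
  f1s <- rep_@cv$folds$f1
  expect_equal(unname(rep_@cv$sd["f1"]),
               sqrt(mean((f1s - mean(f1s))^2)))
  expect_warning(
    crossValidate(records[1:10], factory, k = 5, seed = 2,
                  scheme = schemeFor(c("a", "b", "ghost")),
                  labels = labels[1:10]),
    "missing")
})

test_that("per-source table reports macro-F1 and mean signal length per source", {
  mk <- function(id, src, secs) EcgRecord(id, matrix(rnorm(secs * 100), 1),
                                          fs = 100, labels = "a",
                                          source = src)
  recs <- list(mk("a1", "S1", 10), mk("a2", "S1", 20),
               mk("b1", "S2", 30), mk("b2", "S2", 30))
  truth <- c("a", "b", "a", "b")
  sch <- schemeFor(c("a", "b"))
  tab <- perSourceReport(recs, truth, c("a", "b", "b", "a"), sch)
  expect_equal(tab$mean_length_s[tab$source == "S1"], 15)
  expect_equal(tab$mean_length_s[tab$source == "S2"], 30)
  expect_equal(tab$f1[tab$source == "S1"], 1)
  expect_equal(tab$f1[tab$source == "S2"], 0)
  # two sources with identical records score identically
  tab2 <- perSourceReport(list(mk("x", "P", 10), mk("y", "Q", 10)),
                          c("a", "a"), c("a", "a"), sch)
  expect_equal(tab2$f1[1], tab2$f1[2])
})

test_that("the efficiency report obeys its arithmetic invariants", {
  recs <- as.list(1:4)
  burn <- function(x) sum(sqrt(seq_len(4e5)))
  burn(1)  # warm up timers/allocator
  rep_ <- profilePipeline(burn, burn, recs, carbonIntensity = 0.4)
  expect_equal(rep_@timeTotalMs,
               rep_@timeProcessingMs + rep_@timePredictingMs)
  expect_equal(rep_@co2G, rep_@energyWh * 0.4)
  expect_true(rep_@estimator)
  rep0 <- profilePipeline(burn, burn, recs, carbonIntensity = 0)
  expect_equal(rep0@co2G, 0)
  # a much larger record count must draw more total energy
  rep2 <- profilePipeline(burn, burn, rep(recs, 8), carbonIntensity = 0.4)
  expect_gt(rep2@energyWh, rep_@energyWh)
})

test_that("reports serialize to JSON", {
  sch <- schemeFor(c("a", "b"))
  rep_ <- computeMetrics(c("a", "b"), c("a", "b"), sch)
  f <- withr::local_tempfile(fileext = ".json")
  writeReports(f, evalReport = rep_)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$metrics$macro$f1, 1)
})
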