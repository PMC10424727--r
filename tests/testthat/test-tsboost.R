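smallFeatureSet <- function() {
  getFixture("feat_small", function() {
    ds <- simulateDataset(c(sinus = 30, af = 30, tachy = 30, brady = 30),
                          dialect = "synthetic", seed = 21, durationS = 10)
    list(records = ds$records, labels = firstLabels(ds$records),
         table = extractFeatures(ds$records))
  })
}

test_that("no excluded feature family appears in the extracted columns", {
  tab <- smallFeatureSet()$table
  banned <- c("entropy", "matrix_profile", "number_cwt_peaks",
              "partial_autocorrelation", "agg_linear_trend",
              "augmented_dickey_fuller")
  for (b in banned) expect_length(grep(b, names(tab)), 0)
  # sanity: the canonical groups of the efficient set are present
  for (g in c("fft_coefficient", "ratio_beyond_r_sigma", "autocorrelation",
              "lempel_ziv_complexity", "quantile", "number_peaks",
              "cwt_coefficients", "spkt_welch_density"))
    expect_gt(length(grep(paste0("^", g, "__"), names(tab))), 0)
  expect_equal(anyDuplicated(names(tab)), 0L)
})

test_that("feature extraction is deterministic and respects invariances", {
  rec <- smallFeatureSet()$records[[1]]
  t1 <- extractFeatures(list(rec, rec))
  expect_equal(unname(unlist(t1[1, ])), unname(unlist(t1[2, ])))
  # time reversal leaves reversal-invariant features unchanged
  rev_ <- EcgRecord("rev", ecgSignal(rec)[, ncol(ecgSignal(rec)):1,
                                          drop = FALSE],
                    samplingRate(rec))
  t2 <- extractFeatures(list(rec, rev_))
  for (f in c("variance", "standard_deviation", "abs_energy", "maximum",
              "minimum", "quantile__q_0.1", "ratio_beyond_r_sigma__r_1"))
    expect_equal(t2[1, f], t2[2, f], tolerance = 1e-9)
})

test_that("imputation writes exactly -999 and the variance filter drops constants", {
  tab <- data.frame(a = c(1, NA, 3), b = c(5, 5, 5), c = c(0.1, 0.4, NaN))
  out <- imputeAndFilter(tab)
  expect_false("b" %in% names(out))
  expect_identical(out$a[2], -999)
  expect_identical(out$c[3], -999)
  expect_error(imputeAndFilter(tab, varThreshold = Inf), "every feature")
})

test_that("the variance filter is fitted on training rows only (leak freedom)", {
  fx <- smallFeatureSet()
  tab <- fx$table
  tr <- 1:80
  a <- imputeAndFilter(tab, trainRows = tr)
  # replacing the held-out rows must not change the retained columns
  tab2 <- tab
  tab2[81:120, ] <- tab2[sample(80, 40, replace = TRUE), ]
  b <- imputeAndFilter(tab2, trainRows = tr)
  expect_identical(attr(a, "retainedColumns"), attr(b, "retainedColumns"))
  # and a persisted column list is re-applied verbatim
  c_ <- imputeAndFilter(tab, columns = attr(a, "retainedColumns"))
  expect_identical(names(c_), attr(a, "retainedColumns"))
})

test_that("every sampled configuration lies inside the search space bounds", {
  fx <- smallFeatureSet()
  ft <- imputeAndFilter(fx$table)
  fit <- getFixture("ts_fit", function()
    tuneAndFit(ft, fx$labels, nTrials = 8, seed = 3))
  tr <- fit$trials
  expect_equal(nrow(tr), 8)
  expect_true(all(tr$min_features_to_select >= 10 &
                    tr$min_features_to_select <= ncol(ft)))
  expect_true(all(tr$max_depth >= 2 & tr$max_depth <= 100))
  for (p in c("gamma", "eta", "scale_pos_weight", "reg_lambda",
              "reg_alpha"))
    expect_true(all(tr[[p]] >= 1e-3 & tr[[p]] <= 1e3))
  expect_lte(length(fit$features), max(tr$min_features_to_select))
})

test_that("a single-trial budget still returns a usable model", {
  fx <- smallFeatureSet()
  ft <- imputeAndFilter(fx$table)
  fit1 <- tuneAndFit(ft, fx$labels, nTrials = 1, seed = 5)
  expect_equal(nrow(fit1$trials), 1)
  pred <- predictTsBoost(fit1, ft)
  expect_length(pred$decisions, nrow(ft))
  expect_error(tuneAndFit(ft, rep("one", nrow(ft))), "two classes")
})

test_that("tuning is deterministic for a fixed seed", {
  fx <- smallFeatureSet()
  ft <- imputeAndFilter(fx$table)
  f1 <- tuneAndFit(ft, fx$labels, nTrials = 3, seed = 9)
  f2 <- tuneAndFit(ft, fx$labels, nTrials = 3, seed = 9)
  expect_equal(f1$trials, f2$trials)
  expect_identical(f1$features, f2$features)
})

test_that("grouped importance sums within prefixes, normalized and sorted", {
  ns <- asNamespace("ecgtracks")
  out <- ns$aggregateImportance(
    c("fft_coefficient__a", "fft_coefficient__b", "quantile__q_0.5"),
    c(0.2, 0.1, 0.7))
  expect_equal(out$importance[out$group == "fft_coefficient"], 0.3)
  expect_equal(out$n_features[out$group == "fft_coefficient"], 2)
  expect_equal(sum(out$importance), 1)
  expect_true(all(diff(out$importance) <= 0))
  # and on a real fit: normalization and group sizes
  fit <- getFixture("ts_fit", function() stop("fixture must exist"))
  imp <- featureImportance(fit)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(diff(imp$importance) <= 0))
  expect_error(featureImportance(list()), "fitted")
})

test_that("peak/spectral feature groups dominate AF-vs-sinus discrimination", {
  ds <- getFixture("afsin_feat", function() {
    d <- simulateDataset(c(sinus = 40, af = 40), dialect = "synthetic",
                         seed = 27, durationS = 10)
    list(labels = firstLabels(d$records),
         table = imputeAndFilter(extractFeatures(d$records)))
  })
  fit <- tuneAndFit(ds$table, ds$labels, nTrials = 4, seed = 7)
  imp <- featureImportance(fit)
  peakish <- c("fft_coefficient", "ratio_beyond_r_sigma", "number_peaks",
               "spkt_welch_density", "autocorrelation", "cwt_coefficients",
               "agg_autocorrelation", "standard_deviation", "variance",
               "change_quantiles", "cid_ce", "c3")
  expect_gt(length(intersect(utils::head(imp$group, 5), peakish)), 0)
})
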