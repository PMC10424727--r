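specOf <- function(d, id) jsonlite::fromJSON(d$spec[d$id == id])

test_that("the 12-block CNN audits: block count, kernel and channel schedules", {
  m <- buildCnn1d(4, inputLen = 8999L)
  d <- describeModel(m)
  blocks <- grep("^block\\d+$", d$id, value = TRUE)
  expect_length(blocks, 12)
  kernels <- vapply(1:12, function(i)
    specOf(d, paste0("block", i, ".conv"))$kernel, 1)
  expect_equal(kernels, c(20, rep(5, 5), rep(3, 6)))
  chans <- vapply(1:12, function(i)
    specOf(d, paste0("block", i, ".conv"))$out_channels, 1)
  expect_equal(chans[1], 256)
  expect_equal(chans[12], 32)
  expect_true(all(diff(chans) <= 0))  # monotone decrease
  # every block: BN momentum 0.99, max pool 2/2, dropout 0.3
  for (i in 1:12) {
    expect_equal(specOf(d, paste0("block", i, ".bn"))$momentum, 0.99)
    expect_equal(specOf(d, paste0("block", i, ".pool"))$kernel, 2)
    expect_equal(specOf(d, paste0("block", i, ".drop"))$p, 0.3)
    expect_equal(specOf(d, paste0("block", i, ".conv"))$stride, 1)
    expect_equal(specOf(d, paste0("block", i, ".conv"))$padding, 0)
  }
  # head: average pool kernel 1 stride 2, then flatten + fully connected
  expect_equal(specOf(d, "avgpool")$kernel, 1)
  expect_equal(specOf(d, "avgpool")$stride, 2)
  expect_equal(specOf(d, "fc")$out_features, 4)
})

test_that("the 1D ResNet audits: stem, four blocks, dual-pooling head", {
  m <- buildResnet1d(4)
  d <- describeModel(m)
  expect_equal(specOf(d, "stem_conv")$kernel, 15)
  expect_equal(specOf(d, "stem_conv")$out_channels, 64)
  expect_length(grep("^block\\d+$", d$id), 4)
  expect_true("global_avgmax_concat1d" %in% d$type)
  # concatenated head dimension is twice the last block's channel count
  lastW <- specOf(d, "block4")$out_channels
  expect_equal(specOf(d, "fc")$in_features, 2 * lastW)
  expect_equal(lastW, 256)
})

test_that("1D CNN forward contract: 9000-sample single-lead input gives 4 finite logits", {
  m <- getFixture("cnn_small", function()
    buildCnn1d(4, inputLen = 8999L, widthMult = 1 / 16, seed = 2))
  rec <- simulateRecord(rhythmSpec("sinus", seed = 40), 30, 300)$record
  p <- suppressWarnings(predictModel(m, list(rec)))
  expect_equal(dim(p$scores), c(1L, 4L))
  expect_true(all(is.finite(p$scores)))
  expect_equal(sum(p$scores), 1, tolerance = 1e-6)
})

test_that("too-short input for the 12-block CNN reports the computed minimum length", {
  expect_error(buildCnn1d(4, inputLen = 2999L), "8332")
})

test_that("residual block passes input through when its weights are zeroed", {
  ns <- asNamespace("ecgtracks")
  blk <- ns$blockResidual1d(6, 6, k = 5, dropout = 0)
  for (ch in blk$children) {
    if (length(ch$params)) {
      for (nm in names(ch$params)) ch$params[[nm]][] <-
          if (nm == "gamma") 1 else 0
    }
  }
  x <- array(rnorm(6 * 40 * 2), c(6, 40, 2))
  y <- blk$forward(x, training = FALSE)
  expect_equal(y, pmax(x, 0), tolerance = 1e-12)
})

test_that("image backbone audits: stage layouts and class-sized heads", {
  dnet <- buildImage2d("densenet121", 4)
  dd <- describeModel(dnet)
  for (bi in 1:4) {
    nl <- sum(grepl(paste0("^denseblock", bi, "\\.layer\\d+$"), dd$id))
    expect_equal(nl, c(6, 12, 24, 16)[bi])
  }
  expect_equal(specOf(dd, "conv0")$kernel, 7)
  expect_equal(specOf(dd, "fc")$out_features, 4)
  # bottleneck factor 4: the 1x1 conv in each dense layer emits 4 x growth
  l1 <- specOf(dd, "denseblock1.layer1.conv1")
  expect_equal(l1$out_channels, 4 * 32)
  rnet <- buildImage2d("resnet50", 7)
  rd <- describeModel(rnet)
  for (si in 1:4) {
    nb <- sum(grepl(paste0("^layer", si, "\\.block\\d+$"), rd$id))
    expect_equal(nb, c(3, 4, 6, 3)[si])
  }
  expect_equal(specOf(rd, "fc")$out_features, 7)
  expect_error(buildImage2d("vgg16", 4))
})

test_that("untrained image classifier predicts near-uniform classes", {
  m <- getFixture("dnet_tiny", function()
    buildImage2d("densenet121", 4, inputSize = 32L, widthMult = 1 / 8,
                 seed = 3))
  set.seed(5)
  imgs <- lapply(1:20, function(i)
    new("PoincareImage", pixels = matrix(runif(32 * 32), 32),
        axisMin = 0.2, axisMax = 1.6, markerRadius = 2L))
  p <- suppressWarnings(predictModel(m, imgs))
  expect_equal(rowSums(p$scores), rep(1, 20), tolerance = 1e-6)
  ent <- -mean(rowSums(p$scores * log(pmax(p$scores, 1e-12))))
  expect_gt(ent, 0.6 * log(4))
})

test_that("multilabel scores are independent probabilities in [0, 1]", {
  m <- buildResnet1d(3, inputLen = 999L, baseWidth = 4L,
                     mode = "multilabel", seed = 4)
  xs <- lapply(1:4, function(i) rnorm(1000))
  p <- suppressWarnings(predictModel(m, xs))
  expect_true(all(p$scores >= 0 & p$scores <= 1))
  expect_true(is.list(p$decisions))
})

test_that("batch prediction equals concatenated single-record predictions", {
  m <- getFixture("res_tiny", function()
    buildResnet1d(4, inputLen = 999L, baseWidth = 4L, seed = 6))
  xs <- lapply(1:5, function(i) rnorm(1000))
  pb <- suppressWarnings(predictModel(m, xs))$scores
  ps <- do.call(rbind, lapply(xs, function(x)
    suppressWarnings(predictModel(m, list(x)))$scores))
  expect_equal(pb, ps, tolerance = 1e-10)
})

test_that("predictions are invariant to lead-wise amplitude scaling", {
  m <- getFixture("res_tiny", function()
    buildResnet1d(4, inputLen = 999L, baseWidth = 4L, seed = 6))
  rec <- simulateRecord(rhythmSpec("sinus", seed = 8), 5, 200)$record
  rec2 <- EcgRecord("scaled", 7.7 * ecgSignal(rec) + 0.3, samplingRate(rec))
  p1 <- suppressWarnings(predictModel(m, list(rec)))$scores
  p2 <- suppressWarnings(predictModel(m, list(rec2)))$scores
  expect_equal(p1, p2, tolerance = 1e-5)
})

test_that("an untrained model warns when asked to predict", {
  m <- buildResnet1d(2, inputLen = 999L, baseWidth = 4L)
  expect_warning(predictModel(m, list(rnorm(1000))), "not been trained")
})

test_that("training is seed-deterministic: identical epoch-1 loss across runs", {
  set.seed(99)
  xs <- lapply(1:16, function(i) rnorm(800))
  labs <- as.list(rep(c("a", "b"), 8))
  run <- function() {
    m <- buildResnet1d(2, inputLen = 799L, baseWidth = 4L,
                       classes = c("a", "b"), seed = 5)
    m <- trainModel(m, xs, xs[1:4], trainLabels = labs,
                    valLabels = labs[1:4], epochs = 1, batchSize = 8,
                    seed = 11)
    m@history$train_loss[1]
  }
  expect_identical(run(), run())
})

test_that("the 12-block CNN optimizes on separable data (loss decreases)", {
  ds <- getFixture("cnn_bin", function()
    simulateDataset(c(tachy = 12, brady = 12), dialect = "synthetic",
                    seed = 19, durationS = 30))
  labs <- firstLabels(ds$records)
  m <- buildCnn1d(2, inputLen = 8999L, widthMult = 1 / 16,
                  classes = sort(unique(labs)), seed = 19)
  m <- trainModel(m, ds$records, ds$records[1:6],
                  trainLabels = as.list(labs), valLabels = as.list(labs[1:6]),
                  epochs = 4, batchSize = 8, lr = 1e-3, seed = 19)
  h <- m@history
  expect_lt(h$train_loss[4], h$train_loss[1])
})

test_that("a non-finite loss aborts with a training error and diagnostics", {
  xs <- lapply(1:8, function(i) {
    v <- rnorm(500)
    v[100] <- NaN  # corrupt input propagates to a non-finite loss
    v
  })
  labs <- as.list(rep(c("a", "b"), 4))
  m <- buildResnet1d(2, inputLen = 499L, baseWidth = 4L,
                     classes = c("a", "b"))
  expect_error(
    suppressWarnings(trainModel(m, xs, xs[1:2], trainLabels = labs,
                                valLabels = labs[1:2], epochs = 2,
                                batchSize = 4, seed = 1)),
    "diverged|non-finite")
})

test_that("weight checkpoints round-trip and refuse mismatched architectures", {
  m <- buildResnet1d(3, inputLen = 499L, baseWidth = 4L,
                     classes = c("a", "b", "c"), seed = 21)
  xs <- lapply(1:3, function(i) rnorm(500))
  p1 <- suppressWarnings(predictModel(m, xs))$scores
  f <- withr::local_tempfile(fileext = ".rds")
  saveModelWeights(m, f)
  m2 <- buildResnet1d(3, inputLen = 499L, baseWidth = 4L,
                      classes = c("a", "b", "c"), seed = 22)
  p2raw <- suppressWarnings(predictModel(m2, xs))$scores
  expect_false(isTRUE(all.equal(p1, p2raw)))
  m2 <- loadModelWeights(m2, f)
  expect_true(m2@trained)
  expect_equal(predictModel(m2, xs)$scores, p1, tolerance = 1e-12)
  mc <- buildCnn1d(3, inputLen = 8999L, widthMult = 1 / 16)
  expect_error(loadModelWeights(mc, f), "does not match")
})

test_that("model description JSON dump is complete and machine-readable", {
  m <- getFixture("res_tiny", function()
    buildResnet1d(4, inputLen = 999L, baseWidth = 4L, seed = 6))
  f <- withr::local_tempfile(fileext = ".json")
  writeModelDescription(m, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$arch, "resnet1d")
  expect_equal(length(j$classes), 4)
  expect_true(all(c("id", "type", "spec") %in% names(j$layers)))
  expect_gt(j$n_parameters, 0)
})
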