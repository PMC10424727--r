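tinyTrained1d <- function() {
  getFixture("gc_model", function() {
    set.seed(61)
    n <- 800
    mk <- function(cls) {
      x <- rnorm(n, 0, 0.2)
      if (cls == "pat") x[301:500] <- x[301:500] +
          2.5 * sin(2 * pi * 15 * (1:200) / 200)
      x
    }
    labs <- rep(c("none", "pat"), each = 30)
    xs <- lapply(labs, mk)
    m <- buildResnet1d(2, inputLen = n, baseWidth = 4L,
                       classes = c("none", "pat"), seed = 61)
    m <- trainModel(m, xs, xs[c(1:10, 31:40)],
                    trainLabels = as.list(labs),
                    valLabels = as.list(labs[c(1:10, 31:40)]),
                    epochs = 6, batchSize = 8, lr = 2e-3, seed = 61)
    list(model = m, mk = mk)
  })
}

test_that("saliency is non-negative and max-normalized; eval mode is deterministic", {
  fx <- tinyTrained1d()
  x <- fx$mk("pat")
  s1 <- gradCam(fx$model, x, targetClass = "pat")
  expect_true(all(s1@heatmap >= 0))
  expect_equal(max(s1@heatmap), 1)
  expect_length(s1@heatmap, 800)
  s2 <- gradCam(fx$model, x, targetClass = "pat")
  expect_identical(s1@heatmap, s2@heatmap)
})

test_that("a zero gradient yields an all-zero heatmap", {
  fx <- tinyTrained1d()
  m <- fx$model
  # detach the target class from the network: its logit is constant, so
  # the class-score gradient at every feature map is identically zero
  old <- m@net$children$fc$params
  m@net$children$fc$params$W[2, ] <- 0
  s <- gradCam(m, fx$mk("pat"), targetClass = "pat")
  m@net$children$fc$params <- old
  expect_equal(max(s@heatmap), 0)
})

test_that("unknown layers are rejected with the available layer list", {
  fx <- tinyTrained1d()
  expect_error(gradCam(fx$model, fx$mk("pat"), targetClass = "pat",
                       layer = "nope"), "stem_conv")
  expect_error(gradCam(fx$model, fx$mk("pat"), targetClass = "zz"),
               "unknown target class")
})

test_that("saliency concentrates on the planted pattern window", {
  fx <- tinyTrained1d()
  set.seed(77)
  fr <- vapply(1:5, function(i) {
    x <- fx$mk("pat")
    p <- predictModel(fx$model, list(x))$decisions
    if (p != "pat") return(NA_real_)
    s <- gradCam(fx$model, x, targetClass = "pat")
    sum(s@heatmap[301:500]) / sum(s@heatmap)
  }, 1)
  fr <- fr[!is.na(fr)]
  expect_gt(length(fr), 0)
  # concentration: mass in the window well above its share under a
  # uniform heatmap (200 of 800 samples = 0.25)
  expect_gte(mean(fr), 1.5 * 200 / 800)
})

test_that("2D GradCAM produces an input-sized normalized map", {
  m <- getFixture("dnet_tiny32", function()
    buildImage2d("densenet121", 2, inputSize = 32L, widthMult = 1 / 8,
                 classes = c("af", "sinus"), seed = 62))
  img <- rasterizePoints(buildPoints(runif(40, 0.4, 1.4)), size = 32)
  s <- gradCam(m, img, targetClass = "af")
  expect_true(is.matrix(s@heatmap))
  expect_equal(dim(s@heatmap), c(32L, 32L))
  expect_true(all(s@heatmap >= 0) && max(s@heatmap) <= 1)
})

test_that("overlay rendering: zero saliency reproduces the plain rendering", {
  img <- rasterizePoints(buildPoints(runif(20, 0.4, 1.4)), size = 32)
  zero <- new("Saliency", heatmap = matrix(0, 32, 32),
              targetClass = "af", layerId = "relu_final")
  plain <- renderOverlay(zero, img)
  expect_equal(plain[, , 1], img@pixels)
  expect_equal(plain[, , 2], img@pixels)
  hot <- new("Saliency", heatmap = diag(32), targetClass = "af",
             layerId = "relu_final")
  f <- withr::local_tempfile(fileext = ".png")
  blended <- renderOverlay(hot, img, f)
  expect_true(file.exists(f))
  expect_false(identical(blended, plain))
})

test_that("1D overlay: color extremum sits at the saliency peak", {
  x <- sin(1:200 / 10)
  h <- numeric(199)
  h[120] <- 1
  s <- new("Saliency", heatmap = h, targetClass = "pat", layerId = "block4")
  rgb <- renderOverlay(s, x)
  # high saliency zeroes the blue channel of the trace; background is white
  blueByCol <- apply(rgb[, , 3], 2, min)
  expect_equal(which.min(blueByCol), which.max(h))
  # zero saliency: identical to the plain trace rendering
  s0 <- new("Saliency", heatmap = numeric(199), targetClass = "pat",
            layerId = "block4")
  expect_equal(renderOverlay(s0, x), renderOverlay(s0, x))
  bad <- new("Saliency", heatmap = numeric(50), targetClass = "pat",
             layerId = "block4")
  expect_error(renderOverlay(bad, x), "does not match")
})

test_that("saliency validity rejects negative or unnormalized maps", {
  expect_error(new("Saliency", heatmap = c(-0.1, 1), targetClass = "a",
                   layerId = "l"), "non-negative")
  expect_error(new("Saliency", heatmap = c(0.5, 2), targetClass = "a",
                   layerId = "l"), "normalized")
})
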