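# The three model families and their training loop.
#
# cnn1d    : 12 conv blocks (conv -> BN(momentum .99) -> ReLU -> maxpool 2/2
#            -> dropout .3), channels 256 -> 32, kernels [20, 5x5, 3x6],
#            then avg-pool (k1, stride 2), flatten, fully connected.
# resnet1d : stem conv k15/64ch -> BN -> ReLU -> maxpool, four residual
#            blocks, concatenated global average+max pooling head, FC.
# image2d  : standard ResNet50 / DenseNet121 image backbones trained from
#            scratch on rasterized Poincare diagrams, final layer sized to
#            the class count. A width multiplier scales channel counts for
#            CPU-sized experiments without changing the layer structure.

cnn1dKernelSchedule <- function() c(20L, rep(5L, 5), rep(3L, 6))
cnn1dChannelSchedule <- function() {
  c(256L, 256L, 128L, 128L, 128L, 64L, 64L, 64L, 64L, 32L, 32L, 32L)
}

# minimal input length (after differencing) the 12-block CNN can digest
cnn1dMinLen <- function(kernels = cnn1dKernelSchedule()) {
  need <- 1L
  for (k in rev(kernels)) {
    need <- 2L * need - 1L       # invert ceil-mode maxpool k2 s2
    need <- need + k - 1L        # invert valid convolution
  }
  need
}

#' Build the 12-block 1D CNN
#'
#' @param nClasses Number of output classes (>= 2).
#' @param nLeads Number of input leads (input channels).
#' @param inputLen Fixed input length in samples (after differencing);
#'   the flattened head ties the network to this length.
#' @param widthMult Channel-count multiplier (1 = the full 256->32
#'   schedule); layer structure is unchanged.
#' @param mode "multiclass" or "multilabel".
#' @param classes Class identifiers (length \code{nClasses}).
#' @param dropout Dropout probability per block.
#' @param seed Seed for weight initialization.
#' @return A \linkS4class{ModelBundle}.
#' @export
buildCnn1d <- function(nClasses, nLeads = 1L, inputLen = 8999L,
                       widthMult = 1, mode = "multiclass",
                       classes = NULL, dropout = 0.3, seed = 1L) {
  stopifnot(nClasses >= 2)
  kernels <- cnn1dKernelSchedule()
  chans <- pmax(as.integer(round(cnn1dChannelSchedule() * widthMult)), 16L)
  minLen <- cnn1dMinLen(kernels)
  if (inputLen < minLen)
    stop("input length ", inputLen, " is below the network's minimum ",
         "receptive length of ", minLen, " samples")
  net <- withSeed(as.integer(seed), {
    blocks <- list()
    L <- inputLen
    inC <- as.integer(nLeads)
    for (i in seq_along(kernels)) {
      blocks[[paste0("block", i)]] <- nnSequential(list(
        conv = layerConv1d(inC, chans[i], kernels[i]),
        bn = layerBatchNorm(chans[i], momentum = 0.99),
        relu = layerReLU(),
        pool = layerMaxPool1d(2L, 2L, ceil_mode = TRUE),
        drop = layerDropout(dropout)))
      L <- ceiling((L - kernels[i] + 1L) / 2)
      inC <- chans[i]
    }
    Lfinal <- ceiling(L / 2)  # avg pool kernel 1, stride 2
    c(blocks, list(
      avgpool = layerAvgPool1dK1(2L),
      flatten = layerFlatten(),
      fc = layerDense(inC * Lfinal, as.integer(nClasses))))
  })
  if (is.null(classes)) classes <- paste0("class", seq_len(nClasses))
  new("ModelBundle", arch = "cnn1d",
      hyper = list(kernels = kernels, channels = chans,
                   input_len = as.integer(inputLen),
                   n_leads = as.integer(nLeads), dropout = dropout,
                   width_mult = widthMult, gradcam_layer = "block12",
                   seed = as.integer(seed)),
      net = nnSequential(net), mode = mode, classes = classes,
      inputTransform = list(kind = "diff_z", length = as.integer(inputLen),
                            n_leads = as.integer(nLeads)))
}

#' Build the 1D ResNet
#'
#' Stem: conv kernel 15 to \code{baseWidth} channels, BN, ReLU, max pool;
#' then four residual blocks with widths \code{baseWidth x (1, 2, 3, 4)}
#' (64 to 256 at the default width) each followed by a stride-2 max pool;
#' head: global average and global max pooling concatenated, then FC. The
#' global head makes the network input-length agnostic.
#'
#' @inheritParams buildCnn1d
#' @param baseWidth Stem channel count (64 reproduces the full model).
#' @param kernel Within-block kernel size.
#' @param stemPool Stem max-pool kernel/stride.
#' @export
buildResnet1d <- function(nClasses, nLeads = 1L, inputLen = 2999L,
                          baseWidth = 64L, kernel = 7L, stemPool = 4L,
                          mode = "multiclass", classes = NULL,
                          dropout = 0.3, seed = 1L) {
  stopifnot(nClasses >= 2)
  widths <- as.integer(baseWidth * c(1L, 2L, 3L, 4L))
  net <- withSeed(as.integer(seed), {
    layers <- list(
      stem_conv = layerConv1d(as.integer(nLeads), widths[1], 15L, pad = 7L),
      stem_bn = layerBatchNorm(widths[1], momentum = 0.99),
      stem_relu = layerReLU(),
      stem_pool = layerMaxPool1d(as.integer(stemPool), as.integer(stemPool),
                                 ceil_mode = TRUE))
    inC <- widths[1]
    for (i in 1:4) {
      layers[[paste0("block", i)]] <-
        blockResidual1d(inC, widths[i], k = as.integer(kernel),
                        dropout = dropout)
      layers[[paste0("down", i)]] <- layerMaxPool1d(2L, 2L, ceil_mode = TRUE)
      inC <- widths[i]
    }
    layers$head_pool <- layerGlobalPoolConcat1d()
    layers$fc <- layerDense(2L * inC, as.integer(nClasses))
    layers
  })
  if (is.null(classes)) classes <- paste0("class", seq_len(nClasses))
  new("ModelBundle", arch = "resnet1d",
      hyper = list(stem_kernel = 15L, stem_channels = widths[1],
                   block_widths = widths, kernel = as.integer(kernel),
                   dropout = dropout, base_width = as.integer(baseWidth),
                   gradcam_layer = "block4", seed = as.integer(seed)),
      net = nnSequential(net), mode = mode, classes = classes,
      inputTransform = list(kind = "diff_z", length = as.integer(inputLen),
                            n_leads = as.integer(nLeads)))
}

#' Build a 2D image backbone for Poincare-diagram classification
#'
#' \code{resnet50}: 7x7 stem, four stages of (3, 4, 6, 3) bottleneck blocks
#' with expansion 4. \code{densenet121}: 7x7 stem, dense blocks of
#' (6, 12, 24, 16) BN-ReLU-1x1-BN-ReLU-3x3 layers with growth rate 32 and
#' 0.5-compression transitions. Both end in global average pooling and a
#' fully connected layer sized to \code{nClasses}; weights are randomly
#' initialized (no pre-training).
#'
#' @inheritParams buildCnn1d
#' @param backbone \code{"resnet50"} or \code{"densenet121"}.
#' @param inputSize Input image side in pixels.
#' @param widthMult Channel multiplier (1 = the standard backbone).
#' @export
buildImage2d <- function(backbone = c("densenet121", "resnet50"), nClasses,
                         inputSize = 224L, widthMult = 1,
                         mode = "multiclass", classes = NULL, seed = 1L) {
  backbone <- match.arg(backbone)
  stopifnot(nClasses >= 2)
  sc <- function(x) max(as.integer(round(x * widthMult)), 4L)
  net <- withSeed(as.integer(seed), {
    if (backbone == "densenet121") {
      growth <- sc(32)
      nLayers <- c(6L, 12L, 24L, 16L)
      ch <- 2L * growth
      layers <- list(
        conv0 = layerConv2d(3L, ch, 7L, stride = 2L, pad = 3L),
        bn0 = layerBatchNorm(ch, ndim = 2L, momentum = 0.9),
        relu0 = layerReLU(),
        pool0 = layerMaxPool2d(3L, 2L, pad = 1L))
      for (bi in seq_along(nLayers)) {
        dblk <- list()
        for (li in seq_len(nLayers[bi])) {
          dblk[[paste0("layer", li)]] <- blockDenseLayer2d(ch, growth)
          ch <- ch + growth
        }
        layers[[paste0("denseblock", bi)]] <- nnSequential(dblk)
        if (bi < length(nLayers)) {
          out <- as.integer(ch %/% 2)  # 0.5 compression
          layers[[paste0("transition", bi)]] <- nnSequential(list(
            bn = layerBatchNorm(ch, ndim = 2L, momentum = 0.9),
            relu = layerReLU(),
            conv = layerConv2d(ch, out, 1L),
            pool = layerAvgPool2d(2L, 2L)))
          ch <- out
        }
      }
      layers$bn_final <- layerBatchNorm(ch, ndim = 2L, momentum = 0.9)
      layers$relu_final <- layerReLU()
      layers$gap <- layerGlobalAvgPool2d()
      layers$fc <- layerDense(ch, as.integer(nClasses))
      layers
    } else {
      base <- sc(64)
      stageBlocks <- c(3L, 4L, 6L, 3L)
      layers <- list(
        conv0 = layerConv2d(3L, base, 7L, stride = 2L, pad = 3L),
        bn0 = layerBatchNorm(base, ndim = 2L, momentum = 0.9),
        relu0 = layerReLU(),
        pool0 = layerMaxPool2d(3L, 2L, pad = 1L))
      inC <- base
      for (si in 1:4) {
        mid <- base * 2L^(si - 1L)
        blk <- list()
        for (bi in seq_len(stageBlocks[si])) {
          stride <- if (bi == 1L && si > 1L) 2L else 1L
          blk[[paste0("block", bi)]] <- blockBottleneck2d(inC, mid, stride)
          inC <- 4L * mid
        }
        layers[[paste0("layer", si)]] <- nnSequential(blk)
      }
      layers$gap <- layerGlobalAvgPool2d()
      layers$fc <- layerDense(inC, as.integer(nClasses))
      layers
    }
  })
  if (is.null(classes)) classes <- paste0("class", seq_len(nClasses))
  new("ModelBundle", arch = "image2d",
      hyper = list(backbone = backbone, input_size = as.integer(inputSize),
                   width_mult = widthMult,
                   gradcam_layer = if (backbone == "densenet121")
                     "relu_final" else "layer4",
                   seed = as.integer(seed)),
      net = nnSequential(net), mode = mode, classes = classes,
      inputTransform = list(kind = "poincare",
                            size = as.integer(inputSize)))
}

# ---- input preparation ----

# Convert a list of EcgRecords / PoincareImages into the tensor the model
# expects. 1D models: per-lead first-order difference, z-scored, cropped or
# zero-padded to the configured length. 2D models: Poincare intensity grid
# replicated onto 3 channels.
prepareInputs <- function(model, inputs) {
  tf <- model@inputTransform
  if (tf$kind == "diff_z") {
    L <- tf$length
    C <- tf$n_leads
    x <- array(0, c(C, L, length(inputs)))
    for (i in seq_along(inputs)) {
      rec <- inputs[[i]]
      m <- if (is(rec, "EcgRecord")) transform1d(rec) else
        if (is.null(dim(rec))) matrix(rec, nrow = 1) else rec
      if (nrow(m) != C)
        stop("record ", i, " has ", nrow(m), " lead(s); model expects ", C)
      n <- ncol(m)
      if (n >= L) x[, , i] <- m[, seq_len(L), drop = FALSE]
      else x[, seq_len(n), i] <- m
    }
    x
  } else {
    imgs <- lapply(inputs, function(inp) {
      if (is(inp, "EcgRecord"))
        recordToPoincare(inp, size = tf$size)
      else inp
    })
    sz <- vapply(imgs, function(im) nrow(im@pixels), 1L)
    if (!all(sz == tf$size))
      stop("Poincare image size ", sz[which(sz != tf$size)[1]],
           " does not match model input size ", tf$size)
    poincareBatch(imgs)
  }
}

sliceBatch <- function(x, idx) {
  if (length(dim(x)) == 3) x[, , idx, drop = FALSE]
  else x[, , , idx, drop = FALSE]
}

labelsToY <- function(labels, model) {
  K <- length(model@classes)
  if (model@mode == "multiclass") {
    first <- vapply(labels, function(l) l[1], character(1))
    y <- match(first, model@classes)
    if (anyNA(y)) stop("labels outside the model's class set: ",
                       paste(unique(first[is.na(y)]), collapse = ", "))
    y
  } else {
    y <- matrix(0, K, length(labels))
    for (i in seq_along(labels)) y[match(labels[[i]], model@classes), i] <- 1
    y
  }
}

recordLabelList <- function(inputs) {
  lapply(inputs, function(r) {
    if (!is(r, "EcgRecord")) stop("labels must be supplied explicitly for ",
                                  "non-record inputs")
    r@labels
  })
}

#' Train a model
#'
#' Minibatch Adam on cross-entropy (multiclass) or per-class binary
#' cross-entropy (multilabel); after each epoch the validation macro-F1 is
#' computed and the weight state of the best epoch is restored at the end.
#' Training stops early when validation macro-F1 has not improved for
#' \code{patience} epochs. Deterministic for a fixed \code{seed} (shuffling,
#' dropout and initialization all run under R's RNG).
#'
#' @param model A \linkS4class{ModelBundle}.
#' @param train,val Lists of \linkS4class{EcgRecord} or
#'   \linkS4class{PoincareImage} inputs.
#' @param trainLabels,valLabels Lists/vectors of labels; defaults to the
#'   records' own labels.
#' @param epochs Maximum epochs.
#' @param batchSize Minibatch size.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience in epochs.
#' @param seed RNG seed for shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return The trained \linkS4class{ModelBundle} (with \code{history}).
#' @export
trainModel <- function(model, train, val, trainLabels = NULL,
                       valLabels = NULL, epochs = 30L, batchSize = 32L,
                       lr = 1e-3, patience = 5L, seed = 1L,
                       verbose = FALSE) {
  if (!length(train) || !length(val)) stop("train and val must be non-empty")
  if (is.null(trainLabels)) trainLabels <- recordLabelList(train)
  if (is.null(valLabels)) valLabels <- recordLabelList(val)
  xTr <- prepareInputs(model, train)
  xVa <- prepareInputs(model, val)
  yTr <- labelsToY(trainLabels, model)
  yVa <- labelsToY(valLabels, model)
  net <- model@net
  paramLayers <- collectParamLayers(net)
  nTr <- length(train)
  hist <- list()
  bestF1 <- -Inf
  bestState <- NULL
  bad <- 0L
  step <- 0L
  # Re-estimate batch-norm running statistics at the current weights with
  # dropout disabled; with few optimizer steps the plain exponential
  # averages would mostly reflect activations of stale weights.
  # spread the calibration subset across the whole training list: inputs
  # may arrive grouped by class (stratified splits) and statistics must
  # reflect the class mixture
  calIdx <- unique(round(seq(1, nTr, length.out = min(nTr, 8L * batchSize))))
  recalibrate <- function() {
    for (pl in paramLayers) {
      if (!is.null(pl$n_updates)) {
        pl$n_updates <- 0L
        pl$running_mean[] <- 0
        pl$running_var[] <- 0
      }
    }
    .nnGlobals$stats_only <- TRUE
    on.exit(.nnGlobals$stats_only <- FALSE)
    for (start in seq(1, length(calIdx), by = batchSize)) {
      idx <- calIdx[start:min(start + batchSize - 1, length(calIdx))]
      net$forward(sliceBatch(xTr, idx), training = TRUE)
    }
  }
  withSeed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      ord <- sample(nTr)
      epLoss <- 0
      nb <- 0L
      for (start in seq(1, nTr, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1, nTr)]
        xb <- sliceBatch(xTr, idx)
        out <- net$forward(xb, training = TRUE)
        l <- if (model@mode == "multiclass")
          lossSoftmaxCE(out, yTr[idx])
        else lossSigmoidBCE(out, yTr[, idx, drop = FALSE])
        if (!is.finite(l$loss))
          stop("training diverged (non-finite loss) at epoch ", ep,
               "; try a lower learning rate")
        net$backward(l$grad)
        step <- step + 1L
        adamStep(paramLayers, lr = lr, t = step)
        epLoss <- epLoss + l$loss
        nb <- nb + 1L
      }
      recalibrate()
      valF1 <- evalMacroF1(model, xVa, valLabels)
      hist[[ep]] <- data.frame(epoch = ep, train_loss = epLoss / nb,
                               val_macro_f1 = valF1)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f val macro-F1 %.3f", ep,
                        epLoss / nb, valF1))
      if (valF1 > bestF1 + 1e-6) {
        bestF1 <- valF1
        bestState <- getState(net)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
  })
  if (!is.null(bestState)) setState(net, bestState)
  model@trained <- TRUE
  model@history <- do.call(rbind, hist)
  model
}

# internal: macro-F1 of eval-mode predictions on a prepared tensor
evalMacroF1 <- function(model, x, labels) {
  scores <- forwardScores(model, x)
  pred <- scoresToDecisions(model, scores)
  truth <- if (model@mode == "multiclass")
    vapply(labels, function(l) l[1], character(1)) else labels
  scheme <- new("LabelScheme", mode = model@mode, classes = model@classes,
                codeMap = stats::setNames(model@classes, model@classes))
  rep <- computeMetrics(truth, pred, scheme)
  unname(rep@macro["f1"])
}

forwardScores <- function(model, x, batchSize = 64L) {
  n <- if (length(dim(x)) == 3) dim(x)[3] else dim(x)[4]
  out <- NULL
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, n)
    z <- model@net$forward(sliceBatch(x, idx), training = FALSE)
    p <- if (model@mode == "multiclass") softmaxCols(z) else
      1 / (1 + exp(-z))
    out <- cbind(out, p)
  }
  rownames(out) <- model@classes
  t(out)  # records x classes
}

scoresToDecisions <- function(model, scores, threshold = 0.5) {
  if (model@mode == "multiclass") {
    model@classes[max.col(scores, ties.method = "first")]
  } else {
    lapply(seq_len(nrow(scores)), function(i)
      model@classes[scores[i, ] >= threshold])
  }
}

#' Predict class scores and decisions
#'
#' @param model A trained \linkS4class{ModelBundle}.
#' @param inputs List of records or Poincare images.
#' @param threshold Multilabel decision threshold.
#' @return List with \code{scores} (records x classes probability matrix;
#'   rows sum to 1 in multiclass mode) and \code{decisions} (character
#'   vector, or list of character vectors in multilabel mode).
#' @export
predictModel <- function(model, inputs, threshold = 0.5) {
  if (!model@trained)
    warning("model has not been trained; predictions use random weights")
  x <- prepareInputs(model, inputs)
  scores <- forwardScores(model, x)
  list(scores = scores,
       decisions = scoresToDecisions(model, scores, threshold))
}

#' Save / restore model weights
#'
#' Writes the parameter state (weights, biases, batch-norm statistics) of a
#' built model to an RDS checkpoint, and restores such a checkpoint into a
#' model with the same architecture.
#'
#' @param model A \linkS4class{ModelBundle}.
#' @param path Checkpoint file path.
#' @return \code{saveModelWeights}: invisibly, \code{path};
#'   \code{loadModelWeights}: the model with restored weights (marked
#'   trained).
#' @export
saveModelWeights <- function(model, path) {
  saveRDS(list(arch = model@arch, classes = model@classes,
               state = getState(model@net)), path)
  invisible(path)
}

#' @rdname saveModelWeights
#' @export
loadModelWeights <- function(model, path) {
  ck <- readRDS(path)
  if (!identical(ck$arch, model@arch))
    stop("checkpoint architecture '", ck$arch,
         "' does not match model '", model@arch, "'")
  setState(model@net, ck$state)
  model@trained <- TRUE
  model
}

#' Layer-by-layer model description
#'
#' @param model A \linkS4class{ModelBundle}.
#' @return Data frame with layer id, type, and a JSON spec column; consumed
#'   by the architecture audit tests.
#' @export
describeModel <- function(model) {
  describeLayers(model@net)
}

#' @rdname describeModel
#' @param path Output JSON path.
#' @export
writeModelDescription <- function(model, path) {
  jsonlite::write_json(
    list(arch = model@arch, mode = model@mode, classes = model@classes,
         hyper = model@hyper, n_parameters = countParams(model@net),
         layers = describeModel(model)),
    path, auto_unbox = TRUE)
  invisible(path)
}
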