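# Minimal CPU conv-net engine: layers are environments holding parameters,
# gradients and closures; heavy kernels (im2col, pooling) live in src/.
# Tensor layouts: 1D batches (C, L, B); 2D batches (H, W, C, B).

.nnGlobals <- new.env(parent = emptyenv())
.nnGlobals$cache_eval <- FALSE
.nnGlobals$stats_only <- FALSE

# Caches are kept during training and, when cache_eval is raised (GradCAM),
# during evaluation-mode forward passes too.
shouldCache <- function(training) training || isTRUE(.nnGlobals$cache_eval)

newLayer <- function(type, spec = list()) {
  self <- new.env(parent = emptyenv())
  self$type <- type
  self$spec <- spec
  self$params <- list()
  self$grads <- list()
  self$children <- list()
  self
}

layerConv1d <- function(inC, outC, k, stride = 1L, pad = 0L) {
  self <- newLayer("conv1d", list(in_channels = inC, out_channels = outC,
                                  kernel = k, stride = stride, padding = pad))
  fan <- inC * k
  self$params <- list(
    W = matrix(stats::rnorm(outC * fan, sd = sqrt(2 / fan)), outC, fan),
    b = numeric(outC))
  self$forward <- function(x, training = FALSE) {
    d <- dim(x)
    cols <- im2col1d(x, k, stride, pad)
    y <- self$params$W %*% cols + self$params$b
    self$cache <- list(cols = cols, xdim = d)
    dim(y) <- c(outC, ncol(cols) / d[3], d[3])
    y
  }
  self$backward <- function(dy) {
    dim(dy) <- c(outC, length(dy) / outC)
    self$grads <- list(W = dy %*% t(self$cache$cols), b = rowSums(dy))
    dx <- col2im1d(t(self$params$W) %*% dy, self$cache$xdim, k, stride, pad)
    self$cache <- NULL
    dx
  }
  self
}

layerConv2d <- function(inC, outC, k, stride = 1L, pad = 0L) {
  self <- newLayer("conv2d", list(in_channels = inC, out_channels = outC,
                                  kernel = k, stride = stride, padding = pad))
  fan <- inC * k * k
  self$params <- list(
    W = matrix(stats::rnorm(outC * fan, sd = sqrt(2 / fan)), outC, fan),
    b = numeric(outC))
  self$forward <- function(x, training = FALSE) {
    d <- dim(x)
    cols <- im2col2d(x, k, k, stride, stride, pad, pad)
    y <- self$params$W %*% cols + self$params$b
    ho <- (d[1] + 2 * pad - k) %/% stride + 1
    wo <- (d[2] + 2 * pad - k) %/% stride + 1
    self$cache <- list(cols = cols, xdim = d)
    # produced as (outC, ho, wo, B); permute to canonical (ho, wo, outC, B)
    dim(y) <- c(outC, ho, wo, d[4])
    y <- aperm(y, c(2, 3, 1, 4))
    y
  }
  self$backward <- function(dy) {
    dy <- aperm(dy, c(3, 1, 2, 4))
    dim(dy) <- c(outC, length(dy) / outC)
    self$grads <- list(W = dy %*% t(self$cache$cols), b = rowSums(dy))
    dx <- col2im2d(t(self$params$W) %*% dy, self$cache$xdim, k, k,
                   stride, stride, pad, pad)
    self$cache <- NULL
    dx
  }
  self
}

# Batch normalization over the channel axis; `momentum` follows the
# running = momentum * running + (1 - momentum) * batch convention.
layerBatchNorm <- function(C, ndim = 1L, momentum = 0.99, eps = 1e-3) {
  self <- newLayer(if (ndim == 1L) "batchnorm1d" else "batchnorm2d",
                   list(channels = C, momentum = momentum, eps = eps))
  self$params <- list(gamma = rep(1, C), beta = rep(0, C))
  # running statistics are debiased exponential moving averages (divide by
  # 1 - momentum^n), so evaluation mode is usable from the first updates
  # even at momentum 0.99
  self$running_mean <- rep(0, C)
  self$running_var <- rep(0, C)
  self$n_updates <- 0L
  toCF <- function(x) { # channel-first matrix C x rest
    if (ndim == 1L) { d <- dim(x); dim(x) <- c(d[1], prod(d[-1])); list(x = x, d = d) }
    else { d <- dim(x); x <- aperm(x, c(3, 1, 2, 4)); dim(x) <- c(d[3], prod(d[-3])); list(x = x, d = d) }
  }
  fromCF <- function(x, d) {
    if (ndim == 1L) { dim(x) <- d; x }
    else { dim(x) <- c(d[3], d[1], d[2], d[4]); aperm(x, c(2, 3, 1, 4)) }
  }
  self$forward <- function(x, training = FALSE) {
    cf <- toCF(x)
    if (training) {
      mu <- rowMeans(cf$x)
      xc <- cf$x - mu
      v <- rowMeans(xc * xc)
      self$running_mean <- momentum * self$running_mean + (1 - momentum) * mu
      self$running_var <- momentum * self$running_var + (1 - momentum) * v
      self$n_updates <- self$n_updates + 1L
    } else {
      if (self$n_updates > 0L) {
        corr <- 1 - momentum^self$n_updates
        mu <- self$running_mean / corr
        v <- self$running_var / corr
      } else {
        mu <- rep(0, C)
        v <- rep(1, C)
      }
      xc <- cf$x - mu
    }
    invstd <- 1 / sqrt(v + eps)
    xhat <- xc * invstd
    y <- xhat * self$params$gamma + self$params$beta
    if (shouldCache(training))
      self$cache <- list(xhat = xhat, invstd = invstd, d = cf$d,
                         train_mode = training)
    fromCF(y, cf$d)
  }
  self$backward <- function(dy) {
    cf <- toCF(dy)
    dym <- cf$x
    xhat <- self$cache$xhat
    self$grads <- list(gamma = rowSums(dym * xhat), beta = rowSums(dym))
    dxhat <- dym * self$params$gamma
    dx <- if (self$cache$train_mode) {
      (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
        self$cache$invstd
    } else {
      # in evaluation mode the running statistics are constants
      dxhat * self$cache$invstd
    }
    out <- fromCF(dx, self$cache$d)
    self$cache <- NULL
    out
  }
  self
}

layerReLU <- function() {
  self <- newLayer("relu")
  self$forward <- function(x, training = FALSE) {
    mask <- x > 0
    if (shouldCache(training)) self$cache <- mask
    x * mask
  }
  self$backward <- function(dy) {
    dx <- dy * self$cache
    self$cache <- NULL
    dx
  }
  self
}

layerDropout <- function(p = 0.3) {
  self <- newLayer("dropout", list(p = p))
  self$forward <- function(x, training = FALSE) {
    # stats_only: BN-recalibration passes update normalization statistics
    # with dropout disabled so they match evaluation-time activations
    if (!training || p <= 0 || isTRUE(.nnGlobals$stats_only)) return(x)
    mask <- (stats::runif(length(x)) >= p) / (1 - p)
    dim(mask) <- dim(x)
    self$cache <- mask
    x * mask
  }
  self$backward <- function(dy) {
    if (is.null(self$cache)) return(dy)
    dx <- dy * self$cache
    self$cache <- NULL
    dx
  }
  self
}

layerMaxPool1d <- function(k = 2L, stride = 2L, ceil_mode = TRUE) {
  self <- newLayer("maxpool1d", list(kernel = k, stride = stride,
                                     ceil_mode = ceil_mode))
  self$forward <- function(x, training = FALSE) {
    r <- maxpool1d(x, k, stride, ceil_mode)
    if (shouldCache(training)) self$cache <- list(idx = r$idx, xdim = dim(x))
    r$y
  }
  self$backward <- function(dy) {
    dx <- pool_backward(dy, self$cache$idx, self$cache$xdim)
    self$cache <- NULL
    dx
  }
  self
}

# Average pooling with kernel 1: plain stride-subsampling along time.
layerAvgPool1dK1 <- function(stride = 2L) {
  self <- newLayer("avgpool1d", list(kernel = 1L, stride = stride))
  self$forward <- function(x, training = FALSE) {
    d <- dim(x)
    keep <- seq.int(1L, d[2], by = stride)
    if (shouldCache(training)) self$cache <- list(keep = keep, xdim = d)
    x[, keep, , drop = FALSE]
  }
  self$backward <- function(dy) {
    dx <- array(0, self$cache$xdim)
    dx[, self$cache$keep, ] <- dy
    self$cache <- NULL
    dx
  }
  self
}

# Global average + global max pooling along time, concatenated -> (2C, B).
layerGlobalPoolConcat1d <- function() {
  self <- newLayer("global_avgmax_concat1d")
  self$forward <- function(x, training = FALSE) {
    d <- dim(x)
    avg <- colSums(aperm(x, c(2, 1, 3))) / d[2]  # C x B
    mx <- globalmaxpool1d(x)
    if (shouldCache(training)) self$cache <- list(idx = mx$idx, xdim = d)
    rbind(avg, mx$y)
  }
  self$backward <- function(dy) {
    d <- self$cache$xdim
    C <- d[1]
    davg <- dy[seq_len(C), , drop = FALSE]
    dmax <- dy[C + seq_len(C), , drop = FALSE]
    dx <- aperm(array(davg / d[2], c(C, d[3], d[2])), c(1, 3, 2))
    dx[self$cache$idx] <- dx[self$cache$idx] + dmax
    self$cache <- NULL
    dx
  }
  self
}

layerMaxPool2d <- function(k = 2L, stride = 2L, pad = 0L) {
  self <- newLayer("maxpool2d", list(kernel = k, stride = stride, padding = pad))
  self$forward <- function(x, training = FALSE) {
    r <- maxpool2d(x, k, stride, pad)
    if (shouldCache(training)) self$cache <- list(idx = r$idx, xdim = dim(x))
    r$y
  }
  self$backward <- function(dy) {
    dx <- pool_backward(dy, self$cache$idx, self$cache$xdim)
    self$cache <- NULL
    dx
  }
  self
}

layerAvgPool2d <- function(k = 2L, stride = 2L) {
  self <- newLayer("avgpool2d", list(kernel = k, stride = stride))
  self$forward <- function(x, training = FALSE) {
    if (shouldCache(training)) self$cache <- dim(x)
    avgpool2d(x, k, stride)
  }
  self$backward <- function(dy) {
    dx <- avgpool2d_backward(dy, self$cache, k, stride)
    self$cache <- NULL
    dx
  }
  self
}

layerGlobalAvgPool2d <- function() {
  self <- newLayer("global_avgpool2d")
  self$forward <- function(x, training = FALSE) {
    d <- dim(x)
    if (shouldCache(training)) self$cache <- d
    m <- x
    dim(m) <- c(d[1] * d[2], d[3] * d[4])
    y <- colSums(m) / (d[1] * d[2])
    matrix(y, d[3], d[4])
  }
  self$backward <- function(dy) {
    d <- self$cache
    g <- rep(as.numeric(dy), each = d[1] * d[2]) / (d[1] * d[2])
    dim(g) <- d
    self$cache <- NULL
    g
  }
  self
}

layerFlatten <- function() {
  self <- newLayer("flatten")
  self$forward <- function(x, training = FALSE) {
    d <- dim(x)
    if (shouldCache(training)) self$cache <- d
    nB <- d[length(d)]
    dim(x) <- c(prod(d) / nB, nB)
    x
  }
  self$backward <- function(dy) {
    dim(dy) <- self$cache
    self$cache <- NULL
    dy
  }
  self
}

layerDense <- function(inD, outD) {
  self <- newLayer("dense", list(in_features = inD, out_features = outD))
  self$params <- list(
    W = matrix(stats::rnorm(outD * inD, sd = sqrt(2 / inD)), outD, inD),
    b = numeric(outD))
  self$forward <- function(x, training = FALSE) {
    if (shouldCache(training)) self$cache <- x
    self$params$W %*% x + self$params$b
  }
  self$backward <- function(dy) {
    self$grads <- list(W = dy %*% t(self$cache), b = rowSums(dy))
    dx <- t(self$params$W) %*% dy
    self$cache <- NULL
    dx
  }
  self
}

# ---- composite blocks ----

# Residual block: conv -> BN -> ReLU -> dropout -> conv -> BN, add shortcut
# (1x1 projection when channels differ), final ReLU.
blockResidual1d <- function(inC, outC, k = 7L, dropout = 0.3) {
  self <- newLayer("resblock1d", list(in_channels = inC, out_channels = outC,
                                      kernel = k,
                                      projection = inC != outC))
  pad <- (k - 1L) %/% 2L
  self$children <- list(
    conv1 = layerConv1d(inC, outC, k, pad = pad),
    bn1 = layerBatchNorm(outC),
    relu1 = layerReLU(),
    drop = layerDropout(dropout),
    conv2 = layerConv1d(outC, outC, k, pad = pad),
    bn2 = layerBatchNorm(outC))
  if (inC != outC) self$children$proj <- layerConv1d(inC, outC, 1L)
  self$children$relu_out <- layerReLU()
  self$forward <- function(x, training = FALSE) {
    ch <- self$children
    h <- ch$conv1$forward(x, training)
    h <- ch$bn1$forward(h, training)
    h <- ch$relu1$forward(h, training)
    h <- ch$drop$forward(h, training)
    h <- ch$conv2$forward(h, training)
    h <- ch$bn2$forward(h, training)
    res <- if (is.null(ch$proj)) x else ch$proj$forward(x, training)
    ch$relu_out$forward(h + res, training)
  }
  self$backward <- function(dy) {
    ch <- self$children
    dsum <- ch$relu_out$backward(dy)
    dh <- ch$bn2$backward(dsum)
    dh <- ch$conv2$backward(dh)
    dh <- ch$drop$backward(dh)
    dh <- ch$relu1$backward(dh)
    dh <- ch$bn1$backward(dh)
    dh <- ch$conv1$backward(dh)
    dres <- if (is.null(ch$proj)) dsum else ch$proj$backward(dsum)
    dh + dres
  }
  self
}

# DenseNet composite layer: BN-ReLU-1x1 conv (bottleneck) -> BN-ReLU-3x3 conv,
# output concatenated onto the input along the channel axis.
blockDenseLayer2d <- function(inC, growth, bottleneck = 4L, bnMomentum = 0.9) {
  self <- newLayer("denselayer2d", list(in_channels = inC, growth = growth,
                                        bottleneck = bottleneck))
  mid <- bottleneck * growth
  self$children <- list(
    bn1 = layerBatchNorm(inC, ndim = 2L, momentum = bnMomentum),
    relu1 = layerReLU(),
    conv1 = layerConv2d(inC, mid, 1L),
    bn2 = layerBatchNorm(mid, ndim = 2L, momentum = bnMomentum),
    relu2 = layerReLU(),
    conv2 = layerConv2d(mid, growth, 3L, pad = 1L))
  self$forward <- function(x, training = FALSE) {
    ch <- self$children
    h <- ch$bn1$forward(x, training)
    h <- ch$relu1$forward(h, training)
    h <- ch$conv1$forward(h, training)
    h <- ch$bn2$forward(h, training)
    h <- ch$relu2$forward(h, training)
    h <- ch$conv2$forward(h, training)
    d <- dim(x)
    self$inC_cached <- d[3]
    y <- array(0, c(d[1], d[2], d[3] + growth, d[4]))
    y[, , seq_len(d[3]), ] <- x
    y[, , d[3] + seq_len(growth), ] <- h
    y
  }
  self$backward <- function(dy) {
    ch <- self$children
    inC_ <- self$inC_cached
    growth_ <- dim(dy)[3] - inC_
    dx <- dy[, , seq_len(inC_), , drop = FALSE]
    dh <- dy[, , inC_ + seq_len(growth_), , drop = FALSE]
    dh <- ch$conv2$backward(dh)
    dh <- ch$relu2$backward(dh)
    dh <- ch$bn2$backward(dh)
    dh <- ch$conv1$backward(dh)
    dh <- ch$relu1$backward(dh)
    dh <- ch$bn1$backward(dh)
    dx + dh
  }
  self
}

# ResNet bottleneck block (1x1 -> 3x3 -> 1x1, expansion 4) with projection
# shortcut when shape changes.
blockBottleneck2d <- function(inC, midC, stride = 1L, bnMomentum = 0.9) {
  outC <- 4L * midC
  self <- newLayer("bottleneck2d", list(in_channels = inC, mid_channels = midC,
                                        out_channels = outC, stride = stride,
                                        projection = (inC != outC || stride != 1L)))
  self$children <- list(
    conv1 = layerConv2d(inC, midC, 1L),
    bn1 = layerBatchNorm(midC, ndim = 2L, momentum = bnMomentum),
    relu1 = layerReLU(),
    conv2 = layerConv2d(midC, midC, 3L, stride = stride, pad = 1L),
    bn2 = layerBatchNorm(midC, ndim = 2L, momentum = bnMomentum),
    relu2 = layerReLU(),
    conv3 = layerConv2d(midC, outC, 1L),
    bn3 = layerBatchNorm(outC, ndim = 2L, momentum = bnMomentum))
  if (inC != outC || stride != 1L) {
    self$children$proj <- layerConv2d(inC, outC, 1L, stride = stride)
    self$children$proj_bn <- layerBatchNorm(outC, ndim = 2L,
                                            momentum = bnMomentum)
  }
  self$children$relu_out <- layerReLU()
  self$forward <- function(x, training = FALSE) {
    ch <- self$children
    h <- ch$conv1$forward(x, training)
    h <- ch$bn1$forward(h, training)
    h <- ch$relu1$forward(h, training)
    h <- ch$conv2$forward(h, training)
    h <- ch$bn2$forward(h, training)
    h <- ch$relu2$forward(h, training)
    h <- ch$conv3$forward(h, training)
    h <- ch$bn3$forward(h, training)
    res <- if (is.null(ch$proj)) x else
      ch$proj_bn$forward(ch$proj$forward(x, training), training)
    ch$relu_out$forward(h + res, training)
  }
  self$backward <- function(dy) {
    ch <- self$children
    dsum <- ch$relu_out$backward(dy)
    dh <- ch$bn3$backward(dsum)
    dh <- ch$conv3$backward(dh)
    dh <- ch$relu2$backward(dh)
    dh <- ch$bn2$backward(dh)
    dh <- ch$conv2$backward(dh)
    dh <- ch$relu1$backward(dh)
    dh <- ch$bn1$backward(dh)
    dh <- ch$conv1$backward(dh)
    dres <- if (is.null(ch$proj)) dsum else
      ch$proj$backward(ch$proj_bn$backward(dsum))
    dh + dres
  }
  self
}

# ---- network container ----

nnSequential <- function(layers) {
  self <- newLayer("sequential")
  self$children <- layers
  self$forward <- function(x, training = FALSE) {
    for (ly in self$children) x <- ly$forward(x, training)
    x
  }
  # Forward that also returns the activation output of a named child and the
  # index after which it occurred (used by GradCAM).
  self$forwardTo <- function(x, upto) {
    acts <- NULL
    nm <- names(self$children)
    for (i in seq_along(self$children)) {
      x <- self$children[[i]]$forward(x, FALSE)
      if (!is.null(nm) && identical(nm[i], upto)) acts <- x
    }
    list(out = x, acts = acts)
  }
  self$backward <- function(dy) {
    for (ly in rev(self$children)) dy <- ly$backward(dy)
    dy
  }
  self
}

collectParamLayers <- function(layer) {
  out <- list()
  if (length(layer$params)) out <- list(layer)
  for (ch in layer$children) out <- c(out, collectParamLayers(ch))
  out
}

countParams <- function(layer) {
  sum(vapply(collectParamLayers(layer),
             function(l) sum(vapply(l$params, length, 1L)), 1))
}

# Adam with decoupled state stored inside each parameter layer.
adamStep <- function(paramLayers, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, t = 1L) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (ly in paramLayers) {
    if (!length(ly$grads)) next
    if (is.null(ly$opt)) {
      ly$opt <- lapply(ly$params, function(p) list(m = p * 0, v = p * 0))
    }
    for (nm in names(ly$params)) {
      g <- ly$grads[[nm]]
      st <- ly$opt[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      ly$opt[[nm]] <- st
      ly$params[[nm]] <- ly$params[[nm]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
    ly$grads <- list()
  }
  invisible(NULL)
}

# Serializable weight state (used for best-epoch checkpointing).
getState <- function(layer) {
  lapply(collectParamLayers(layer), function(l)
    list(params = l$params, running_mean = l$running_mean,
         running_var = l$running_var, n_updates = l$n_updates))
}

setState <- function(layer, state) {
  pls <- collectParamLayers(layer)
  stopifnot(length(pls) == length(state))
  for (i in seq_along(pls)) {
    pls[[i]]$params <- state[[i]]$params
    if (!is.null(state[[i]]$running_mean)) {
      pls[[i]]$running_mean <- state[[i]]$running_mean
      pls[[i]]$running_var <- state[[i]]$running_var
      pls[[i]]$n_updates <- state[[i]]$n_updates
    }
  }
  invisible(NULL)
}

# Layer-by-layer description used for the JSON model dump and audits.
describeLayers <- function(layer, prefix = "") {
  rows <- list()
  nm <- names(layer$children)
  add <- function(id, ly) {
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, type = ly$type,
      spec = if (length(ly$spec)) as.character(jsonlite::toJSON(ly$spec, auto_unbox = TRUE)) else "{}",
      stringsAsFactors = FALSE)
    if (length(ly$children)) {
      sub <- describeLayers(ly, paste0(id, "."))
      rows[[length(rows) + 1]] <<- sub
    }
  }
  for (i in seq_along(layer$children)) {
    id <- paste0(prefix, if (!is.null(nm) && nzchar(nm[i])) nm[i] else i)
    add(id, layer$children[[i]])
  }
  do.call(rbind, rows)
}

softmaxCols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# Multiclass cross-entropy; y is an integer vector of 1-based class indices.
lossSoftmaxCE <- function(logits, y) {
  p <- softmaxCols(logits)
  B <- ncol(logits)
  ix <- cbind(y, seq_len(B))
  loss <- -mean(log(pmax(p[ix], 1e-12)))
  d <- p
  d[ix] <- d[ix] - 1
  list(loss = loss, grad = d / B)
}

# Multilabel binary cross-entropy; targets is a 0/1 matrix (K x B).
lossSigmoidBCE <- function(logits, targets) {
  p <- 1 / (1 + exp(-logits))
  loss <- -mean(targets * log(pmax(p, 1e-12)) +
                  (1 - targets) * log(pmax(1 - p, 1e-12)))
  list(loss = loss, grad = (p - targets) / length(p))
}
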