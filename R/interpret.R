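# GradCAM for the 1D and 2D models: the gradient of the target-class score
# (pre-softmax logit) with respect to a convolutional feature map is
# averaged over positions to weight that map; the ReLU of the weighted sum,
# upsampled to input resolution and max-normalized, is the saliency.

#' Saliency map
#' @slot heatmap Non-negative vector (1D) or matrix (2D), max-normalized to
#'   1 unless identically zero.
#' @slot targetClass Class the saliency explains.
#' @slot layerId Network layer whose feature maps were used.
#' @export
setClass("Saliency",
  representation(heatmap = "ANY", targetClass = "character",
                 layerId = "character"),
  validity = function(object) {
    h <- object@heatmap
    if (!is.numeric(h)) return("heatmap must be numeric")
    if (any(h < 0)) return("heatmap must be non-negative")
    if (length(h) && max(h) > 1 + 1e-9)
      return("heatmap must be normalized to max 1")
    TRUE
  })

setMethod("show", "Saliency", function(object) {
  cat(sprintf("Saliency for class '%s' at layer '%s' (%s)\n",
              object@targetClass, object@layerId,
              if (is.matrix(object@heatmap))
                paste(dim(object@heatmap), collapse = "x")
              else paste0("length ", length(object@heatmap))))
  invisible(object)
})

upsampleLinear1d <- function(h, n) {
  if (length(h) == n) return(h)
  stats::approx(seq_along(h), h, n = n)$y
}

upsampleBilinear2d <- function(m, n) {
  if (nrow(m) == n && ncol(m) == n) return(m)
  interpAxis <- function(mat, n) {  # interpolate along rows
    src <- seq(1, nrow(mat), length.out = n)
    lo <- pmin(floor(src), nrow(mat))
    hi <- pmin(lo + 1, nrow(mat))
    w <- src - lo
    (1 - w) * mat[lo, , drop = FALSE] + w * mat[hi, , drop = FALSE]
  }
  t(interpAxis(t(interpAxis(m, n)), n))
}

#' GradCAM saliency
#'
#' Runs the model in evaluation mode (dropout off; deterministic), takes
#' the activations of the requested layer, backpropagates the target-class
#' logit to that layer, and forms the ReLU-weighted activation sum.
#'
#' @param model A \linkS4class{ModelBundle}.
#' @param input One \linkS4class{EcgRecord} or \linkS4class{PoincareImage}.
#' @param targetClass Class id to explain; defaults to the predicted class.
#' @param layer Name of a top-level network layer; defaults to the model's
#'   last convolutional block.
#' @return A \linkS4class{Saliency} at input resolution.
#' @export
gradCam <- function(model, input, targetClass = NULL, layer = NULL) {
  net <- model@net
  layerNames <- names(net$children)
  if (is.null(layer)) layer <- model@hyper$gradcam_layer
  li <- match(layer, layerNames)
  if (is.na(li))
    stop("layer '", layer, "' not found; available layers: ",
         paste(layerNames, collapse = ", "))
  x <- prepareInputs(model, list(input))
  .nnGlobals$cache_eval <- TRUE
  on.exit(.nnGlobals$cache_eval <- FALSE)
  acts <- NULL
  for (i in seq_along(net$children)) {
    x <- net$children[[i]]$forward(x, training = FALSE)
    if (i == li) acts <- x
  }
  logits <- x
  K <- length(model@classes)
  if (is.null(targetClass)) {
    targetClass <- model@classes[which.max(logits)]
  }
  ci <- match(targetClass, model@classes)
  if (is.na(ci)) stop("unknown target class: ", targetClass)
  dy <- matrix(0, K, 1)
  dy[ci, 1] <- 1
  g <- dy
  for (i in rev(seq_along(net$children))) {
    if (i <= li) break
    g <- net$children[[i]]$backward(g)
  }
  if (length(dim(acts)) == 3) {            # (C, L, 1)
    A <- acts[, , 1, drop = TRUE]
    G <- array(g, dim(acts))[, , 1, drop = TRUE]
    if (is.null(dim(A))) { A <- matrix(A, nrow = dim(acts)[1]) ; G <- matrix(G, nrow = dim(acts)[1]) }
    w <- rowMeans(G)
    heat <- pmax(colSums(A * w), 0)
    heat <- upsampleLinear1d(heat, model@inputTransform$length)
  } else {                                  # (H, W, C, 1)
    d <- dim(acts)
    A <- acts[, , , 1, drop = FALSE]
    G <- array(g, d)[, , , 1, drop = FALSE]
    w <- apply(G, 3, mean)
    heat <- matrix(0, d[1], d[2])
    for (c_ in seq_len(d[3])) heat <- heat + w[c_] * A[, , c_, 1]
    heat <- pmax(heat, 0)
    heat <- upsampleBilinear2d(heat, model@inputTransform$size)
  }
  mx <- max(heat)
  if (mx > 0) heat <- heat / mx
  new("Saliency", heatmap = heat, targetClass = targetClass,
      layerId = layer)
}

salColor <- function(s) {
  # blue (low) -> red (high)
  list(r = s, g = 0.2 * (1 - s), b = 1 - s)
}

#' Render a saliency overlay as a PNG
#'
#' 2D: the saliency is alpha-blended in red over the grayscale Poincare
#' image. 1D: the signal trace is drawn colored by saliency (blue = low,
#' red = high). A zero saliency reproduces the plain input rendering.
#'
#' @param saliency A \linkS4class{Saliency} (its heatmap must match the
#'   input's resolution).
#' @param input The \linkS4class{PoincareImage} or \linkS4class{EcgRecord}
#'   (or numeric vector) the saliency belongs to.
#' @param path Output PNG path, or NULL to skip writing.
#' @return Invisibly, the rendered H x W x 3 RGB array.
#' @export
renderOverlay <- function(saliency, input, path = NULL) {
  h <- saliency@heatmap
  if (is(input, "PoincareImage")) {
    if (!is.matrix(h) || !all(dim(h) == dim(input@pixels)))
      stop("saliency and image dimensions do not match")
    base <- input@pixels
    a <- 0.6 * h
    rgb <- array(0, c(nrow(base), ncol(base), 3))
    rgb[, , 1] <- base * (1 - a) + a * 1.0
    rgb[, , 2] <- base * (1 - a) + a * 0.3
    rgb[, , 3] <- base * (1 - a)
  } else {
    x <- if (is(input, "EcgRecord")) input@signal[1, ] else as.numeric(input)
    sig <- x
    if (length(h) == length(sig) - 1) sig <- sig[-length(sig)]
    if (length(h) != length(sig))
      stop("saliency length ", length(h), " does not match signal length ",
           length(sig))
    W <- length(sig)
    H <- 240L
    rng <- range(sig)
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    rows <- H - round((sig - rng[1]) / diff(rng) * (H - 21)) - 10L
    rgb <- array(1, c(H, W, 3))
    col <- salColor(h)
    for (j in seq_len(W)) {
      r0 <- rows[j]
      r1 <- if (j < W) rows[j + 1] else rows[j]
      span <- min(r0, r1):max(r0, r1)
      rgb[span, j, 1] <- col$r[j]
      rgb[span, j, 2] <- col$g[j]
      rgb[span, j, 3] <- col$b[j]
    }
  }
  if (!is.null(path)) png::writePNG(rgb, path)
  invisible(rgb)
}
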