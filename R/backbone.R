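## ---- frozen convolutional backbones -----------------------------------
##
## Three scales of a fixed-weight 2D convolutional feature extractor. The
## filter banks are random-Gaussian (He-scaled) and frozen: they are generated
## once per backbone id from a fixed seed and cached, so feature extraction is
## bit-reproducible across sessions and machines, runs on CPU, and involves no
## training anywhere. Channel count and input size are properties of the
## loaded model, never assumed by callers.

backbone_registry <- new.env(parent = emptyenv())

backbone_configs <- list(
  small  = list(input_size = 64,  channels = c(8, 16, 32),  seed = 101L),
  medium = list(input_size = 96,  channels = c(12, 24, 48), seed = 102L),
  large  = list(input_size = 128, channels = c(16, 32, 64), seed = 103L)
)

#' Load a frozen feature-extraction backbone
#'
#' Builds (or retrieves from cache) one of the three built-in frozen
#' convolutional backbones. Each is a stack of 3x3 convolution + ReLU blocks
#' with 2x2 max-pool downsampling between blocks; weights are fixed
#' He-scaled Gaussian filter banks generated deterministically from a
#' per-backbone seed, so the extractor behaves as a frozen, never-trained
#' network. The three ids trade spatial resolution and channel width against
#' compute, mirroring a small/medium/large model family.
#'
#' @param backbone_id \code{"small"}, \code{"medium"} or \code{"large"}.
#' @return A list of class \code{backbone} with elements \code{id},
#'   \code{input_size}, \code{n_channels} and the layer weights.
#' @export
load_backbone <- function(backbone_id = c("small", "medium", "large")) {
  backbone_id <- match.arg(backbone_id)
  if (!is.null(backbone_registry[[backbone_id]]))
    return(backbone_registry[[backbone_id]])
  cfg <- backbone_configs[[backbone_id]]
  layers <- with_seed(cfg$seed, {
    n_in <- 3L
    lapply(cfg$channels, function(n_out) {
      fan_in <- 9L * n_in
      w <- matrix(stats::rnorm(fan_in * n_out, sd = sqrt(2 / fan_in)),
                  nrow = fan_in, ncol = n_out)
      b <- stats::rnorm(n_out, sd = 0.01)
      n_in <<- n_out
      list(weight = w, bias = b, n_in = nrow(w) / 9L, n_out = n_out)
    })
  })
  bb <- structure(list(id = backbone_id, input_size = cfg$input_size,
                       n_channels = cfg$channels[length(cfg$channels)],
                       layers = layers),
                  class = "backbone")
  backbone_registry[[backbone_id]] <- bb
  bb
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone '%s'> input %dx%dx3 -> %d channels, %d conv blocks\n",
              x$id, x$input_size, x$input_size, x$n_channels,
              length(x$layers)))
  invisible(x)
}

## im2col for a HxWxC array with 3x3 kernels, zero 'same' padding, stride 1:
## returns (H*W) x (9*C) matrix whose row i holds the patch around pixel i.
im2col3 <- function(a) {
  h <- dim(a)[1]; w <- dim(a)[2]; nc <- dim(a)[3]
  pad <- array(0, c(h + 2, w + 2, nc))
  pad[2:(h + 1), 2:(w + 1), ] <- a
  cols <- matrix(0, h * w, 9 * nc)
  k <- 0L
  for (ch in seq_len(nc)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        k <- k + 1L
        cols[, k] <- pad[di + seq_len(h), dj + seq_len(w), ch]
      }
    }
  }
  cols
}

## 2x2 max pool, stride 2, on an HxWxC array (H, W even)
maxpool2 <- function(a) {
  h <- dim(a)[1]; w <- dim(a)[2]; nc <- dim(a)[3]
  i1 <- seq(1, h, by = 2); j1 <- seq(1, w, by = 2)
  pmax(a[i1, j1, , drop = FALSE], a[i1 + 1, j1, , drop = FALSE],
       a[i1, j1 + 1, , drop = FALSE], a[i1 + 1, j1 + 1, , drop = FALSE])
}

#' Extract the pre-pooling activation tensor of a frozen backbone
#'
#' Runs a prepared 3-channel image through the frozen convolutional stack and
#' returns the activation tensor of the last convolutional block, before any
#' global pooling -- the tensor that the four global pooling operators reduce
#' to a feature vector. Deterministic: the same image always yields a
#' bit-identical tensor.
#'
#' @param image numeric array \code{c(S, S, 3)} as produced by
#'   \code{\link{prep_for_backbone}} with \code{input_size = S} matching the
#'   backbone.
#' @param backbone_id backbone id, or a loaded \code{backbone} object.
#' @return An object of class \code{feature_tensor}: list with \code{values}
#'   (array indexed channel x height x width) and \code{backbone_id}.
#' @export
extract_feature_tensor <- function(image, backbone_id = "small") {
  bb <- if (inherits(backbone_id, "backbone")) backbone_id
        else load_backbone(backbone_id)
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("'image' must be an S x S x 3 array")
  if (dim(image)[1] != bb$input_size || dim(image)[2] != bb$input_size)
    stop(sprintf("backbone '%s' expects %dx%d input, got %dx%d", bb$id,
                 bb$input_size, bb$input_size, dim(image)[1], dim(image)[2]))
  a <- image
  n_layers <- length(bb$layers)
  for (li in seq_len(n_layers)) {
    ly <- bb$layers[[li]]
    h <- dim(a)[1]; w <- dim(a)[2]
    z <- im2col3(a) %*% ly$weight
    z <- sweep(z, 2, ly$bias, "+")
    z[z < 0] <- 0                       # ReLU
    a <- array(z, c(h, w, ly$n_out))
    if (li < n_layers) a <- maxpool2(a)
  }
  structure(list(values = aperm(a, c(3, 1, 2)), backbone_id = bb$id),
            class = "feature_tensor")
}

#' Global pooling of a feature tensor
#'
#' Reduces a channel x height x width activation tensor to a length-C vector
#' with one of four per-channel spatial statistics: mean, max, median, or
#' standard deviation. The standard deviation uses the population
#' (divide-by-N) convention, as a descriptive summary of the spatial
#' activation distribution rather than an estimator.
#'
#' @param t a \code{feature_tensor} (or plain C x H x W array).
#' @param method one of \code{"avg"}, \code{"max"}, \code{"median"},
#'   \code{"std"}.
#' @return Numeric vector of length C.
#' @export
global_pool <- function(t, method = c("avg", "max", "median", "std")) {
  method <- match.arg(method)
  vals <- if (inherits(t, "feature_tensor")) t$values else t
  if (!is.array(vals) || length(dim(vals)) != 3L)
    stop("expected a C x H x W feature tensor")
  ch <- dim(vals)[1]
  m <- matrix(vals, nrow = ch)
  switch(method,
         avg = rowMeans(m),
         max = apply(m, 1, max),
         median = apply(m, 1, stats::median),
         std = {
           mu <- rowMeans(m)
           sqrt(pmax(rowMeans(m^2) - mu^2, 0))
         })
}

#' Per-view pooled deep features for a whole MIP stack
#'
#' Applies \code{\link{prep_for_backbone}}, \code{\link{extract_feature_tensor}}
#' and \code{\link{global_pool}} to every view of a MIP stack, producing the
#' V x C views-by-channels feature matrix that the fusion stage consumes.
#' Rows are ordered by view angle and each row depends only on its own view.
#'
#' @param stack a \code{\link{mip_stack}}.
#' @param backbone_id backbone id or loaded \code{backbone}.
#' @param pooling pooling method passed to \code{\link{global_pool}}.
#' @param intensity_window optional fixed intensity window passed to
#'   \code{\link{prep_for_backbone}}.
#' @return A numeric V x C matrix of class \code{feature_matrix} with
#'   attributes \code{backbone_id}, \code{pooling_id} and \code{view_angles}.
#' @export
extract_mamip_features <- function(stack, backbone_id = "small",
                                   pooling = "avg",
                                   intensity_window = NULL) {
  if (!inherits(stack, "mip_stack")) stop("'stack' must be a mip_stack")
  bb <- if (inherits(backbone_id, "backbone")) backbone_id
        else load_backbone(backbone_id)
  rows <- lapply(stack$mips, function(m) {
    img <- prep_for_backbone(m, input_size = bb$input_size,
                             intensity_window = intensity_window)
    global_pool(extract_feature_tensor(img, bb), pooling)
  })
  out <- do.call(rbind, rows)
  structure(out, backbone_id = bb$id, pooling_id = pooling,
            view_angles = vapply(stack$mips, function(m) m$angle_deg,
                                 numeric(1)),
            class = c("feature_matrix", class(out)))
}
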