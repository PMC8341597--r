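#' U-Net architecture configuration
#'
#' Describes the encoder-decoder used for five-class IVUS segmentation:
#' `depth` encoder levels of two 3x3 stride-1 convolutions (ReLU, dropout
#' rate 0.1 after each) with 2x2 max-pooling between levels and filter
#' counts doubling per level; a symmetric decoder with 2x2 nearest-neighbour
#' upsampling and skip concatenation from the matching encoder level; and a
#' final 1x1 convolution to a per-pixel 5-way softmax. Padding is "same",
#' so the output grid equals the input grid.
#'
#' @param depth Number of encoder levels (the deepest is the bottleneck).
#' @param base_filters Filters at the first level; doubled at each level.
#' @param input_size Input side length, px; must be divisible by
#'   `2^(depth - 1)`.
#' @param n_classes Number of output classes (5).
#' @param in_channels Input channels (1 for grayscale B-mode).
#' @param dropout_rate Dropout rate after every convolution (training only).
#' @return A `net_config` list.
#' @export
net_config <- function(depth = 3L, base_filters = 16L, input_size = 64L,
                       n_classes = 5L, in_channels = 1L, dropout_rate = 0.1) {
  cfg <- structure(list(depth = as.integer(depth),
                        base_filters = as.integer(base_filters),
                        input_size = as.integer(input_size),
                        n_classes = as.integer(n_classes),
                        in_channels = as.integer(in_channels),
                        dropout_rate = as.numeric(dropout_rate)),
                   class = "net_config")
  if (cfg$depth < 1L || cfg$base_filters < 1L)
    stop("configuration error: depth and base_filters must be >= 1", call. = FALSE)
  if (cfg$input_size %% (2L^(cfg$depth - 1L)) != 0L)
    stop("configuration error: input_size must be divisible by 2^(depth-1)",
         call. = FALSE)
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("configuration error: dropout_rate must lie in [0, 1)", call. = FALSE)
  cfg
}

# (out_channels, in_channels, kernel) of every convolution, in the parameter
# order shared with the C++ kernels: encoder levels 1..depth (two convs
# each), decoder levels depth-1..1 (two convs each), then the 1x1 head
unet_layer_dims <- function(config) {
  d <- config$depth; f <- config$base_filters * 2L^(0:(d - 1L))
  dims <- list()
  for (l in 1:d) {
    cin <- if (l == 1L) config$in_channels else f[l - 1L]
    dims[[length(dims) + 1L]] <- c(out = f[l],'in' = cin, k = 3L)
    dims[[length(dims) + 1L]] <- c(out = f[l], 'in' = f[l], k = 3L)
  }
  if (d > 1L) for (l in (d - 1L):1L) {
    dims[[length(dims) + 1L]] <- c(out = f[l], 'in' = f[l + 1L] + f[l], k = 3L)
    dims[[length(dims) + 1L]] <- c(out = f[l], 'in' = f[l], k = 3L)
  }
  dims[[length(dims) + 1L]] <- c(out = config$n_classes, 'in' = f[1L], k = 1L)
  dims
}

#' Build an untrained U-Net
#'
#' Initializes weights with He-style Gaussian draws (sd = sqrt(2 / fan-in))
#' from R's RNG stream and zero biases; call under `set.seed()` for a
#' reproducible initialization.
#'
#' @param config A [net_config()].
#' @return An object of class `ivus_unet` holding `config` and `params`.
#' @export
build_unet <- function(config) {
  if (!inherits(config, "net_config")) stop("config must be a `net_config`", call. = FALSE)
  params <- list()
  for (dm in unet_layer_dims(config)) {
    fan_in <- dm[["k"]]^2 * dm[["in"]]
    w <- matrix(rnorm(dm[["out"]] * fan_in, sd = sqrt(2 / fan_in)),
                nrow = dm[["out"]], ncol = fan_in)
    params[[length(params) + 1L]] <- w
    params[[length(params) + 1L]] <- numeric(dm[["out"]])
  }
  structure(list(config = config, params = params, history = NULL),
            class = "ivus_unet")
}

#' Number of trainable parameters of a U-Net
#'
#' @param model An `ivus_unet`.
#' @return Integer parameter count (weights plus biases).
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Number of skip connections of a U-Net
#'
#' One concatenation per decoder level, i.e. `depth - 1`.
#'
#' @param model An `ivus_unet`.
#' @return Integer.
#' @export
n_skip_connections <- function(model) model$config$depth - 1L

# integer config vector consumed by the C++ kernels
cpp_cfg <- function(config, h, w) {
  as.integer(c(config$depth, config$base_filters, config$n_classes, h, w,
               config$in_channels))
}

#' @export
print.ivus_unet <- function(x, ...) {
  cat(sprintf("<ivus_unet> depth %d, base %d, %d classes, %s parameters%s\n",
              x$config$depth, x$config$base_filters, x$config$n_classes,
              format(n_params(x), big.mark = ","),
              if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

#' Segment a B-mode frame
#'
#' Runs the network forward (no dropout) and returns the per-pixel argmax
#' label mask together with the five per-class probability maps. Argmax ties
#' are broken toward the lower class index.
#'
#' @param object A trained (or untrained) `ivus_unet`.
#' @param frame Numeric matrix, square, side divisible by `2^(depth-1)`.
#' @param pixel_spacing Spacing attached to the returned mask, mm/px.
#' @param ... Unused.
#' @return List with `mask` (an `ivus_mask`) and `probs`
#'   (H x W x n_classes array; each pixel's probabilities sum to 1).
#' @export
predict.ivus_unet <- function(object, frame, pixel_spacing = 1, ...) {
  if (!is.matrix(frame) || nrow(frame) != ncol(frame))
    stop("argument error: frame must be a square matrix", call. = FALSE)
  h <- nrow(frame)
  if (h %% (2L^(object$config$depth - 1L)) != 0L)
    stop("argument error: frame size incompatible with network depth", call. = FALSE)
  x <- matrix(as.numeric(frame), nrow = 1L)
  p <- cpp_unet_forward(object$params, cpp_cfg(object$config, h, h), x)
  lab <- matrix(max.col(t(p), ties.method = "first") - 1L, h, h)
  probs <- array(t(p), dim = c(h, h, object$config$n_classes))
  list(mask = label_mask(lab, pixel_spacing), probs = probs)
}
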