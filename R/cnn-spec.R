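#' Convolutional network architecture specification
#'
#' Describes the strain-regression network.  The default is the empirically
#' optimized architecture used throughout: three convolutional layers of 32
#' filters with kernels 3 x 10, 1 x 10 and 1 x 5 and strides 1 x 2, 1 x 2 and
#' 1 x 1; a flattening layer with dropout 0.2; and two fully connected layers
#' ending in a single output.  Rectified linear activations are used
#' throughout, including at the output -- strains are non-negative, so a ReLU
#' head encodes the codomain.
#'
#' Convolutions are valid (unpadded).  The first kernel spans all 3 input
#' rows, collapsing the channel axis in one layer; subsequent 1 x w kernels
#' span all feature channels and slide along time only.  On a 3 x 201 input
#' the feature maps are 1 x 96 x 32, 1 x 44 x 32 and 1 x 40 x 32, and the
#' flattened width is 1280 (see [cnn_shapes()]).
#'
#' @param conv_filters,conv_kernel,conv_stride Integer vectors, one entry per
#'   convolutional layer: number of filters, temporal kernel width, temporal
#'   stride.
#' @param dropout_rate Dropout probability applied to the flattened features
#'   during training.
#' @param fc_sizes Widths of the fully connected layers; the last must be 1
#'   (scalar strain output).
#'
#' @return An object of class `cnn_spec`.
#' @export
#' @examples
#' spec <- cnn_spec()
#' cnn_shapes(spec)$conv_widths  # 96 44 40
cnn_spec <- function(conv_filters = c(32, 32, 32),
                     conv_kernel = c(10, 10, 5),
                     conv_stride = c(2, 2, 1),
                     dropout_rate = 0.2,
                     fc_sizes = c(64, 1)) {
  n <- length(conv_filters)
  stopifnot(length(conv_kernel) == n, length(conv_stride) == n, n >= 1,
            all(conv_filters >= 1), all(conv_kernel >= 1), all(conv_stride >= 1),
            dropout_rate >= 0, dropout_rate < 1,
            length(fc_sizes) >= 1, all(fc_sizes >= 1))
  if (utils::tail(fc_sizes, 1) != 1) {
    abort("the final fully connected layer must have width 1 (scalar strain)")
  }
  structure(
    list(conv_filters = as.integer(conv_filters),
         conv_kernel = as.integer(conv_kernel),
         conv_stride = as.integer(conv_stride),
         dropout_rate = dropout_rate,
         fc_sizes = as.integer(fc_sizes)),
    class = "cnn_spec"
  )
}

#' Layer-by-layer shape arithmetic
#'
#' Valid (unpadded) convolution of width `W` with kernel `k` and stride `s`
#' yields `floor((W - k)/s) + 1` outputs.  This function applies that
#' recurrence through the spec and reports every intermediate width, the
#' flattened feature count, and the total parameter count.
#'
#' @param spec A [cnn_spec()].
#' @param input_height,input_width Input dimensions (3 x 201 by default).
#' @return List with `conv_widths`, `flatten`, and `n_parameters`.
#' @export
cnn_shapes <- function(spec, input_height = 3, input_width = 201) {
  stopifnot(inherits(spec, "cnn_spec"))
  W <- input_width
  rows <- input_height
  widths <- integer(0)
  n_par <- 0
  for (l in seq_along(spec$conv_filters)) {
    k <- spec$conv_kernel[l]; s <- spec$conv_stride[l]; f <- spec$conv_filters[l]
    if (k > W) {
      abort(paste0("conv layer ", l, ": kernel width ", k,
                   " exceeds feature-map width ", W))
    }
    n_par <- n_par + f * (rows * k) + f
    W <- (W - k) %/% s + 1L
    widths <- c(widths, W)
    rows <- f
  }
  flatten <- rows * W
  prev <- flatten
  for (h in spec$fc_sizes) {
    n_par <- n_par + h * prev + h
    prev <- h
  }
  list(conv_widths = widths, flatten = flatten, n_parameters = n_par)
}

# 0-based gather indices for one full-height conv layer on a rows x W map
# stored column-major (channel-fastest); column j of the result lists the
# flat indices of the j-th kernel window.
make_conv_idx <- function(rows, W, k, s) {
  out_w <- (W - k) %/% s + 1L
  idx <- matrix(0L, rows * k, out_w)
  for (j in seq_len(out_w)) {
    cols <- (j - 1L) * s + seq_len(k) - 1L
    idx[, j] <- as.integer(outer(seq_len(rows) - 1L, cols * rows, `+`))
  }
  idx
}

# geometry bundle handed to the C++ core
cnn_geometry <- function(spec, input_height = 3, input_width = 201) {
  W <- input_width; rows <- input_height
  idx <- vector("list", length(spec$conv_filters))
  for (l in seq_along(spec$conv_filters)) {
    k <- spec$conv_kernel[l]; s <- spec$conv_stride[l]
    if (k > W) abort(paste0("conv layer ", l, ": kernel wider than feature map"))
    idx[[l]] <- make_conv_idx(rows, W, k, s)
    W <- (W - k) %/% s + 1L
    rows <- spec$conv_filters[l]
  }
  list(idx = idx, flatten = rows * W)
}
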