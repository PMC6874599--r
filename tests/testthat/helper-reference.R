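# Independent pure-R reference implementations used as oracles for the
# compiled network path.  Written from the layer definitions directly: im2col
# by explicit window enumeration, double precision throughout.

ref_relu <- function(x) pmax(x, 0)

# forward pass of the default architecture for ONE sample (3 x 201 matrix),
# given the package's weight list layout (conv W/b pairs, then fc W/b pairs)
ref_forward_one <- function(weights, m, spec) {
  A <- m  # rows x width feature map
  n_conv <- length(spec$conv_filters)
  for (l in seq_len(n_conv)) {
    k <- spec$conv_kernel[l]; s <- spec$conv_stride[l]
    W <- weights[[2 * l - 1]]; b <- weights[[2 * l]]
    starts <- seq(1, ncol(A) - k + 1, by = s)
    Z <- vapply(starts, function(j) {
      patch <- as.vector(A[, j:(j + k - 1), drop = FALSE])
      as.vector(W %*% patch + b)
    }, numeric(nrow(W)))
    A <- ref_relu(matrix(Z, nrow = nrow(W)))
  }
  h <- as.vector(A)  # flatten, column-major (channel-fastest)
  for (f in seq_along(spec$fc_sizes)) {
    W <- weights[[2 * n_conv + 2 * f - 1]]; b <- weights[[2 * n_conv + 2 * f]]
    h <- ref_relu(as.vector(W %*% h + b))
  }
  h
}

# definition-level metrics, independent of the package implementations
ref_r2 <- function(pred, truth) {
  1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)
}
ref_rmse <- function(pred, truth) sqrt(sum((pred - truth)^2) / length(truth))

# enumeration oracle for valid-convolution output width
ref_conv_width <- function(W, k, s) length(seq(1, W - k + 1, by = s))
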