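## Primitive tensor operations shared by the network builders. Feature
## tensors are double arrays dim c(H, W, C, N). The compiled kernels carry
## the weight-layout contract (see src/kernels.cpp).

as_feature_tensor <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 4L)
  storage.mode(x) <- "double"
  x
}

#' Max-pooling with recorded argmax indices
#'
#' 2x2, stride-2 max pooling that also returns, for every pooling window,
#' the position of the maximum so that a decoder can later place values back
#' at exactly those locations ("index unpooling"). Ties are broken by the
#' first position in row-major window order, making the operation
#' deterministic.
#'
#' @param x Feature tensor: array with dim `c(H, W, C, N)` (a plain `H x W`
#'   matrix is promoted). `H` and `W` must be even.
#' @return A list with `y` (the pooled `H/2 x W/2 x C x N` tensor) and `idx`
#'   (integer array of the same shape; codes `2*di + dj` for the in-window
#'   offset `(di, dj)`).
#' @seealso [unpool_with_indices()]
#' @export
max_pool_with_indices <- function(x) {
  x <- as_feature_tensor(x)
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("max_pool_with_indices: H and W must be even, got ",
         d[1], "x", d[2])
  .maxpool_fw(x)
}

#' Index-based unpooling
#'
#' Doubles the spatial size of `x`, writing each value at the argmax
#' position recorded by [max_pool_with_indices()] and zeros everywhere else.
#'
#' @param x Pooled feature tensor (`h x w x C x N`).
#' @param idx Integer index array as returned by [max_pool_with_indices()];
#'   must have the same dimensions as `x`.
#' @return Tensor of dim `c(2h, 2w, C, N)`.
#' @export
unpool_with_indices <- function(x, idx) {
  x <- as_feature_tensor(x)
  if (!identical(dim(x), dim(idx)))
    stop("unpool_with_indices: shape mismatch between x (",
         paste(dim(x), collapse = "x"), ") and idx (",
         paste(dim(idx), collapse = "x"), ")")
  .pool_scatter(x, idx)
}

conv_fw <- function(x, w, b, kh, kw) .conv2d_fw(x, w, b, kh, kw)
conv_bw <- function(x, dy, w, kh, kw) .conv2d_bw(x, dy, w, kh, kw)
tconv_fw <- function(x, w, b) .tconv2d_fw(x, w, b)
tconv_bw <- function(x, dy, w) .tconv2d_bw(x, dy, w)

## ---- batch normalization (per channel over H, W, N) ----

bn_forward <- function(x, gamma, beta, running, train, eps = 1e-5)
  .bn_fw(x, gamma, beta, running$mean, running$var, train, eps)

## exponential-moving-average update of running batch-norm statistics
bn_update_running <- function(running, bn, momentum = 0.1) {
  list(mean = (1 - momentum) * running$mean + momentum * bn$mean,
       var = (1 - momentum) * running$var + momentum * bn$var)
}

bn_backward <- function(dy, cache, gamma)
  .bn_bw(dy, cache$xhat, cache$std, gamma)

## ---- activations (a ReLU is a leaky ReLU with slope 0) ----

act_forward <- function(a, act, slope) {
  switch(act,
    none = a,
    relu = .lrelu_fw(a, 0),
    lrelu = .lrelu_fw(a, slope))
}

act_backward <- function(dy, a, act, slope) {
  switch(act,
    none = dy,
    relu = .lrelu_bw(dy, a, 0),
    lrelu = .lrelu_bw(dy, a, slope))
}

sigmoid <- function(z) 1 / (1 + exp(-z))
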