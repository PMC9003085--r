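#' @useDynLib macnseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif
NULL

# ---------------------------------------------------------------------------
# Minimal CNN toolkit: 2-D convolution (im2col + BLAS matmul), bilinear
# resampling expressed as separable interpolation matrices, pointwise
# activations, He initialization and Adam.  Every forward has a matching
# hand-derived backward; gradient correctness is pinned by finite-difference
# tests.  Arrays are (H, W, C); batches are handled as lists one level up.
# ---------------------------------------------------------------------------

conv_out_size <- function(size, k, stride, pad, dilation) {
  eff <- (k - 1L) * dilation + 1L
  as.integer((size + 2L * pad - eff) %/% stride + 1L)
}

#' 2-D convolution forward pass
#'
#' @param x input array (H, W, C_in).
#' @param W weight matrix (C_out x C_in*k*k), tap order matching the
#'   internal patch-matrix layout.
#' @param b bias vector length C_out.
#' @param stride,pad,dilation usual convolution arithmetic; `pad` is
#'   zero-padding on every side.
#' @return list with `out` (Hout, Wout, C_out) and `cols`, the patch matrix
#'   retained for the backward pass.
#' @keywords internal
conv_forward <- function(x, W, b, stride = 1L, pad = 1L, dilation = 1L) {
  d <- dim(x)
  k <- as.integer(sqrt(ncol(W) / d[3L]))
  cols <- im2col_cpp(as.numeric(x), d[1L], d[2L], d[3L],
                     k, as.integer(stride), as.integer(pad),
                     as.integer(dilation))
  out_pc <- crossprod(cols, t(W))                  # P x C_out, no big t()
  for (co in seq_len(ncol(out_pc))) out_pc[, co] <- out_pc[, co] + b[co]
  ho <- conv_out_size(d[1L], k, stride, pad, dilation)
  wo <- conv_out_size(d[2L], k, stride, pad, dilation)
  list(out = array(out_pc, dim = c(ho, wo, nrow(W))), cols = cols,
       in_dim = d, k = k, stride = as.integer(stride),
       pad = as.integer(pad), dilation = as.integer(dilation))
}

#' 2-D convolution backward pass
#' @param gout gradient w.r.t. the conv output, (Hout, Wout, C_out).
#' @param fw the list returned by [conv_forward()].
#' @param W the weight matrix used in the forward pass.
#' @return list with `gx`, `gW`, `gb`.
#' @keywords internal
conv_backward <- function(gout, fw, W) {
  cout <- dim(gout)[3L]
  gpc <- matrix(gout, ncol = cout)          # P x C_out
  gW <- t(fw$cols %*% gpc)                  # only the small result transposed
  gb <- colSums(gpc)
  gcols_t <- gpc %*% W                      # P x (C_in*k*k)
  gx <- col2im_t_cpp(gcols_t, fw$in_dim[1L], fw$in_dim[2L], fw$in_dim[3L],
                     fw$k, fw$stride, fw$pad, fw$dilation)
  list(gx = array(gx, dim = fw$in_dim), gW = gW, gb = gb)
}

# --- bilinear resampling ----------------------------------------------------

#' Separable bilinear interpolation matrix
#'
#' Row i of the returned (out x in) matrix holds the linear weights that
#' produce output sample i from the input samples, using the half-pixel
#' center convention src = (i + 0.5) * in/out - 0.5 clamped to the valid
#' range.  Rows sum to 1, so constants are preserved under resampling.
#' @keywords internal
bilinear_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5
    src <- min(max(src, 0), n_in - 1L)
    lo <- floor(src)
    frac <- src - lo
    hi <- min(lo + 1, n_in - 1L)
    A[i, lo + 1L] <- A[i, lo + 1L] + (1 - frac)
    A[i, hi + 1L] <- A[i, hi + 1L] + frac
  }
  A
}

.resize_cache <- new.env(parent = emptyenv())

resize_mats <- function(dims_in, dims_out) {
  key <- paste(dims_in[1L], dims_in[2L], dims_out[1L], dims_out[2L], sep = "x")
  m <- .resize_cache[[key]]
  if (is.null(m)) {
    m <- list(R = bilinear_matrix(dims_in[1L], dims_out[1L]),
              C = bilinear_matrix(dims_in[2L], dims_out[2L]))
    .resize_cache[[key]] <- m
  }
  m
}

#' Bilinear resize of an (H, W, C) array
#' @param x input array (H, W, C) or matrix (H, W).
#' @param out_h,out_w target spatial size.
#' @return resized array with the same channel count.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  two_d <- is.matrix(x)
  if (two_d) x <- array(x, dim = c(dim(x), 1L))
  d <- dim(x)
  m <- resize_mats(d[1:2], c(out_h, out_w))
  out <- array(0, dim = c(out_h, out_w, d[3L]))
  for (c in seq_len(d[3L])) out[, , c] <- m$R %*% x[, , c] %*% t(m$C)
  if (two_d) out[, , 1L] else out
}

# adjoint of resize_bilinear for backprop
resize_bilinear_backward <- function(gout, dims_in) {
  d <- dim(gout)
  m <- resize_mats(dims_in, d[1:2])
  gx <- array(0, dim = c(dims_in[1L], dims_in[2L], d[3L]))
  for (c in seq_len(d[3L])) gx[, , c] <- crossprod(m$R, gout[, , c]) %*% m$C
  gx
}

# --- activations ------------------------------------------------------------

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(gout, out) {
  gout * (out > 0)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Per-pixel softmax over the channel dimension
#' @param logits array (H, W, K).
#' @return array of probabilities, channels summing to 1 at every pixel.
#' @export
softmax_channels <- function(logits) {
  k <- dim(logits)[3L]
  m <- logits[, , 1L]
  if (k > 1L) for (j in 2:k) m <- pmax(m, logits[, , j])
  e <- exp(logits - as.vector(m))           # recycles over channels
  s <- e[, , 1L]
  if (k > 1L) for (j in 2:k) s <- s + e[, , j]
  e / as.vector(s)
}

# --- parameter initialization and Adam --------------------------------------

he_conv <- function(c_out, c_in, k, rng_sd_gain = 2) {
  fan_in <- c_in * k * k
  list(W = matrix(rnorm(c_out * fan_in, sd = sqrt(rng_sd_gain / fan_in)),
                  nrow = c_out),
       b = numeric(c_out))
}

adam_init <- function(params) {
  flat <- unlist(params, recursive = TRUE, use.names = FALSE)
  list(m = numeric(length(flat)), v = numeric(length(flat)), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  p <- unlist(params, recursive = TRUE, use.names = FALSE)
  g <- unlist(grads, recursive = TRUE, use.names = FALSE)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  p <- p - lr * mhat / (sqrt(vhat) + eps)
  list(params = utils::relist(p, params), state = state)
}

# elementwise sum of two parameter trees with identical structure
grad_tree_add <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- grad_tree_add(a[[nm]], b[[nm]])
    a
  } else a + b
}

grad_tree_scale <- function(a, s) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- grad_tree_scale(a[[nm]], s)
    a
  } else a * s
}

grad_tree_zero <- function(a) grad_tree_scale(a, 0)
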