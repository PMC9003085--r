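# Independent oracles, implemented directly from first principles so they
# share no code with the package internals they check.

# Separable bilinear resampler written straight from the interpolation
# formula (half-pixel centers, clamped borders).
naive_resize <- function(x, out_h, out_w) {
  two_d <- is.matrix(x)
  if (two_d) x <- array(x, dim = c(dim(x), 1L))
  d <- dim(x)
  out <- array(0, dim = c(out_h, out_w, d[3L]))
  for (c in seq_len(d[3L])) {
    for (i in seq_len(out_h)) {
      sr <- min(max((i - 0.5) * d[1L] / out_h - 0.5, 0), d[1L] - 1)
      r0 <- floor(sr); fr <- sr - r0; r1 <- min(r0 + 1, d[1L] - 1)
      for (j in seq_len(out_w)) {
        sc <- min(max((j - 0.5) * d[2L] / out_w - 0.5, 0), d[2L] - 1)
        c0 <- floor(sc); fc <- sc - c0; c1 <- min(c0 + 1, d[2L] - 1)
        out[i, j, c] <-
          (1 - fr) * ((1 - fc) * x[r0 + 1, c0 + 1, c] + fc * x[r0 + 1, c1 + 1, c]) +
          fr       * ((1 - fc) * x[r1 + 1, c0 + 1, c] + fc * x[r1 + 1, c1 + 1, c])
      }
    }
  }
  if (two_d) out[, , 1L] else out
}

# Direct-loop 2-D convolution oracle (zero padding, stride, dilation).
naive_conv <- function(x, W, b, stride = 1L, pad = 1L, dil = 1L) {
  d <- dim(x)
  k <- as.integer(sqrt(ncol(W) / d[3L]))
  eff <- (k - 1L) * dil + 1L
  ho <- (d[1L] + 2L * pad - eff) %/% stride + 1L
  wo <- (d[2L] + 2L * pad - eff) %/% stride + 1L
  out <- array(0, c(ho, wo, nrow(W)))
  for (oh in seq_len(ho)) for (ow in seq_len(wo)) for (co in seq_len(nrow(W))) {
    acc <- b[co]
    for (c in seq_len(d[3L])) for (kw in seq_len(k)) for (kh in seq_len(k)) {
      h <- (oh - 1L) * stride - pad + (kh - 1L) * dil + 1L
      w <- (ow - 1L) * stride - pad + (kw - 1L) * dil + 1L
      if (h >= 1L && h <= d[1L] && w >= 1L && w <= d[2L]) {
        q <- kh + (kw - 1L) * k + (c - 1L) * k * k
        acc <- acc + W[co, q] * x[h, w, c]
      }
    }
    out[oh, ow, co] <- acc
  }
  out
}

# Central finite difference of a scalar function over an array argument.
fd_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# Small model configuration for fast structural / gradient tests.
tiny_config <- function(...) {
  model_config(input_size = 32L, backbone_width_multiplier = 2L,
               aspp_growth = 2L, seed = 5L, ...)
}

# A 64-px model + a handful of labelled 64-px pairs cut from one scene,
# shared across training tests (built once per test run).
.shared <- new.env(parent = emptyenv())

small_train_setup <- function() {
  if (is.null(.shared$setup)) {
    ds <- generate_dataset(2, scene_spec(image_size = c(128L, 128L),
                                         n_ducts = 1L, n_arteries = 1L,
                                         duct_inner_radius_range = c(5, 8),
                                         duct_wall_thickness_range = c(3, 5),
                                         artery_inner_radius_range = c(6, 9),
                                         artery_wall_thickness_range = c(8, 10)),
                           seed = 21)
    pairs <- list()
    for (sc in ds$scenes) {
      pyr <- build_pyramid(sc$image, 2)
      pairs <- c(pairs, extract_patch_pairs(pyr, 0L, 1L, window = 64L,
                                            stride = 64L,
                                            mask = sc$duct_mask))
    }
    keep <- vapply(pairs, function(p) sum(p$mask_patch) > 0, TRUE)
    .shared$setup <- list(pairs = pairs, labelled = pairs[keep],
                          cfg = model_config(input_size = 64L,
                                             backbone_width_multiplier = 4L,
                                             seed = 5L))
  }
  .shared$setup
}

# Memorization run shared by the training tests: 200 Adam steps on a
# repeated batch of up to 4 labelled 64-px pairs.
overfit_run <- function() {
  if (is.null(.shared$overfit)) {
    setup <- small_train_setup()
    pairs <- setup$labelled[seq_len(min(4L, length(setup$labelled)))]
    log_path <- tempfile(fileext = ".jsonl")
    tc <- train_config(model = setup$cfg, batch_size = 4L, max_steps = 200L,
                       seed = 3L, learning_rate = 2e-3, log_path = log_path)
    res <- macn_train(tc, pairs)
    .shared$overfit <- list(model = res$model, pairs = pairs,
                            losses = res$losses, log_path = log_path)
  }
  .shared$overfit
}
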