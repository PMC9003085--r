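test_that("encoder produces the stated feature geometry", {
  cfg <- model_config(backbone_width_multiplier = 4L, seed = 2L)
  m <- macn_init(cfg)
  patch <- array(runif(256 * 256 * 3) - 0.5, c(256L, 256L, 3L))
  enc <- macn_encode(m, patch, "high")
  expect_identical(dim(enc$bottleneck)[1:2], c(16L, 16L))   # stride 16
  expect_identical(dim(enc$low_level)[1:2], c(64L, 64L))    # stride 4
  expect_identical(attr(enc$bottleneck, "downsample_factor"), 16L)
  expect_identical(attr(enc$low_level, "downsample_factor"), 4L)

  cfg8 <- model_config(backbone_width_multiplier = 4L, output_stride = 8L,
                       seed = 2L)
  enc8 <- macn_encode(macn_init(cfg8), patch, "high")
  expect_identical(dim(enc8$bottleneck)[1:2], c(32L, 32L))

  expect_error(macn_encode(m, array(0, c(64L, 64L, 3L)), "high"), "256x256")
})

test_that("the two branches are separately parameterized", {
  m <- macn_init(tiny_config())
  s <- m$config$input_size
  patch <- array(runif(s * s * 3) - 0.5, c(s, s, 3L))
  eh <- macn_encode(m, patch, "high")
  el <- macn_encode(m, patch, "low")
  expect_gt(max(abs(eh$bottleneck - el$bottleneck)), 1e-6)
})

test_that("a zero patch yields a zero bottleneck in the bias-free network", {
  m <- macn_init(tiny_config())   # biases initialize to zero
  s <- m$config$input_size
  enc <- macn_encode(m, array(0, c(s, s, 3L)), "high")
  expect_equal(max(abs(enc$bottleneck)), 0)
})

test_that("pyramid pooling preserves shape, mode none is the identity", {
  cfg <- tiny_config()
  m <- macn_init(cfg)
  s <- cfg$input_size
  feat <- macn_encode(m, array(runif(s * s * 3) - 0.5, c(s, s, 3L)),
                      "high")$bottleneck
  out <- suppressWarnings(macn_aspp(m, feat, "high"))
  expect_identical(dim(out)[1:2], dim(feat)[1:2])

  m_none <- macn_init(tiny_config(aspp_mode = "none"))
  expect_identical(macn_aspp(m_none, feat, "high"), feat)

  expect_warning(macn_aspp(m, feat, "high"), "clamped")
})

test_that("dense pyramid pooling widens the receptive field beyond one 3x3 conv", {
  cfg <- model_config(input_size = 64L, backbone_width_multiplier = 2L,
                      aspp_growth = 2L, aspp_rates = c(2L, 3L, 5L, 7L, 7L),
                      seed = 3L)
  m <- macn_init(cfg)
  set.seed(30)
  x <- array(rnorm(16 * 16 * 8), c(16L, 16L, 8L))
  fw <- macnseg:::aspp_forward(x, m$params$high$aspp, cfg)
  gout <- array(0, dim(fw$out))
  co <- which.max(fw$out[8L, 8L, ])          # a ReLU-active output channel
  expect_gt(fw$out[8L, 8L, co], 0)
  gout[8L, 8L, co] <- 1                      # one output pixel
  gx <- macnseg:::aspp_backward(gout, fw$cache, m$params$high$aspp, cfg)$gx
  support <- apply(abs(gx) > 1e-12, c(1L, 2L), any)
  on <- which(support, arr.ind = TRUE)
  extent <- max(max(on[, 1]) - min(on[, 1]), max(on[, 2]) - min(on[, 2]))
  expect_gt(extent, 2L)                      # a lone 3x3 conv spans extent 2
  expect_gt(sum(support), 9L)
})

test_that("central crop takes the middle quarter and tracks impulses", {
  cst <- array(2.5, c(32L, 32L, 1L))
  expect_equal(max(abs(central_crop_align(cst, 2L) - 2.5)), 0)

  # crop indices [8, 24) of a 32-map: an impulse at (8, 8) (0-based) maps
  # to the crop's (0, 0) corner, so its energy lands at the output corner
  imp <- array(0, c(32L, 32L, 1L))
  imp[9L, 9L, 1L] <- 1
  out <- central_crop_align(imp, 2L)
  pos <- which(out[, , 1L] == max(out[, , 1L]), arr.ind = TRUE)
  expect_true(all(pos[1, ] <= 2L))
  # impulse outside the central crop vanishes
  edge <- array(0, c(32L, 32L, 1L))
  edge[2L, 2L, 1L] <- 1
  expect_equal(max(abs(central_crop_align(edge, 2L))), 0)

  expect_error(central_crop_align(array(0, c(15L, 15L, 1L)), 2L),
               "not divisible")
})

test_that("attention fusion obeys its algebra and saturation limits", {
  set.seed(31)
  H <- array(runif(8 * 8 * 4), c(8L, 8L, 4L))       # nonnegative, post-ReLU
  expect_equal(attention_fuse(H, array(0, dim(H)))$fused, 1.5 * H)
  expect_lt(max(abs(attention_fuse(H, array(20, dim(H)))$fused - 2 * H)),
            1e-6)
  expect_lt(max(abs(attention_fuse(H, array(-20, dim(H)))$fused - H)), 1e-6)
  expect_equal(max(abs(attention_fuse(array(0, dim(H)), H)$fused)), 0)
  expect_error(attention_fuse(H, array(0, c(4L, 4L, 4L))), "shape")

  for (i in 1:10) {
    L <- array(rnorm(8 * 8 * 4, sd = 5), dim(H))
    fu <- attention_fuse(H, L)
    expect_true(all(fu$gate >= 0 & fu$gate <= 1))
    expect_true(all(fu$fused >= H - 1e-12))
    expect_true(all(fu$fused <= 2 * H + 1e-12))
    # exact gating algebra: fused - H = gate * H
    expect_equal(fu$fused - H, fu$gate * H, tolerance = 1e-12)
  }
})

test_that("forward emits normalized, deterministic per-pixel probabilities", {
  cfg <- tiny_config()
  m <- macn_init(cfg)
  s <- cfg$input_size
  set.seed(32)
  x_hi <- array(runif(s * s * 3), c(s, s, 3L))
  x_lo <- array(runif(s * s * 3), c(s, s, 3L))
  a <- macn_forward(m, x_hi, x_lo)
  b <- macn_forward(m, x_hi, x_lo)
  expect_identical(a$probs, b$probs)
  expect_identical(dim(a$probs), c(s, s, 2L))
  sums <- a$probs[, , 1L] + a$probs[, , 2L]
  expect_lt(max(abs(sums - 1)), 1e-6)
})

test_that("zero high-branch input forces uniform class probabilities", {
  # bias-free initialization: H(x) = 0 makes the fused map and every
  # decoder activation zero, so the logits are zero and softmax is uniform
  cfg <- tiny_config()
  m <- macn_init(cfg)
  s <- cfg$input_size
  x_hi <- array(0.5, c(s, s, 3L))                  # normalizes to zero
  x_lo <- array(runif(s * s * 3), c(s, s, 3L))
  out <- macn_forward(m, x_hi, x_lo)
  expect_lt(max(abs(out$probs - 0.5)), 1e-12)
})

test_that("decoder output hits full resolution and the skip is separable", {
  cfg <- tiny_config()
  m <- macn_init(cfg)
  s <- cfg$input_size
  x <- array(runif(s * s * 3), c(s, s, 3L))
  out <- macn_forward(m, x, x)
  expect_identical(dim(out$logits), c(s, s, 2L))

  # without the decoder there are strictly fewer parameter groups
  m_nodec <- macn_init(tiny_config(decoder_enabled = FALSE))
  expect_lt(n_params(m_nodec), n_params(m))
  out2 <- macn_forward(m_nodec, x, x)
  expect_identical(dim(out2$logits), c(s, s, 2L))

  # zeroed skip projection: the decoder output no longer depends on the
  # low-level features, matching the no-skip merge path
  m0 <- m
  m0$params$dec$skip$W[] <- 0
  m0$params$dec$skip$b[] <- 0
  enc <- macn_encode(m0, x - 0.5, "high")
  fused <- array(runif(prod(c(2L, 2L, 8L))), c(2L, 2L, 8L))
  d1 <- macn_decode(m0, fused, enc$low_level)
  d2 <- macn_decode(m0, fused, enc$low_level * 0 + 1)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("concatenation fusion keeps downstream shapes intact", {
  m <- macn_init(tiny_config(fusion_mode = "concatenation"))
  s <- m$config$input_size
  x <- array(runif(s * s * 3), c(s, s, 3L))
  out <- macn_forward(m, x, x)
  expect_identical(dim(out$probs), c(s, s, 2L))
})

test_that("model configuration validates its fields", {
  expect_error(model_config(output_stride = 4L), "8 or 16")
  expect_error(model_config(backbone = "resnet101"), "pretrained")
  expect_error(model_config(fusion_mode = "sum"))
})
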