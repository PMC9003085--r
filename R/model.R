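# ---------------------------------------------------------------------------
# Dual-branch multi-magnification attention segmentation network.
#
# Two parallel encoders (separate weights) process the high- and
# low-magnification patches of a co-centered pair.  Bottleneck features are
# enriched by (dense) atrous spatial pyramid pooling, the low-magnification
# features are aligned to the high-magnification field of view by a central
# crop + bilinear resize, and fused by sigmoid-gated attention
#     Y = (1 + sigmoid(L)) * H,
# so the low-magnification context can at most double, never suppress, a
# high-magnification activation.  A skip-connection decoder merges the fused
# map with factor-4 low-level features and produces 256x256 per-pixel class
# scores.  Forward and backward passes are explicit; the backward is the
# exact adjoint of the forward and is verified by finite differences in the
# test suite.
# ---------------------------------------------------------------------------

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1L], da[2L], da[3L] + db[3L]))
}

#' Model configuration
#'
#' @param backbone `"reduced"` (a width-scaled residual encoder with the
#'   stem + three downsampling stages layout of the large residual nets) —
#'   the desk-scale default.  `"resnet101"` is reserved for pretrained
#'   full-scale weights and is not bundled.
#' @param backbone_width_multiplier base channel width `w`; stages use
#'   (w, 2w, 4w, 4w) channels.
#' @param backbone_depth residual blocks per stage (0 disables them).
#' @param output_stride downsampling factor of the bottleneck, 8 or 16.
#' @param aspp_mode `"dense_aspp"` (densely connected dilated branches),
#'   `"aspp"` (parallel branches) or `"none"` (identity).
#' @param aspp_growth channels added by each dilated branch.
#' @param aspp_rates dilation rates of the five branches.
#' @param fusion_mode `"attention"` (sigmoid-gated, the proposed method) or
#'   `"concatenation"` (channel concat + 1x1 merge, the ablation).
#' @param crop_mode `"central_crop"` (align low-magnification features to
#'   the high field of view) or `"none"`.
#' @param decoder_enabled use the skip-connection decoder; `FALSE` applies
#'   the classifier directly to the fused bottleneck.
#' @param magnification_ratio field-of-view ratio between the branches
#'   (2 for adjacent pyramid levels, e.g. 40x/20x).
#' @param num_classes number of output classes (2: duct vs background).
#' @param focal_gamma focusing exponent of the training loss.
#' @param input_size patch side in pixels.
#' @param seed seed for parameter initialization.
#' @return object of class `model_config`.
#' @export
model_config <- function(backbone = "reduced",
                         backbone_width_multiplier = 8L,
                         backbone_depth = 1L,
                         output_stride = 16L,
                         aspp_mode = c("dense_aspp", "aspp", "none"),
                         aspp_growth = 8L,
                         aspp_rates = c(3L, 6L, 12L, 18L, 24L),
                         fusion_mode = c("attention", "concatenation"),
                         crop_mode = c("central_crop", "none"),
                         decoder_enabled = TRUE,
                         magnification_ratio = 2L,
                         num_classes = 2L,
                         focal_gamma = 1,
                         input_size = 256L,
                         seed = 1L) {
  aspp_mode <- match.arg(aspp_mode)
  fusion_mode <- match.arg(fusion_mode)
  crop_mode <- match.arg(crop_mode)
  if (!output_stride %in% c(8L, 16L)) stop("output_stride must be 8 or 16")
  if (backbone == "resnet101") {
    stop("the full-scale resnet101 backbone requires external pretrained ",
         "weights and is not bundled; use backbone = 'reduced'")
  }
  if (backbone != "reduced") stop("unknown backbone: ", backbone)
  structure(list(backbone = backbone,
                 backbone_width_multiplier = as.integer(backbone_width_multiplier),
                 backbone_depth = as.integer(backbone_depth),
                 output_stride = as.integer(output_stride),
                 aspp_mode = aspp_mode, aspp_growth = as.integer(aspp_growth),
                 aspp_rates = as.integer(aspp_rates),
                 fusion_mode = fusion_mode, crop_mode = crop_mode,
                 decoder_enabled = isTRUE(decoder_enabled),
                 magnification_ratio = as.integer(magnification_ratio),
                 num_classes = as.integer(num_classes),
                 focal_gamma = focal_gamma,
                 input_size = as.integer(input_size),
                 seed = as.integer(seed)),
            class = "model_config")
}

branch_params <- function(cfg, bias_free = FALSE) {
  w <- cfg$backbone_width_multiplier
  p <- list(stem = he_conv(w, 3L, 3L),
            down1 = he_conv(2L * w, w, 3L),
            down2 = he_conv(4L * w, 2L * w, 3L),
            down3 = he_conv(4L * w, 4L * w, 3L))
  if (cfg$backbone_depth >= 1L) {
    p$b1c1 <- he_conv(2L * w, 2L * w, 3L); p$b1c2 <- he_conv(2L * w, 2L * w, 3L)
    p$b2c1 <- he_conv(4L * w, 4L * w, 3L); p$b2c2 <- he_conv(4L * w, 4L * w, 3L)
    p$b3c1 <- he_conv(4L * w, 4L * w, 3L); p$b3c2 <- he_conv(4L * w, 4L * w, 3L)
  }
  if (cfg$aspp_mode != "none") {
    g <- cfg$aspp_growth
    cin <- 4L * w
    p$aspp <- list()
    for (i in seq_along(cfg$aspp_rates)) {
      nin <- if (cfg$aspp_mode == "dense_aspp") cin + (i - 1L) * g else cin
      p$aspp[[paste0("l", i)]] <- he_conv(g, nin, 3L)
    }
    p$aspp$proj <- he_conv(cin, cin + length(cfg$aspp_rates) * g, 1L)
  }
  p
}

#' Initialize a model
#'
#' He-style initialization; the two branches draw independent weights from
#' the seeded stream, so they are separately parameterized from the start.
#'
#' @param config a [model_config()].
#' @return object of class `macn_model`: list with `config` and `params`.
#' @export
macn_init <- function(config = model_config()) {
  set.seed(config$seed)
  w <- config$backbone_width_multiplier
  params <- list(high = branch_params(config), low = branch_params(config))
  cbot <- 4L * w
  if (config$fusion_mode == "concatenation") {
    params$fuse <- list(merge = he_conv(cbot, 2L * cbot, 1L))
  }
  if (config$decoder_enabled) {
    c_skip <- w
    params$dec <- list(skip = he_conv(c_skip, 2L * w, 1L),
                       m1 = he_conv(2L * w, cbot + c_skip, 3L),
                       m2 = he_conv(2L * w, 2L * w, 3L),
                       cls = he_conv(config$num_classes, 2L * w, 1L))
  } else {
    params$head <- list(cls = he_conv(config$num_classes, cbot, 1L))
  }
  structure(list(config = config, params = params), class = "macn_model")
}

#' Number of trainable parameters
#' @param model a `macn_model`.
#' @export
n_params <- function(model) {
  length(unlist(model$params, recursive = TRUE, use.names = FALSE))
}

# --- encoder ----------------------------------------------------------------

res_block_forward <- function(x, p1, p2) {
  c1 <- conv_forward(x, p1$W, p1$b, stride = 1L, pad = 1L)
  r1 <- relu(c1$out)
  c2 <- conv_forward(r1, p2$W, p2$b, stride = 1L, pad = 1L)
  out <- relu(x + c2$out)
  list(out = out, c1 = c1, r1 = r1, c2 = c2)
}

res_block_backward <- function(gout, cache, p1, p2) {
  g <- relu_backward(gout, cache$out)
  b2 <- conv_backward(g, cache$c2, p2$W)
  gr1 <- relu_backward(b2$gx, cache$r1)
  b1 <- conv_backward(gr1, cache$c1, p1$W)
  list(gx = g + b1$gx,
       g1 = list(W = b1$gW, b = b1$gb),
       g2 = list(W = b2$gW, b = b2$gb))
}

encode_forward <- function(x, pr, cfg) {
  cache <- list()
  s3_stride <- if (cfg$output_stride == 16L) 2L else 1L
  s3_dil <- if (cfg$output_stride == 16L) 1L else 2L
  cache$stem <- conv_forward(x, pr$stem$W, pr$stem$b, stride = 2L, pad = 1L)
  a0 <- relu(cache$stem$out); cache$a0 <- a0
  cache$down1 <- conv_forward(a0, pr$down1$W, pr$down1$b, stride = 2L, pad = 1L)
  a1 <- relu(cache$down1$out); cache$a1 <- a1
  if (cfg$backbone_depth >= 1L) {
    cache$blk1 <- res_block_forward(a1, pr$b1c1, pr$b1c2)
    a1 <- cache$blk1$out
  }
  low_level <- a1                                  # factor 4
  cache$down2 <- conv_forward(a1, pr$down2$W, pr$down2$b, stride = 2L, pad = 1L)
  a2 <- relu(cache$down2$out); cache$a2 <- a2
  if (cfg$backbone_depth >= 1L) {
    cache$blk2 <- res_block_forward(a2, pr$b2c1, pr$b2c2)
    a2 <- cache$blk2$out
  }
  cache$down3 <- conv_forward(a2, pr$down3$W, pr$down3$b,
                              stride = s3_stride, pad = s3_dil,
                              dilation = s3_dil)
  a3 <- relu(cache$down3$out); cache$a3 <- a3
  if (cfg$backbone_depth >= 1L) {
    cache$blk3 <- res_block_forward(a3, pr$b3c1, pr$b3c2)
    a3 <- cache$blk3$out
  }
  list(low_level = low_level, bottleneck = a3, cache = cache)
}

encode_backward <- function(g_bot, g_low, cache, pr, cfg) {
  gr <- list()
  g <- g_bot
  if (cfg$backbone_depth >= 1L) {
    bb <- res_block_backward(g, cache$blk3, pr$b3c1, pr$b3c2)
    gr$b3c1 <- bb$g1; gr$b3c2 <- bb$g2; g <- bb$gx
  }
  g <- relu_backward(g, cache$a3)
  bd3 <- conv_backward(g, cache$down3, pr$down3$W)
  gr$down3 <- list(W = bd3$gW, b = bd3$gb)
  g <- bd3$gx
  if (cfg$backbone_depth >= 1L) {
    bb <- res_block_backward(g, cache$blk2, pr$b2c1, pr$b2c2)
    gr$b2c1 <- bb$g1; gr$b2c2 <- bb$g2; g <- bb$gx
  }
  g <- relu_backward(g, cache$a2)
  bd2 <- conv_backward(g, cache$down2, pr$down2$W)
  gr$down2 <- list(W = bd2$gW, b = bd2$gb)
  g <- bd2$gx
  if (!is.null(g_low)) g <- g + g_low              # skip branch into decoder
  if (cfg$backbone_depth >= 1L) {
    bb <- res_block_backward(g, cache$blk1, pr$b1c1, pr$b1c2)
    gr$b1c1 <- bb$g1; gr$b1c2 <- bb$g2; g <- bb$gx
  }
  g <- relu_backward(g, cache$a1)
  bd1 <- conv_backward(g, cache$down1, pr$down1$W)
  gr$down1 <- list(W = bd1$gW, b = bd1$gb)
  g <- relu_backward(bd1$gx, cache$a0)
  bst <- conv_backward(g, cache$stem, pr$stem$W)
  gr$stem <- list(W = bst$gW, b = bst$gb)
  gr
}

# --- atrous spatial pyramid pooling -----------------------------------------

aspp_forward <- function(x, pa, cfg) {
  s <- dim(x)[1L]
  rates <- pmin(cfg$aspp_rates, s - 1L)            # clamp oversized dilations
  cache <- list(x = x, rates = rates, convs = list(), acts = list())
  feats <- list(x)
  for (i in seq_along(rates)) {
    inp <- if (cfg$aspp_mode == "dense_aspp") Reduce(cat_channels, feats) else x
    cv <- conv_forward(inp, pa[[paste0("l", i)]]$W, pa[[paste0("l", i)]]$b,
                       stride = 1L, pad = rates[i], dilation = rates[i])
    a <- relu(cv$out)
    cache$convs[[i]] <- cv
    cache$acts[[i]] <- a
    feats[[i + 1L]] <- a
  }
  allf <- Reduce(cat_channels, feats)
  pj <- conv_forward(allf, pa$proj$W, pa$proj$b, stride = 1L, pad = 0L)
  out <- relu(pj$out)
  cache$proj <- pj
  cache$out <- out
  cache$feat_ch <- vapply(feats, function(f) dim(f)[3L], 0L)
  list(out = out, cache = cache)
}

aspp_backward <- function(gout, cache, pa, cfg) {
  gr <- list()
  g <- relu_backward(gout, cache$out)
  bp <- conv_backward(g, cache$proj, pa$proj$W)
  gr$proj <- list(W = bp$gW, b = bp$gb)
  nch <- cache$feat_ch
  # split the projection input gradient back into x and the branch outputs
  splits <- vector("list", length(nch))
  off <- 0L
  for (j in seq_along(nch)) {
    splits[[j]] <- bp$gx[, , (off + 1L):(off + nch[j]), drop = FALSE]
    off <- off + nch[j]
  }
  gx <- splits[[1L]]
  gacts <- splits[-1L]
  for (i in rev(seq_along(cache$rates))) {
    ga <- gacts[[i]]
    g <- relu_backward(ga, cache$acts[[i]])
    bc <- conv_backward(g, cache$convs[[i]], pa[[paste0("l", i)]]$W)
    gr[[paste0("l", i)]] <- list(W = bc$gW, b = bc$gb)
    if (cfg$aspp_mode == "dense_aspp") {
      # input was concat(x, act_1, ..., act_{i-1})
      off <- 0L
      for (j in seq_len(i)) {
        piece <- bc$gx[, , (off + 1L):(off + nch[j]), drop = FALSE]
        if (j == 1L) gx <- gx + piece
        else gacts[[j - 1L]] <- gacts[[j - 1L]] + piece
        off <- off + nch[j]
      }
    } else {
      gx <- gx + bc$gx
    }
  }
  list(gx = gx, grads = gr)
}

# --- alignment and fusion ---------------------------------------------------

#' Central-crop alignment of a low-magnification feature map
#'
#' Crops the central 1/ratio fraction in each spatial dimension (for ratio 2
#' and size S, rows and columns \[S/4, 3S/4) in 0-based half-open indexing)
#' and bilinearly resizes back to S x S, so each output position covers the
#' same tissue as the high-magnification feature map at that position.
#'
#' @param low_feat (S, S, C) array of low-magnification features.
#' @param ratio field-of-view ratio (2 for adjacent pyramid levels).
#' @return aligned (S, S, C) array.
#' @export
central_crop_align <- function(low_feat, ratio = 2L) {
  d <- dim(low_feat)
  if (d[1L] %% ratio != 0L || d[2L] %% ratio != 0L) {
    stop(sprintf("feature map %dx%d not divisible by crop ratio %d",
                 d[1L], d[2L], ratio))
  }
  ch <- d[1L] %/% ratio; cw <- d[2L] %/% ratio
  r0 <- (d[1L] - ch) %/% 2L; c0 <- (d[2L] - cw) %/% 2L
  crop <- low_feat[(r0 + 1L):(r0 + ch), (c0 + 1L):(c0 + cw), , drop = FALSE]
  resize_bilinear(crop, d[1L], d[2L])
}

central_crop_align_backward <- function(gout, in_dim, ratio = 2L) {
  ch <- in_dim[1L] %/% ratio; cw <- in_dim[2L] %/% ratio
  r0 <- (in_dim[1L] - ch) %/% 2L; c0 <- (in_dim[2L] - cw) %/% 2L
  gcrop <- resize_bilinear_backward(gout, c(ch, cw))
  gx <- array(0, dim = in_dim)
  gx[(r0 + 1L):(r0 + ch), (c0 + 1L):(c0 + cw), ] <- gcrop
  gx
}

#' Sigmoid-gated attention fusion of two magnification feature maps
#'
#' Computes `gate = sigmoid(low)` and `fused = (1 + gate) * high`
#' elementwise.  Where the low-magnification context is strongly activated
#' the high-magnification feature is up to doubled; where it is strongly
#' negative the feature passes through unchanged — the low branch can
#' enhance but never veto the prediction branch.
#'
#' @param high_feat,low_feat_aligned identically shaped (H, W, C) arrays.
#' @return list with `fused` and `gate` (values in \[0, 1\]).
#' @export
attention_fuse <- function(high_feat, low_feat_aligned) {
  if (!identical(dim(high_feat), dim(low_feat_aligned))) {
    stop("attention fusion requires identically shaped feature maps")
  }
  gate <- sigmoid(low_feat_aligned)
  list(fused = (1 + gate) * high_feat, gate = gate)
}

# --- full forward / backward ------------------------------------------------

#' Forward pass of the dual-magnification network
#'
#' @param model a `macn_model`.
#' @param x_hi,x_lo co-centered patches, (S, S, 3) arrays in \[0, 1\].
#' @param keep_cache retain all intermediates for a backward pass.
#' @return list with `probs` (S, S, num_classes; per-pixel softmax),
#'   `logits`, and when requested `cache`.
#' @export
macn_forward <- function(model, x_hi, x_lo, keep_cache = FALSE) {
  cfg <- model$config
  pp <- model$params
  s <- cfg$input_size
  if (!identical(dim(x_hi)[1:2], c(s, s)) ||
      !identical(dim(x_lo)[1:2], c(s, s))) {
    stop(sprintf("patches must be %dx%d", s, s))
  }
  cache <- list()
  xh <- x_hi - 0.5; xl <- x_lo - 0.5               # center the input range
  enc_h <- encode_forward(xh, pp$high, cfg)
  enc_l <- encode_forward(xl, pp$low, cfg)
  bh <- enc_h$bottleneck; bl <- enc_l$bottleneck
  if (cfg$aspp_mode != "none") {
    ah <- aspp_forward(bh, pp$high$aspp, cfg)
    al <- aspp_forward(bl, pp$low$aspp, cfg)
    bh <- ah$out; bl <- al$out
    cache$aspp_h <- ah$cache; cache$aspp_l <- al$cache
  }
  bot_dim <- dim(bl)
  aligned <- if (cfg$crop_mode == "central_crop") {
    central_crop_align(bl, cfg$magnification_ratio)
  } else bl
  if (cfg$fusion_mode == "attention") {
    fu <- attention_fuse(bh, aligned)
    fused <- fu$fused
    cache$gate <- fu$gate
  } else {
    catin <- cat_channels(bh, aligned)
    mg <- conv_forward(catin, pp$fuse$merge$W, pp$fuse$merge$b,
                       stride = 1L, pad = 0L)
    fused <- relu(mg$out)
    cache$merge <- mg
    cache$merge_out <- fused
    cache$cat_ch <- c(dim(bh)[3L], dim(aligned)[3L])
  }
  cache$bh <- bh; cache$aligned <- aligned; cache$bot_dim <- bot_dim
  if (cfg$decoder_enabled) {
    y <- fused
    up_dims <- list()
    while (dim(y)[1L] < s %/% 4L) {
      up_dims[[length(up_dims) + 1L]] <- dim(y)
      y <- resize_bilinear(y, dim(y)[1L] * 2L, dim(y)[2L] * 2L)
    }
    sk <- conv_forward(enc_h$low_level, pp$dec$skip$W, pp$dec$skip$b,
                       stride = 1L, pad = 0L)
    catd <- cat_channels(y, sk$out)
    m1 <- conv_forward(catd, pp$dec$m1$W, pp$dec$m1$b, stride = 1L, pad = 1L)
    a1 <- relu(m1$out)
    m2 <- conv_forward(a1, pp$dec$m2$W, pp$dec$m2$b, stride = 1L, pad = 1L)
    a2 <- relu(m2$out)
    cl <- conv_forward(a2, pp$dec$cls$W, pp$dec$cls$b, stride = 1L, pad = 0L)
    logits <- resize_bilinear(cl$out, s, s)
    cache <- c(cache, list(up_dims = up_dims, sk = sk, m1 = m1, a1 = a1,
                           m2 = m2, a2 = a2, cl = cl,
                           dec_ch = c(dim(y)[3L], dim(sk$out)[3L]),
                           cls_dim = dim(cl$out)))
  } else {
    cl <- conv_forward(fused, pp$head$cls$W, pp$head$cls$b,
                       stride = 1L, pad = 0L)
    logits <- resize_bilinear(cl$out, s, s)
    cache$cl <- cl
    cache$cls_dim <- dim(cl$out)
  }
  probs <- softmax_channels(logits)
  out <- list(probs = probs, logits = logits)
  if (keep_cache) {
    cache$enc_h <- enc_h; cache$enc_l <- enc_l
    out$cache <- cache
  }
  out
}

macn_backward <- function(model, cache, glogits) {
  cfg <- model$config
  pp <- model$params
  gr <- grad_tree_zero(pp)
  g <- resize_bilinear_backward(glogits, cache$cls_dim[1:2])
  if (cfg$decoder_enabled) {
    bcl <- conv_backward(g, cache$cl, pp$dec$cls$W)
    gr$dec$cls <- list(W = bcl$gW, b = bcl$gb)
    g <- relu_backward(bcl$gx, cache$a2)
    bm2 <- conv_backward(g, cache$m2, pp$dec$m2$W)
    gr$dec$m2 <- list(W = bm2$gW, b = bm2$gb)
    g <- relu_backward(bm2$gx, cache$a1)
    bm1 <- conv_backward(g, cache$m1, pp$dec$m1$W)
    gr$dec$m1 <- list(W = bm1$gW, b = bm1$gb)
    nup <- cache$dec_ch[1L]
    gy <- bm1$gx[, , seq_len(nup), drop = FALSE]
    gsk <- bm1$gx[, , (nup + 1L):(nup + cache$dec_ch[2L]), drop = FALSE]
    bsk <- conv_backward(gsk, cache$sk, pp$dec$skip$W)
    gr$dec$skip <- list(W = bsk$gW, b = bsk$gb)
    g_low_skip <- bsk$gx
    for (d in rev(cache$up_dims)) gy <- resize_bilinear_backward(gy, d[1:2])
    gfused <- gy
  } else {
    bcl <- conv_backward(g, cache$cl, pp$head$cls$W)
    gr$head$cls <- list(W = bcl$gW, b = bcl$gb)
    gfused <- bcl$gx
    g_low_skip <- NULL
  }
  if (cfg$fusion_mode == "attention") {
    gbh <- gfused * (1 + cache$gate)
    galigned <- gfused * cache$bh * cache$gate * (1 - cache$gate)
  } else {
    g <- relu_backward(gfused, cache$merge_out)
    bmg <- conv_backward(g, cache$merge, pp$fuse$merge$W)
    gr$fuse$merge <- list(W = bmg$gW, b = bmg$gb)
    gbh <- bmg$gx[, , seq_len(cache$cat_ch[1L]), drop = FALSE]
    galigned <- bmg$gx[, , (cache$cat_ch[1L] + 1L):
                             (cache$cat_ch[1L] + cache$cat_ch[2L]),
                       drop = FALSE]
  }
  gbl <- if (cfg$crop_mode == "central_crop") {
    central_crop_align_backward(galigned, cache$bot_dim,
                                cfg$magnification_ratio)
  } else galigned
  if (cfg$aspp_mode != "none") {
    ab <- aspp_backward(gbh, cache$aspp_h, pp$high$aspp, cfg)
    # assign by name: the grad tree must keep the parameter tree's order
    for (nm in names(ab$grads)) gr$high$aspp[[nm]] <- ab$grads[[nm]]
    gbh <- ab$gx
    ab <- aspp_backward(gbl, cache$aspp_l, pp$low$aspp, cfg)
    for (nm in names(ab$grads)) gr$low$aspp[[nm]] <- ab$grads[[nm]]
    gbl <- ab$gx
  }
  gh <- encode_backward(gbh, g_low_skip, cache$enc_h$cache, pp$high, cfg)
  gl <- encode_backward(gbl, NULL, cache$enc_l$cache, pp$low, cfg)
  for (nm in names(gh)) gr$high[[nm]] <- gh[[nm]]
  for (nm in names(gl)) gr$low[[nm]] <- gl[[nm]]
  gr
}

#' Encode one patch through one branch
#'
#' @param model a `macn_model`.
#' @param patch (S, S, 3) patch already normalized to the model's input
#'   range (centered at 0).
#' @param branch `"high"` or `"low"`.
#' @return list with `low_level` (factor-4 features) and `bottleneck`
#'   (factor `output_stride` features), each carrying a
#'   `downsample_factor` attribute.
#' @export
macn_encode <- function(model, patch, branch = c("high", "low")) {
  branch <- match.arg(branch)
  cfg <- model$config
  if (!identical(dim(patch)[1:2], c(cfg$input_size, cfg$input_size))) {
    stop(sprintf("patch must be %dx%d", cfg$input_size, cfg$input_size))
  }
  enc <- encode_forward(patch, model$params[[branch]], cfg)
  structure(list(low_level = structure(enc$low_level, downsample_factor = 4L),
                 bottleneck = structure(enc$bottleneck,
                                        downsample_factor = cfg$output_stride)),
            class = "macn_features")
}

#' Atrous spatial pyramid pooling on a bottleneck feature map
#'
#' Dense mode chains dilated 3x3 branches, each seeing the concatenation of
#' the input and all previous branch outputs; parallel mode feeds every
#' branch from the input alone; `none` is the identity.  Dilation rates
#' that reach or exceed the spatial size are clamped (with a warning) so
#' every tap stays inside the padded map.
#'
#' @param model a `macn_model` (supplies weights and mode).
#' @param feature bottleneck (S, S, C) array.
#' @param branch which branch's weights to use.
#' @return enriched (S, S, C) array.
#' @export
macn_aspp <- function(model, feature, branch = c("high", "low")) {
  branch <- match.arg(branch)
  cfg <- model$config
  if (cfg$aspp_mode == "none") return(feature)
  if (any(cfg$aspp_rates >= dim(feature)[1L])) {
    warning(sprintf("dilation rates (%s) clamped to fit a %dx%d feature map",
                    paste(cfg$aspp_rates, collapse = ", "),
                    dim(feature)[1L], dim(feature)[2L]))
  }
  aspp_forward(feature, model$params[[branch]]$aspp, cfg)$out
}

#' Decode fused features into full-resolution logits
#'
#' Upsamples the fused bottleneck to the factor-4 grid (one or two bilinear
#' x2 steps depending on the output stride), concatenates 1x1-projected
#' low-level skip features, merges with two 3x3 convolutions, classifies,
#' and bilinearly upsamples to the input resolution.
#'
#' @param model a `macn_model` with `decoder_enabled = TRUE`.
#' @param fused fused bottleneck features.
#' @param low_level factor-4 low-level features of the high branch.
#' @return (S, S, num_classes) logits.
#' @export
macn_decode <- function(model, fused, low_level) {
  cfg <- model$config
  if (!cfg$decoder_enabled) stop("model configured without decoder")
  pp <- model$params
  s <- cfg$input_size
  if (dim(low_level)[1L] != s %/% 4L) {
    stop(sprintf("low_level features must be at downsample factor 4 (%dx%d), got %dx%d",
                 s %/% 4L, s %/% 4L, dim(low_level)[1L], dim(low_level)[2L]))
  }
  y <- fused
  while (dim(y)[1L] < s %/% 4L) {
    y <- resize_bilinear(y, dim(y)[1L] * 2L, dim(y)[2L] * 2L)
  }
  sk <- conv_forward(low_level, pp$dec$skip$W, pp$dec$skip$b,
                     stride = 1L, pad = 0L)
  catd <- cat_channels(y, sk$out)
  a1 <- relu(conv_forward(catd, pp$dec$m1$W, pp$dec$m1$b,
                          stride = 1L, pad = 1L)$out)
  a2 <- relu(conv_forward(a1, pp$dec$m2$W, pp$dec$m2$b,
                          stride = 1L, pad = 1L)$out)
  cl <- conv_forward(a2, pp$dec$cls$W, pp$dec$cls$b, stride = 1L, pad = 0L)
  resize_bilinear(cl$out, s, s)
}

#' Segment one co-centered patch pair
#'
#' @param model a `macn_model`.
#' @param pair a `patch_pair` (or any list with `high_patch`, `low_patch`).
#' @return list with `probs` (per-pixel class probabilities) and `mask`
#'   (argmax; exact ties resolve to background).
#' @export
macn_predict <- function(model, pair) {
  out <- macn_forward(model, pair$high_patch, pair$low_patch)
  p_fg <- out$probs[, , 2L]
  list(probs = out$probs, mask = (p_fg > 0.5) * 1L)
}
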