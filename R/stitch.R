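# ---------------------------------------------------------------------------
# Tile-stitched whole-image inference: tile the base image into co-centered
# patch pairs, run the network on every pair, average the per-pixel class
# probabilities over overlapping tiles, and argmax (ties to background).
# ---------------------------------------------------------------------------

#' Segment a whole image by tiled patch-pair inference
#'
#' @param model a `macn_model`.
#' @param image (H, W, 3) array in \[0, 1\]; must be at least one window
#'   wide and tall.
#' @param n_levels pyramid depth (default 2: the two-magnification setup).
#' @param stride tiling stride on the high level; defaults to half a
#'   window, which overlaps tiles for smoother seams.  `stride = window`
#'   reproduces the blockwise concatenation of independent per-patch masks.
#' @return list with `mask` (binary H x W), `prob` (foreground probability
#'   H x W) and `coverage` (tiles covering each pixel).
#' @export
predict_stitch <- function(model, image, n_levels = 2L,
                           stride = model$config$input_size %/% 2L) {
  window <- model$config$input_size
  d <- dim(image)
  if (d[1L] < window || d[2L] < window) {
    stop(sprintf("image %dx%d smaller than the %d-px window", d[1L], d[2L],
                 window))
  }
  pyr <- build_pyramid(image, n_levels)
  pairs <- extract_patch_pairs(pyr, high_level = 0L, low_level = 1L,
                               window = window, stride = stride)
  prob_acc <- matrix(0, d[1L], d[2L])
  cover <- matrix(0L, d[1L], d[2L])
  for (p in pairs) {
    out <- macn_forward(model, p$high_patch, p$low_patch)
    r0 <- p$center_base[1L] - window %/% 2L
    c0 <- p$center_base[2L] - window %/% 2L
    rr <- (r0 + 1L):(r0 + window)
    cc <- (c0 + 1L):(c0 + window)
    prob_acc[rr, cc] <- prob_acc[rr, cc] + out$probs[, , 2L]
    cover[rr, cc] <- cover[rr, cc] + 1L
  }
  seen <- cover > 0L
  prob <- matrix(0, d[1L], d[2L])
  prob[seen] <- prob_acc[seen] / cover[seen]
  list(mask = (prob > 0.5) * 1L, prob = prob, coverage = cover)
}
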