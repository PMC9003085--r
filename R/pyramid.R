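# ---------------------------------------------------------------------------
# Image pyramids and co-centered multi-magnification patch pairs.
#
# Geometry conventions (fixed for testability):
#   * 0-based (row, col) coordinates; windows are half-open
#     [origin, origin + window).
#   * level k of a pyramid has ceil(dim/2) of level k-1, produced by bilinear
#     resampling (half-pixel centers), so level k maps to base coordinates by
#     multiplying by 2^k.
#   * the sliding window tiles the high-magnification level; the
#     low-magnification window is centered on the same base-level location.
# ---------------------------------------------------------------------------

#' Build a bilinear image pyramid
#'
#' Level 0 is the input image unchanged; each further level halves both
#' spatial dimensions (ceiling division for odd sizes) by bilinear
#' resampling, emulating how a whole-slide scan at base magnification (say
#' 40x) is viewed at progressively lower magnifications (20x, 10x, ...).
#'
#' @param image numeric array (H, W, C) with values in \[0, 1\].
#' @param n_levels number of pyramid levels (>= 1), including level 0.
#' @param base_magnification nominal magnification of level 0 (metadata
#'   only).
#' @return an object of class `image_pyramid`: list with `levels` (list of
#'   arrays), `base_magnification`, `factor_per_level` (always 2) and
#'   `level_shapes`.
#' @export
build_pyramid <- function(image, n_levels, base_magnification = 40) {
  if (length(dim(image)) == 2L) image <- array(image, dim = c(dim(image), 1L))
  d <- dim(image)
  if (!is.numeric(n_levels) || n_levels < 1L) {
    stop("n_levels must be a positive integer")
  }
  n_levels <- as.integer(n_levels)
  if (min(d[1:2]) < 2^(n_levels - 1L)) {
    stop(sprintf(
      "image of size %dx%d is too small for %d pyramid levels (needs >= %d px per side)",
      d[1L], d[2L], n_levels, 2^(n_levels - 1L)))
  }
  levels <- vector("list", n_levels)
  levels[[1L]] <- image
  for (k in seq_len(n_levels - 1L)) {
    prev <- levels[[k]]
    dp <- dim(prev)
    levels[[k + 1L]] <- resize_bilinear(prev, ceiling(dp[1L] / 2),
                                        ceiling(dp[2L] / 2))
  }
  structure(list(levels = levels,
                 base_magnification = base_magnification,
                 factor_per_level = 2L,
                 level_shapes = lapply(levels, function(x) dim(x)[1:2])),
            class = "image_pyramid")
}

#' @export
print.image_pyramid <- function(x, ...) {
  cat(sprintf("<image_pyramid: %d levels, base %gx, shapes %s>\n",
              length(x$levels), x$base_magnification,
              paste(vapply(x$level_shapes,
                           function(s) paste(s, collapse = "x"), ""),
                    collapse = ", ")))
  invisible(x)
}

# reflection-padded window extraction: rows/cols are 0-based origins,
# window extends [origin, origin + window) and indices outside the image
# are reflected about the borders (no pixel duplication at the edge fold).
reflect_index <- function(idx, n) {
  # 0-based reflection onto [0, n)
  if (n == 1L) return(rep.int(0L, length(idx)))
  period <- 2L * (n - 1L)
  idx <- idx %% period
  idx[idx < 0L] <- idx[idx < 0L] + period
  ifelse(idx >= n, period - idx, idx)
}

extract_window <- function(image, origin_row, origin_col, window) {
  d <- dim(image)
  rows <- reflect_index(origin_row + 0:(window - 1L), d[1L]) + 1L
  cols <- reflect_index(origin_col + 0:(window - 1L), d[2L]) + 1L
  image[rows, cols, , drop = FALSE]
}

#' Extract co-centered multi-magnification patch pairs
#'
#' A fixed-size window slides over the high-magnification level with the
#' given stride; for every window the low-magnification patch is the
#' window-sized region of the lower level centered at the same base-level
#' location, so the high patch's field of view is the central 1/r fraction
#' of the low patch's (r = 2 per level difference).  Low windows that extend
#' past the image border are reflection-padded.
#'
#' @param pyramid an `image_pyramid`.
#' @param high_level,low_level pyramid levels of the two branches
#'   (`high_level < low_level`; smaller level = higher magnification).
#' @param window patch side in pixels (default 256).
#' @param stride window step on the high level; defaults to `window`
#'   (non-overlapping tiling).
#' @param mask optional base-level (level 0) binary mask; when given, each
#'   pair carries the mask restricted to the high patch footprint.
#' @return list of `patch_pair` objects, each with `high_patch`,
#'   `low_patch`, `center_base` (0-based row, col at level 0), `high_level`,
#'   `low_level` and optional `mask_patch`.
#' @export
extract_patch_pairs <- function(pyramid, high_level = 0L, low_level = 1L,
                                window = 256L, stride = window, mask = NULL) {
  stopifnot(inherits(pyramid, "image_pyramid"))
  n <- length(pyramid$levels)
  if (!(high_level < low_level && low_level < n)) {
    stop("need high_level < low_level < number of levels")
  }
  if (stride < 1L) stop("stride must be >= 1")
  hi_img <- pyramid$levels[[high_level + 1L]]
  lo_img <- pyramid$levels[[low_level + 1L]]
  dh <- dim(hi_img)
  if (dh[1L] < window || dh[2L] < window) {
    warning(sprintf("high level %d (%dx%d) is smaller than the %d-px window; no patches",
                    high_level, dh[1L], dh[2L], window))
    return(list())
  }
  origins_r <- seq.int(0L, dh[1L] - window, by = stride)
  origins_c <- seq.int(0L, dh[2L] - window, by = stride)
  r_hi <- 2^high_level    # base px per high-level px
  r_lo <- 2^low_level
  pairs <- vector("list", length(origins_r) * length(origins_c))
  i <- 0L
  for (orow in origins_r) {
    for (ocol in origins_c) {
      i <- i + 1L
      center_base <- c(orow + window %/% 2L, ocol + window %/% 2L) * r_hi
      lo_origin <- floor(center_base / r_lo) - window %/% 2L
      mask_patch <- NULL
      if (!is.null(mask) && high_level == 0L) {
        mask_patch <- mask[(orow + 1L):(orow + window),
                           (ocol + 1L):(ocol + window)]
      } else if (!is.null(mask)) {
        # nearest-neighbour reduction of the base mask onto the high level
        rows <- pmin(dim(mask)[1L], (orow + 0:(window - 1L)) * r_hi + 1L)
        cols <- pmin(dim(mask)[2L], (ocol + 0:(window - 1L)) * r_hi + 1L)
        mask_patch <- mask[rows, cols]
      }
      pairs[[i]] <- structure(list(
        high_patch = hi_img[(orow + 1L):(orow + window),
                            (ocol + 1L):(ocol + window), , drop = FALSE],
        low_patch = extract_window(lo_img, lo_origin[1L], lo_origin[2L],
                                   window),
        center_base = center_base,
        high_level = as.integer(high_level),
        low_level = as.integer(low_level),
        window = as.integer(window),
        mask_patch = mask_patch), class = "patch_pair")
    }
  }
  pairs
}

#' Retain patch pairs containing annotated structures
#'
#' Mirrors the dataset-construction rule used when most tiles of a liver
#' slide are plain hepatocyte background: a pair is kept only if its
#' high-patch footprint contains at least `min_pixels` annotated pixels of
#' any of the named structures (bile duct, artery, vein, fibrosis), which
#' rebalances the tile set toward portal areas.
#'
#' @param pairs list of `patch_pair`s.
#' @param annotations named list of base-level binary masks, e.g.
#'   `list(duct = ..., artery = ..., fibrosis = ...)`.  `NULL` or empty
#'   retains everything with a warning.
#' @param min_pixels minimum annotated pixels for retention (default 1:
#'   presence, not area).
#' @return list with `retained` (the kept pairs) and `index`, a data.frame
#'   with one row per input pair: patch_id, center_row, center_col,
#'   high_level, low_level, retained, structure_flags.
#' @export
filter_patches <- function(pairs, annotations, min_pixels = 1L) {
  if (is.null(annotations) || length(annotations) == 0L) {
    warning("no annotation masks supplied; retaining all patch pairs")
    annotations <- list()
  }
  n <- length(pairs)
  rows <- vector("list", n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    p <- pairs[[i]]
    half <- p$window %/% 2L * 2^p$high_level
    r0 <- p$center_base[1L] - half
    c0 <- p$center_base[2L] - half
    side <- p$window * 2^p$high_level
    flags <- character(0)
    for (nm in names(annotations)) {
      m <- annotations[[nm]]
      rr <- (r0 + 1L):min(r0 + side, nrow(m))
      cc <- (c0 + 1L):min(c0 + side, ncol(m))
      if (sum(m[rr, cc]) >= min_pixels) flags <- c(flags, nm)
    }
    keep[i] <- length(annotations) == 0L || length(flags) > 0L
    rows[[i]] <- data.frame(
      patch_id = sprintf("p%05d_r%d_c%d", i, p$center_base[1L],
                         p$center_base[2L]),
      center_row = p$center_base[1L], center_col = p$center_base[2L],
      high_level = p$high_level, low_level = p$low_level,
      retained = keep[i],
      structure_flags = paste(flags, collapse = "+"),
      stringsAsFactors = FALSE)
  }
  list(retained = pairs[keep], index = do.call(rbind, rows))
}

#' Write patch pairs to disk as paired PNGs plus a CSV index
#'
#' @param pairs list of `patch_pair`s.
#' @param dir output directory (created if missing).
#' @param index optional index data.frame from [filter_patches()]; written
#'   as `index.csv`.
#' @return invisibly, the vector of patch ids written.
#' @export
write_patch_pairs <- function(pairs, dir, index = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- character(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    ids[i] <- sprintf("p%05d_r%d_c%d", i, p$center_base[1L], p$center_base[2L])
    png::writePNG(p$high_patch, file.path(dir, paste0(ids[i], "_hi.png")))
    png::writePNG(p$low_patch, file.path(dir, paste0(ids[i], "_lo.png")))
    if (!is.null(p$mask_patch)) {
      png::writePNG(p$mask_patch * 1.0,
                    file.path(dir, paste0(ids[i], "_mask.png")))
    }
  }
  if (!is.null(index)) {
    utils::write.csv(index, file.path(dir, "index.csv"), row.names = FALSE)
  }
  invisible(ids)
}

#' Read an RGB image (PNG or TIFF) as an (H, W, 3) array in \[0, 1\]
#' @param path file path; format chosen by extension.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' Read a single-channel mask PNG, normalizing \{0, 255\} to \{0, 1\}
#' @param path PNG path.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  (m > 0.5) * 1L
}
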