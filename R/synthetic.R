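# ---------------------------------------------------------------------------
# Seedable histology-like scene generator.
#
# Emulates the structures of a Masson-stained portal area at base
# magnification: bile ducts as thin-walled annuli (lumen + epithelial
# wall), hepatic-artery distractors as thicker-walled annuli in a nearby
# hue (the classic confusion case), fibrosis as a smooth low-frequency
# collagen-like texture, hepatocyte-like background, and additive Gaussian
# pixel noise.  Ground truth is exact by construction: the duct mask marks
# precisely the duct wall pixels.
# ---------------------------------------------------------------------------

#' Specification of one synthetic scene
#'
#' @param image_size (height, width) in pixels.
#' @param n_ducts number of bile-duct annuli.
#' @param duct_inner_radius_range (min, max) lumen radius in px.
#' @param duct_wall_thickness_range (min, max) epithelial wall thickness in
#'   px (>= 1).
#' @param n_arteries number of artery-like distractor annuli (thicker
#'   walls, similar hue).
#' @param artery_inner_radius_range,artery_wall_thickness_range artery
#'   geometry; walls default noticeably thicker than duct walls.
#' @param fibrosis_texture_amplitude amplitude in \[0, 1\] of the smooth
#'   collagen-like texture field.
#' @param background_color,duct_color,artery_color,fibrosis_color RGB
#'   triples in \[0, 1\]; defaults approximate Masson hues (pink-lavender
#'   hepatocytes, red-purple epithelium, blue-green collagen).
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @param seed integer seed; identical specs (including seed) generate
#'   bit-identical scenes.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(512L, 512L),
                       n_ducts = 3L,
                       duct_inner_radius_range = c(6, 14),
                       duct_wall_thickness_range = c(3, 6),
                       n_arteries = 2L,
                       artery_inner_radius_range = c(8, 16),
                       artery_wall_thickness_range = c(9, 14),
                       fibrosis_texture_amplitude = 0.12,
                       background_color = c(0.84, 0.72, 0.80),
                       duct_color = c(0.55, 0.22, 0.38),
                       artery_color = c(0.70, 0.33, 0.42),
                       fibrosis_color = c(0.42, 0.58, 0.62),
                       noise_sigma = 0.02,
                       seed = 1L) {
  spec <- list(image_size = as.integer(image_size), n_ducts = as.integer(n_ducts),
               duct_inner_radius_range = duct_inner_radius_range,
               duct_wall_thickness_range = duct_wall_thickness_range,
               n_arteries = as.integer(n_arteries),
               artery_inner_radius_range = artery_inner_radius_range,
               artery_wall_thickness_range = artery_wall_thickness_range,
               fibrosis_texture_amplitude = fibrosis_texture_amplitude,
               background_color = background_color, duct_color = duct_color,
               artery_color = artery_color, fibrosis_color = fibrosis_color,
               noise_sigma = noise_sigma, seed = as.integer(seed))
  stopifnot(all(spec$duct_inner_radius_range > 0),
            all(spec$duct_wall_thickness_range >= 1),
            all(spec$artery_inner_radius_range > 0),
            all(spec$artery_wall_thickness_range >= 1),
            spec$fibrosis_texture_amplitude >= 0,
            spec$fibrosis_texture_amplitude <= 1,
            spec$noise_sigma >= 0)
  structure(spec, class = "scene_spec")
}

# annulus membership on the pixel grid: inner <= dist(center) < outer.
# Distances measured between pixel centers (0-based integer grid).
annulus_mask <- function(h, w, center, inner, outer) {
  dr <- outer(0:(h - 1L) - center[1L], rep(1, w))
  dc <- outer(rep(1, h), 0:(w - 1L) - center[2L])
  dist <- sqrt(dr^2 + dc^2)
  dist >= inner & dist < outer
}

# smooth unit-amplitude random field: coarse iid grid bilinearly upsampled
smooth_field <- function(h, w, cells = 8L) {
  coarse <- matrix(runif(cells * cells, -1, 1), cells, cells)
  resize_bilinear(coarse, h, w)
}

#' Generate one synthetic portal-area scene
#'
#' Structures are placed by rejection sampling with a margin of one outer
#' radius from the border and no overlap between any two annuli
#' (duct and artery masks are disjoint by construction).
#'
#' @param spec a [scene_spec()].
#' @param max_attempts rejection-sampling attempts per structure before
#'   giving up with an error naming the crowded spec.
#' @return object of class `scene`: list with `image` (H, W, 3),
#'   `duct_mask` (binary matrix), `structure_masks` (list duct/artery/
#'   fibrosis) and `spec`.
#' @export
generate_scene <- function(spec, max_attempts = 200L) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  set.seed(spec$seed)

  occupied <- matrix(FALSE, h, w)

  place_annuli <- function(n, inner_range, wall_range) {
    target <- matrix(FALSE, h, w)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        inner <- runif(1, inner_range[1L], inner_range[2L])
        wall <- runif(1, wall_range[1L], wall_range[2L])
        outer_r <- inner + wall
        margin <- ceiling(outer_r) + 2L
        if (2L * margin >= min(h, w)) next
        center <- c(sample(margin:(h - margin - 1L), 1L),
                    sample(margin:(w - margin - 1L), 1L))
        disk <- annulus_mask(h, w, center, 0, outer_r + 2)
        if (any(occupied & disk)) next
        ring <- annulus_mask(h, w, center, inner, outer_r)
        occupied <<- occupied | disk
        target <- target | ring
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf(
          "could not place structure %d of %d in a %dx%d scene after %d attempts; spec too crowded",
          i, n, h, w, max_attempts))
      }
    }
    target
  }

  duct_mask <- place_annuli(spec$n_ducts, spec$duct_inner_radius_range,
                            spec$duct_wall_thickness_range)
  artery_mask <- place_annuli(spec$n_arteries, spec$artery_inner_radius_range,
                              spec$artery_wall_thickness_range)

  # collagen-like texture: smooth field; its high quantile is the fibrosis
  # region that the retention filter can key on
  field <- smooth_field(h, w)
  fib_strength <- pmax(field, 0) * spec$fibrosis_texture_amplitude
  fibrosis_mask <- field > stats::quantile(field, 0.85)

  image <- array(0, dim = c(h, w, 3L))
  for (c in 1:3) {
    plane <- matrix(spec$background_color[c], h, w)
    plane <- plane + fib_strength * (spec$fibrosis_color[c] -
                                       spec$background_color[c])
    # structures overwrite the background/fibrosis tint
    plane[duct_mask] <- spec$duct_color[c]
    plane[artery_mask] <- spec$artery_color[c]
    image[, , c] <- plane
  }
  if (spec$noise_sigma > 0) {
    image <- image + array(rnorm(h * w * 3L, sd = spec$noise_sigma),
                           dim = dim(image))
  }
  image <- pmin(pmax(image, 0), 1)

  structure(list(image = image,
                 duct_mask = duct_mask * 1L,
                 structure_masks = list(duct = duct_mask * 1L,
                                        artery = artery_mask * 1L,
                                        fibrosis = fibrosis_mask * 1L),
                 spec = spec),
            class = "scene")
}

# deterministic per-scene seed from a master seed (documented fixed hash)
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 2654435761 + index * 97) %% 2147483647)
}

#' Generate a seeded multi-scene dataset with a scene-level split
#'
#' Per-scene seeds derive deterministically from the master seed
#' (`(master * 2654435761 + index * 97) mod 2^31-1`), so the manifest is
#' reproducible regardless of generation order.  Train/test assignment is
#' by scene, never by patch, mirroring case-level splits in histopathology
#' studies: no tile of a test scene can leak into training.
#'
#' @param n_scenes number of scenes (>= 1).
#' @param spec_template a [scene_spec()] whose seed field is overridden per
#'   scene.
#' @param seed master seed.
#' @param train_fraction fraction of scenes assigned to training.
#' @return list with `scenes` (list of `scene`), `manifest` (data.frame of
#'   scene_id, seed, split) and the arguments.
#' @export
generate_dataset <- function(n_scenes, spec_template = scene_spec(),
                             seed = 1L, train_fraction = 0.5) {
  stopifnot(n_scenes >= 1L)
  scenes <- vector("list", n_scenes)
  seeds <- vapply(seq_len(n_scenes), function(i) derive_seed(seed, i), 0L)
  n_train <- round(n_scenes * train_fraction)
  split <- rep("test", n_scenes)
  if (n_train > 0L) split[seq_len(n_train)] <- "train"
  for (i in seq_len(n_scenes)) {
    sp <- spec_template
    sp$seed <- seeds[i]
    scenes[[i]] <- generate_scene(sp)
  }
  manifest <- data.frame(scene_id = sprintf("scene%03d", seq_len(n_scenes)),
                         seed = seeds, split = split,
                         stringsAsFactors = FALSE)
  list(scenes = scenes, manifest = manifest, master_seed = seed,
       train_fraction = train_fraction)
}

#' Write a dataset to disk as PNGs plus a JSON manifest
#' @param dataset result of [generate_dataset()].
#' @param dir output directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$scenes)) {
    sc <- dataset$scenes[[i]]
    id <- dataset$manifest$scene_id[i]
    png::writePNG(sc$image, file.path(dir, paste0(id, ".png")))
    png::writePNG(sc$duct_mask * 1.0, file.path(dir, paste0(id, "_duct.png")))
    for (nm in names(sc$structure_masks)) {
      png::writePNG(sc$structure_masks[[nm]] * 1.0,
                    file.path(dir, paste0(id, "_", nm, ".png")))
    }
  }
  manifest <- dataset$manifest
  manifest$spec <- I(rep(list(unclass(dataset$scenes[[1L]]$spec)),
                         nrow(manifest)))
  for (i in seq_len(nrow(manifest))) {
    manifest$spec[[i]] <- unclass(dataset$scenes[[i]]$spec)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
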