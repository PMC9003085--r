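# ---------------------------------------------------------------------------
# Ablation harness over the five architectural axes: fusion mode, crop
# mode, pyramid-pooling mode, decoder, and focal gamma.  Every variant is
# trained from the same seed on the same data; trained variants are cached
# by configuration signature so rebuilding the report from cache is
# deterministic and free.
# ---------------------------------------------------------------------------

#' Ablation plan over the five architectural axes
#'
#' @param gammas focal gamma sweep (default 0:4; gamma 0 is plain
#'   cross-entropy).
#' @return object of class `ablation_plan`: named list of axes, each a list
#'   of named [model_config()] field deltas.
#' @export
ablation_plan <- function(gammas = 0:4) {
  axes <- list(
    fusion_mode = list(attention = list(fusion_mode = "attention"),
                       concatenation = list(fusion_mode = "concatenation")),
    crop_mode = list(central_crop = list(crop_mode = "central_crop"),
                     no_crop = list(crop_mode = "none")),
    aspp_mode = list(dense_aspp = list(aspp_mode = "dense_aspp"),
                     aspp = list(aspp_mode = "aspp")),
    decoder = list(with_decoder = list(decoder_enabled = TRUE),
                   without_decoder = list(decoder_enabled = FALSE)),
    focal_gamma = stats::setNames(
      lapply(gammas, function(g) list(focal_gamma = g)),
      paste0("gamma", gammas)))
  structure(axes, class = "ablation_plan")
}

config_signature <- function(cfg) {
  paste(vapply(unclass(cfg), function(x) paste(x, collapse = ","), ""),
        collapse = "|")
}

#' Train and evaluate every ablation variant
#'
#' Applies each delta of the plan to the base configuration, trains from
#' the base seed on the training pairs, evaluates micro-averaged metrics on
#' the test pairs, and returns one report row per variant in the layout
#' axis / variant / precision / recall / f1 / iou.  Variants that share a
#' configuration (e.g. the proposed setting appearing on every axis) are
#' trained once and reused from `cache`.
#'
#' @param plan an [ablation_plan()].
#' @param base a [train_config()] for the proposed setting.
#' @param train_pairs,test_pairs labelled `patch_pair`s.
#' @param cache optional environment of trained models keyed by config
#'   signature; pass the same environment to re-run from cache.
#' @param csv_path optional output CSV.
#' @param verbose print one line per variant.
#' @return data.frame with columns axis, variant, precision, recall, f1,
#'   iou.
#' @export
macn_ablate <- function(plan, base, train_pairs, test_pairs,
                        cache = new.env(parent = emptyenv()),
                        csv_path = NULL, verbose = FALSE) {
  stopifnot(inherits(plan, "ablation_plan"), inherits(base, "train_config"))
  rows <- list()
  for (axis in names(plan)) {
    for (variant in names(plan[[axis]])) {
      delta <- plan[[axis]][[variant]]
      mcfg <- unclass(base$model)
      mcfg[names(delta)] <- delta
      mcfg <- do.call(model_config, mcfg)
      tcfg <- base
      tcfg$model <- mcfg
      tcfg$loss <- loss_config(kind = base$loss$kind,
                               gamma = mcfg$focal_gamma,
                               class_weights = base$loss$class_weights)
      key <- config_signature(mcfg)
      if (is.null(cache[[key]])) {
        cache[[key]] <- macn_train(tcfg, train_pairs)$model
      }
      m <- macn_evaluate(cache[[key]], test_pairs)$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axis, variant = variant, precision = m$precision,
        recall = m$recall, f1 = m$f1, iou = m$iou,
        stringsAsFactors = FALSE)
      if (verbose) {
        message(sprintf("%-12s %-16s P %.3f R %.3f F1 %.3f IoU %.3f",
                        axis, variant, m$precision, m$recall, m$f1, m$iou))
      }
    }
  }
  report <- do.call(rbind, rows)
  if (!is.null(csv_path)) utils::write.csv(report, csv_path, row.names = FALSE)
  report
}
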