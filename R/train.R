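# ---------------------------------------------------------------------------
# Training / evaluation orchestration.
#
# Desk-scale defaults: Adam at a fixed learning rate, step-budget training
# on shuffled mini-batches of co-centered patch pairs, JSON-lines logging,
# and micro-averaged (pooled-count) evaluation.
# ---------------------------------------------------------------------------

#' Loss configuration
#'
#' @param kind `"focal"` or `"cross_entropy"`.
#' @param gamma focusing exponent for the focal loss (>= 0); `gamma = 0`
#'   makes the focal loss identical to cross-entropy.
#' @param class_weights optional per-class scalars (background, foreground).
#' @export
loss_config <- function(kind = c("focal", "cross_entropy"), gamma = 1,
                        class_weights = NULL) {
  kind <- match.arg(kind)
  if (gamma < 0) stop("gamma must be >= 0")
  if (kind == "cross_entropy") gamma <- 0
  structure(list(kind = kind, gamma = gamma, class_weights = class_weights),
            class = "loss_config")
}

#' Training configuration
#'
#' @param model a [model_config()].
#' @param loss a [loss_config()]; its gamma defaults to the model's
#'   `focal_gamma`.
#' @param optimizer_name `"adam"` or `"sgd"` (momentum 0.9).
#' @param learning_rate,batch_size,max_steps optimization budget.
#' @param seed master seed for init, shuffling and any data generation.
#' @param data_dir,checkpoint_path,log_path,report_path optional paths used
#'   by the CLI workflow; in-memory use passes data directly to
#'   [macn_train()].
#' @param eval_every evaluate on the validation pairs every this many steps
#'   (0 = only at the end).
#' @export
train_config <- function(model = model_config(),
                         loss = loss_config(gamma = model$focal_gamma),
                         optimizer_name = c("adam", "sgd"),
                         learning_rate = 1e-3,
                         batch_size = 8L,
                         max_steps = 300L,
                         seed = 1L,
                         data_dir = NULL,
                         checkpoint_path = NULL,
                         log_path = NULL,
                         report_path = NULL,
                         eval_every = 0L) {
  optimizer_name <- match.arg(optimizer_name)
  structure(list(model = model, loss = loss,
                 optimizer_name = optimizer_name,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps),
                 seed = as.integer(seed),
                 data_dir = data_dir, checkpoint_path = checkpoint_path,
                 log_path = log_path, report_path = report_path,
                 eval_every = as.integer(eval_every)),
            class = "train_config")
}

#' Write / read a training configuration as YAML
#'
#' The round trip `read_train_config(write_train_config(x))` is the
#' identity.
#' @param config a [train_config()].
#' @param path YAML file path.
#' @export
write_train_config <- function(config, path) {
  yaml::write_yaml(list(model = unclass(config$model),
                        loss = unclass(config$loss),
                        train = unclass(config)[setdiff(names(config),
                                                        c("model", "loss"))]),
                   path)
  invisible(path)
}

#' @rdname write_train_config
#' @export
read_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  model <- do.call(model_config, y$model)
  loss <- do.call(loss_config, y$loss)
  do.call(train_config, c(list(model = model, loss = loss), y$train))
}

#' Cut a scene dataset into retained, labelled patch pairs
#'
#' Builds a 2-level bilinear pyramid per scene, extracts co-centered
#' high/low patch pairs, applies the structure-retention filter against the
#' scene's annotation masks, and attaches the duct mask of each high-patch
#' footprint as the training label.
#'
#' @param dataset result of [generate_dataset()].
#' @param high_level,low_level,window,stride passed to
#'   [extract_patch_pairs()].
#' @param min_pixels retention threshold of [filter_patches()].
#' @return list with `train` and `test`: lists of labelled `patch_pair`s,
#'   split at scene level.
#' @export
build_patch_dataset <- function(dataset, high_level = 0L, low_level = 1L,
                                window = 256L, stride = window,
                                min_pixels = 1L) {
  out <- list(train = list(), test = list())
  for (i in seq_along(dataset$scenes)) {
    sc <- dataset$scenes[[i]]
    pyr <- build_pyramid(sc$image, n_levels = low_level + 1L)
    pairs <- extract_patch_pairs(pyr, high_level, low_level, window, stride,
                                 mask = sc$duct_mask)
    flt <- filter_patches(pairs, sc$structure_masks, min_pixels)
    split <- dataset$manifest$split[i]
    out[[split]] <- c(out[[split]], flt$retained)
  }
  out
}

log_jsonl <- function(path, record) {
  if (is.null(path)) return(invisible(NULL))
  cat(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = path, append = TRUE)
}

#' Train a model on labelled patch pairs
#'
#' Optimizes the configured loss over shuffled mini-batches.  Training
#' aborts with a diagnostic on a NaN loss and on an empty dataset.  The
#' JSON-lines log (append-only) records one `{"step", "loss"}` record per
#' step plus periodic validation metrics.
#'
#' @param config a [train_config()].
#' @param pairs list of labelled `patch_pair`s (each with `mask_patch`).
#' @param val_pairs optional held-out pairs for periodic evaluation.
#' @param model optional warm-start `macn_model`; defaults to a fresh
#'   [macn_init()] from `config$model`.
#' @param verbose print progress lines.
#' @return list with `model`, `losses` (per-step vector) and `log_path`.
#' @export
macn_train <- function(config, pairs, val_pairs = NULL, model = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (length(pairs) == 0L) stop("training dataset is empty")
  if (any(vapply(pairs, function(p) is.null(p$mask_patch), TRUE))) {
    stop("all training pairs need a mask_patch label")
  }
  if (is.null(model)) model <- macn_init(config$model)
  set.seed(config$seed)
  gamma <- if (config$loss$kind == "focal") config$loss$gamma else 0
  cw <- config$loss$class_weights
  opt <- adam_init(model$params)
  sgd_v <- NULL
  losses <- numeric(config$max_steps)
  for (step in seq_len(config$max_steps)) {
    idx <- sample.int(length(pairs), min(config$batch_size, length(pairs)),
                      replace = length(pairs) < config$batch_size)
    gacc <- NULL
    lsum <- 0
    for (j in idx) {
      p <- pairs[[j]]
      fw <- macn_forward(model, p$high_patch, p$low_patch, keep_cache = TRUE)
      lg <- focal_loss_grad(fw$probs, p$mask_patch, gamma, class_weights = cw)
      lsum <- lsum + lg$loss
      gr <- macn_backward(model, fw$cache, lg$glogits)
      gacc <- if (is.null(gacc)) gr else grad_tree_add(gacc, gr)
    }
    gacc <- grad_tree_scale(gacc, 1 / length(idx))
    loss <- lsum / length(idx)
    if (!is.finite(loss)) {
      stop(sprintf("non-finite loss %g at step %d; aborting training", loss,
                   step))
    }
    losses[step] <- loss
    if (config$optimizer_name == "adam") {
      upd <- adam_step(model$params, gacc, opt, lr = config$learning_rate)
      model$params <- upd$params
      opt <- upd$state
    } else {
      g <- unlist(gacc, recursive = TRUE, use.names = FALSE)
      if (is.null(sgd_v)) sgd_v <- numeric(length(g))
      sgd_v <- 0.9 * sgd_v - config$learning_rate * g
      pflat <- unlist(model$params, recursive = TRUE, use.names = FALSE)
      model$params <- utils::relist(pflat + sgd_v, model$params)
    }
    log_jsonl(config$log_path, list(step = step, loss = loss))
    if (verbose && (step %% 25L == 0L || step == 1L)) {
      message(sprintf("step %4d  loss %.5f", step, loss))
    }
    if (!is.null(val_pairs) && config$eval_every > 0L &&
        step %% config$eval_every == 0L) {
      vm <- macn_evaluate(model, val_pairs)$metrics
      log_jsonl(config$log_path,
                list(step = step, val_f1 = vm$f1, val_iou = vm$iou))
    }
  }
  if (!is.null(config$checkpoint_path)) {
    save_checkpoint(model, config$checkpoint_path)
  }
  list(model = model, losses = losses, log_path = config$log_path)
}

#' Evaluate a model on labelled pairs (micro-averaged)
#'
#' Pools TP/FP/FN/TN over all patches before computing the scores, matching
#' the pixel-count definitions of the metric suite.
#'
#' @param model a `macn_model`.
#' @param pairs labelled `patch_pair`s.
#' @param per_patch_csv optional path for a per-patch debugging CSV.
#' @return list with `metrics` (pooled `seg_metrics`) and `per_patch`
#'   (data.frame of counts and scores per patch).
#' @export
macn_evaluate <- function(model, pairs, per_patch_csv = NULL) {
  if (length(pairs) == 0L) stop("evaluation dataset is empty")
  rows <- vector("list", length(pairs))
  pooled <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    pr <- macn_predict(model, p)
    cc <- confusion_counts(pr$mask, p$mask_patch)
    pooled <- pooled + cc
    m <- compute_metrics(cc)
    rows[[i]] <- data.frame(patch = i, tp = cc[["tp"]], fp = cc[["fp"]],
                            fn = cc[["fn"]], tn = cc[["tn"]],
                            precision = m$precision, recall = m$recall,
                            f1 = m$f1, iou = m$iou)
  }
  per_patch <- do.call(rbind, rows)
  if (!is.null(per_patch_csv)) {
    utils::write.csv(per_patch, per_patch_csv, row.names = FALSE)
  }
  list(metrics = compute_metrics(pooled), per_patch = per_patch)
}

#' Save / load a model checkpoint
#'
#' The parameter archive is a single RDS file; a JSON sidecar
#' (`<path>.json`) records the full model configuration.  Loading validates
#' that the stored parameters match the sidecar's architecture.
#' @param model a `macn_model`.
#' @param path checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  cfgl <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  config <- do.call(model_config, cfgl)
  params <- readRDS(path)
  ref <- macn_init(config)
  if (!identical(lapply(rapply(params, dim, how = "list"), unlist),
                 lapply(rapply(ref$params, dim, how = "list"), unlist))) {
    stop("checkpoint parameters do not match the sidecar configuration")
  }
  structure(list(config = config, params = params), class = "macn_model")
}
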