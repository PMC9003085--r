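test_that("training overfits a repeated small batch and logs every step", {
  run <- overfit_run()
  expect_lt(run$losses[200L], 0.1 * run$losses[1L])

  # per-pixel accuracy above 99% on the memorized batch
  acc <- vapply(run$pairs, function(p) {
    mean(macn_predict(run$model, p)$mask == p$mask_patch)
  }, 0)
  expect_gt(mean(acc), 0.99)

  logs <- lapply(readLines(run$log_path), jsonlite::fromJSON)
  expect_identical(length(logs), 200L)
  expect_equal(logs[[1L]]$loss, run$losses[1L])
  expect_equal(logs[[200L]]$loss, run$losses[200L])
})

test_that("training is reproducible from the seed at the first steps", {
  setup <- small_train_setup()
  pairs <- setup$labelled[seq_len(min(4L, length(setup$labelled)))]
  tc <- train_config(model = setup$cfg, batch_size = 2L, max_steps = 2L,
                     seed = 11L)
  a <- macn_train(tc, pairs)
  b <- macn_train(tc, pairs)
  expect_identical(a$losses, b$losses)
})

test_that("a larger focal gamma strictly lowers the initial total loss", {
  setup <- small_train_setup()
  pairs <- setup$labelled[seq_len(min(4L, length(setup$labelled)))]
  base <- setup$cfg
  l1 <- macn_train(train_config(model = base,
                                loss = loss_config(gamma = 1),
                                batch_size = 2L, max_steps = 1L, seed = 6L),
                   pairs)$losses[1L]
  l4 <- macn_train(train_config(model = base,
                                loss = loss_config(gamma = 4),
                                batch_size = 2L, max_steps = 1L, seed = 6L),
                   pairs)$losses[1L]
  expect_lt(l4, l1)
})

test_that("training rejects empty or unlabelled datasets", {
  setup <- small_train_setup()
  tc <- train_config(model = setup$cfg, max_steps = 1L)
  expect_error(macn_train(tc, list()), "empty")
  unlabelled <- setup$pairs[[1L]]
  unlabelled$mask_patch <- NULL
  expect_error(macn_train(tc, list(unlabelled)), "mask_patch")
})

test_that("evaluation is self-consistent and pools counts over patches", {
  trained <- overfit_run()
  # score the model against its own predictions: perfect agreement
  self_pairs <- lapply(trained$pairs, function(p) {
    p$mask_patch <- macn_predict(trained$model, p)$mask
    p
  })
  expect_true(any(vapply(self_pairs, function(p) sum(p$mask_patch) > 0, TRUE)))
  ev <- macn_evaluate(trained$model, self_pairs)
  expect_equal(ev$metrics$precision, 1)
  expect_equal(ev$metrics$recall, 1)
  expect_equal(ev$metrics$f1, 1)
  expect_equal(ev$metrics$iou, 1)

  # micro-average equals metrics of the pooled per-patch counts
  csv <- withr::local_tempfile(fileext = ".csv")
  ev2 <- macn_evaluate(trained$model, trained$pairs, per_patch_csv = csv)
  per <- utils::read.csv(csv)
  pooled <- compute_metrics(c(tp = sum(per$tp), fp = sum(per$fp),
                              fn = sum(per$fn)))
  expect_equal(ev2$metrics$f1, pooled$f1)
  expect_equal(ev2$metrics$iou, pooled$iou)

  # degenerate all-background predictor has zero recall
  zero_model <- trained$model
  zero_model$params <- macnseg:::grad_tree_zero(zero_model$params)
  evz <- macn_evaluate(zero_model, trained$pairs)
  expect_equal(evz$metrics$recall, 0)
})

test_that("train configurations round-trip through YAML", {
  cfg <- train_config(model = tiny_config(focal_gamma = 2),
                      loss = loss_config(gamma = 2),
                      optimizer_name = "sgd", learning_rate = 5e-4,
                      batch_size = 3L, max_steps = 7L, seed = 99L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_train_config(cfg, path)
  back <- read_train_config(path)
  expect_equal(back, cfg)
})

test_that("checkpoints round-trip and validate their architecture sidecar", {
  trained <- overfit_run()
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_checkpoint(trained$model, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, trained$model$params)
  expect_equal(unclass(back$config), unclass(trained$model$config))

  # corrupt the sidecar: width no longer matches the stored parameters
  cfg <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg$backbone_width_multiplier <- 8L
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(load_checkpoint(path), "do not match")
})

test_that("the ablation plan spans the five architectural axes", {
  plan <- ablation_plan()
  expect_setequal(names(plan), c("fusion_mode", "crop_mode", "aspp_mode",
                                 "decoder", "focal_gamma"))
  expect_length(plan$focal_gamma, 5L)
  expect_identical(names(plan$focal_gamma),
                   paste0("gamma", 0:4))
})

test_that("ablation reports valid rows and is reproducible from cache", {
  setup <- small_train_setup()
  pairs <- setup$labelled
  expect_gte(length(pairs), 2L)
  base <- train_config(model = setup$cfg, batch_size = 2L, max_steps = 2L,
                       seed = 13L)
  cache <- new.env(parent = emptyenv())
  rep1 <- macn_ablate(ablation_plan(gammas = 0:1), base,
                      train_pairs = pairs, test_pairs = pairs[1:2],
                      cache = cache)
  expect_identical(nrow(rep1), 2L + 2L + 2L + 2L + 2L)
  expect_true(all(is.finite(unlist(rep1[, c("precision", "recall",
                                            "f1", "iou")]))))
  expect_true(all(rep1$iou >= 0 & rep1$iou <= 1))
  for (i in seq_len(nrow(rep1))) {
    if (rep1$f1[i] > 0) {
      expect_equal(rep1$iou[i], rep1$f1[i] / (2 - rep1$f1[i]),
                   tolerance = 1e-8)
    }
  }
  # rebuilding from the same cache trains nothing new: identical table
  rep2 <- macn_ablate(ablation_plan(gammas = 0:1), base,
                      train_pairs = pairs, test_pairs = pairs[1:2],
                      cache = cache)
  expect_identical(rep1, rep2)
})

test_that("stitched inference reassembles tile predictions exactly", {
  model <- overfit_run()$model
  set.seed(77)
  img <- generate_scene(scene_spec(image_size = c(128L, 128L), n_ducts = 1L,
                                   n_arteries = 0L,
                                   duct_inner_radius_range = c(5, 8),
                                   duct_wall_thickness_range = c(3, 5),
                                   seed = 55L))$image
  st <- predict_stitch(model, img, stride = 64L)
  expect_identical(dim(st$mask), c(128L, 128L))

  # stride = window: stitching is blockwise concatenation of patch masks
  pyr <- build_pyramid(img, 2)
  pairs <- extract_patch_pairs(pyr, 0L, 1L, window = 64L, stride = 64L)
  manual <- matrix(0L, 128L, 128L)
  for (p in pairs) {
    r0 <- p$center_base[1L] - 32L; c0 <- p$center_base[2L] - 32L
    manual[(r0 + 1L):(r0 + 64L), (c0 + 1L):(c0 + 64L)] <-
      macn_predict(model, p)$mask
  }
  expect_identical(st$mask, manual)

  # an all-zero model gives p = 0.5 everywhere: ties break to background
  zero_model <- model
  zero_model$params <- macnseg:::grad_tree_zero(zero_model$params)
  stz <- predict_stitch(zero_model, img, stride = 64L)
  expect_identical(sum(stz$mask), 0L)

  expect_error(predict_stitch(model, img[1:32, 1:32, , drop = FALSE]),
               "smaller")
})
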