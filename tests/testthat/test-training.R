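small_sets <- function(seed = 7, n_per_class = 8, window = c(-0.2, 0.824)) {
  ds <- tiny_separable_ds(n_subjects = 1, n_trials_per_class = n_per_class,
                          erd_depth = 0.8, snr = 3, seed = seed,
                          epoch_window = window)
  self_standardize(ds)
}

test_that("zero-epoch training returns the parameters untouched", {
  ds <- small_sets()
  m <- with_seed(3, build_model(tiny_cfg()))
  before <- param_snapshot(m)
  res <- train_model(m, ds, ds, train_plan("scratch", epochs = 0, seed = 1))
  expect_identical(param_snapshot(res$model), before)
  expect_length(res$history$train_loss, 0)
})

test_that("an all-frozen policy makes training a no-op on the parameters", {
  ds <- small_sets()
  m <- with_seed(3, build_model(tiny_cfg()))
  before <- param_snapshot(m)
  fp <- freeze_policy(conv_frozen = TRUE, bilstm_frozen = TRUE,
                      transformer_frozen_layers = 0L, mlp_frozen = TRUE)
  plan <- train_plan("finetune_full", epochs = 2, freeze_policy = fp,
                     seed = 1, batch_size = 16)
  res <- train_model(m, ds, ds, plan)
  expect_identical(param_snapshot(res$model), before)
})

test_that("training history is bit-reproducible under a fixed seed", {
  ds <- small_sets()
  run <- function() {
    m <- with_seed(5, build_model(tiny_cfg()))
    train_model(m, ds, ds, train_plan("scratch", epochs = 3, seed = 11,
                                      batch_size = 8))$history
  }
  h1 <- run(); h2 <- run()
  expect_identical(h1, h2)
})

test_that("a tiny model overfits 16 separable trials within 150 epochs", {
  ds <- small_sets(seed = 7, n_per_class = 8)
  m <- with_seed(3, build_model(tiny_cfg()))
  res <- train_model(m, ds, ds,
                     train_plan("scratch", epochs = 150, seed = 3,
                                batch_size = 16))
  h <- res$history
  expect_equal(max(h$train_accuracy), 1.0)
  # loss strictly decreases from the first epoch to the best epoch
  expect_lt(h$train_loss[h$best_epoch], h$train_loss[1])
})

test_that("the default freeze policy protects the lower transformer while convs adapt", {
  ds <- small_sets()
  m <- with_seed(3, build_model(tiny_cfg(n_transformer_layers = 2)))
  before <- param_snapshot(m)
  plan <- train_plan("finetune_full", epochs = 2, seed = 1, batch_size = 16,
                     freeze_policy = freeze_policy(
                       transformer_frozen_layers = 0L))
  res <- train_model(m, ds, ds, plan)
  after <- param_snapshot(res$model)
  frozen_units <- grep("^transformer_1_", names(after), value = TRUE)
  for (nm in frozen_units) expect_identical(after[[nm]], before[[nm]])
  thawed <- grep("^transformer_2_", names(after), value = TRUE)
  expect_true(any(vapply(thawed, function(nm)
    !identical(after[[nm]], before[[nm]]), logical(1))))
  for (nm in c("deep_conv1", "deep_conv2", "shallow_spatial",
               "shallow_temporal", "fusion")) {
    expect_gt(sum(abs(after[[nm]]$W - before[[nm]]$W)), 0)
  }
  expect_error(
    train_model(m, ds, ds,
                train_plan("finetune_full", epochs = 1, seed = 1,
                           freeze_policy = freeze_policy(
                             transformer_frozen_layers = 5L))),
    "exceeds")
})

test_that("fine-tuning plans carry the documented epochs and rates", {
  expect_equal(train_plan("scratch")$epochs, 150L)
  expect_equal(train_plan("scratch")$learning_rate, 1e-3)
  expect_equal(train_plan("finetune_full")$epochs, 150L)
  expect_equal(train_plan("finetune_full")$learning_rate, 5e-4)
  expect_equal(train_plan("finetune_reduced")$epochs, 75L)
  expect_equal(train_plan("finetune_reduced")$learning_rate, 5e-5)
  expect_equal(train_plan("scratch")$batch_size, 64L)
})

test_that("reduced fine-tuning moves the weights less than full fine-tuning", {
  src <- small_sets(seed = 19)
  tgt <- small_sets(seed = 23)
  cfg <- tiny_cfg()
  param_dist <- function(a, b) {
    sqrt(sum(vapply(names(a), function(nm) {
      sum(vapply(names(a[[nm]]), function(p)
        sum((a[[nm]][[p]] - b[[nm]][[p]])^2), numeric(1)))
    }, numeric(1))))
  }
  fp <- freeze_policy(transformer_frozen_layers = 0L)
  run_ft <- function(regime) {
    pretrain_then_finetune(
      cfg, list(train = src, val = src), list(train = tgt, val = tgt),
      train_plan("scratch", epochs = 3, seed = 2, batch_size = 16),
      train_plan(regime, epochs = 4, seed = 2, batch_size = 16,
                 freeze_policy = fp))
  }
  full <- run_ft("finetune_full")
  red <- run_ft("finetune_reduced")
  # both start from the identical pretrained state (same seeds)
  pre <- with_seed(2, build_model(cfg))
  pre_res <- train_model(pre, src, src,
                         train_plan("scratch", epochs = 3, seed = 2,
                                    batch_size = 16))
  p0 <- param_snapshot(pre_res$model)
  expect_lt(param_dist(param_snapshot(red$model), p0),
            param_dist(param_snapshot(full$model), p0))
  expect_length(full$ft_history$train_loss, 4)
  expect_equal(full$provenance$ft_plan$learning_rate, 5e-4)
  expect_equal(red$provenance$ft_plan$learning_rate, 5e-5)
  expect_equal(red$provenance$ft_plan$epochs, 4L)
})

test_that("cross-geometry transfer rebuilds the spatial stage and keeps the rest", {
  src <- small_sets(seed = 29)                       # 3 channels
  tgt_raw <- generate_dataset(synth_spec(
    n_subjects = 1, n_trials_per_class = 6, n_classes = 2, n_channels = 5,
    erd_depth = 0.8, snr = 3, artifact_fraction = 0,
    epoch_window = c(-0.2, 0.824), seed = 31))
  tgt <- self_standardize(tgt_raw)
  cfg <- tiny_cfg(n_channels = 5)
  res <- pretrain_then_finetune(
    cfg, list(train = src, val = src), list(train = tgt, val = tgt),
    train_plan("scratch", epochs = 1, seed = 4, batch_size = 16),
    train_plan("finetune_reduced", epochs = 1, seed = 4, batch_size = 16,
               freeze_policy = freeze_policy(
                 transformer_frozen_layers = 0L)))
  expect_equal(res$model$config$n_channels, 5L)
  expect_length(res$ft_history$train_loss, 1)
})
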