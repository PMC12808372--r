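test_that("forward contract maps both benchmark geometries to logits", {
  cfg <- make_preset("tl", n_channels = 22, n_samples = 1125, n_classes = 4)
  m <- with_seed(1, build_model(cfg))
  x <- with_seed(2, array(rnorm(22 * 1125 * 2), dim = c(22, 1125, 2)))
  lg <- midecode:::model_forward(m, x, train = FALSE)
  expect_equal(dim(lg), c(4L, 2L))
  expect_true(all(is.finite(lg)))
  # bipolar 3-channel binary geometry at a reduced width
  cfg2 <- tiny_cfg(n_channels = 3, n_samples = 256, n_classes = 2)
  m2 <- with_seed(1, build_model(cfg2))
  x2 <- with_seed(3, array(rnorm(3 * 256 * 4), dim = c(3, 256, 4)))
  lg2 <- midecode:::model_forward(m2, x2, train = FALSE)
  expect_equal(dim(lg2), c(2L, 4L))
})

test_that("initialization is deterministic under a seed", {
  cfg <- tiny_cfg()
  m1 <- with_seed(42, build_model(cfg))
  m2 <- with_seed(42, build_model(cfg))
  expect_identical(param_snapshot(m1), param_snapshot(m2))
  m3 <- with_seed(43, build_model(cfg))
  expect_false(identical(param_snapshot(m1), param_snapshot(m3)))
})

test_that("eval-mode forward is deterministic and per-trial independent", {
  cfg <- tiny_cfg()
  m <- with_seed(7, build_model(cfg))
  x <- with_seed(8, array(rnorm(3 * 256 * 5), dim = c(3, 256, 5)))
  lg_a <- midecode:::model_forward(m, x, train = FALSE)
  lg_b <- midecode:::model_forward(m, x, train = FALSE)
  expect_identical(lg_a, lg_b)
  perm <- c(3, 1, 5, 2, 4)
  lg_p <- midecode:::model_forward(m, x[, , perm], train = FALSE)
  expect_equal(lg_p, lg_a[, perm], tolerance = 1e-10)
})

test_that("gradient reaches every trainable tensor", {
  cfg <- tiny_cfg(extra_lstm_branch = TRUE, conv_dropout = 0,
                  transformer_dropout = 0, bilstm_dropout = 0,
                  mlp_dropout = 0)
  m <- with_seed(5, build_model(cfg))
  x <- with_seed(6, array(rnorm(3 * 256 * 4), dim = c(3, 256, 4)))
  midecode:::model_zero_grads(m)
  lg <- midecode:::model_forward(m, x, train = TRUE)
  sx <- midecode:::softmax_xent(lg, c(0L, 1L, 0L, 1L))
  midecode:::model_backward(m, sx$dlogits)
  for (u in midecode:::model_units(m)) {
    gnorm <- sum(vapply(u$grads, function(g) sum(abs(g)), numeric(1)))
    expect_gt(gnorm, 0)
  }
})

test_that("backpropagation matches central finite differences in every layer type", {
  cfg <- tiny_cfg(n_samples = 64, deep_block_filters = c(4, 6),
                  shallow_spatial_filters = 5, shallow_temporal_kernel_t = 7,
                  fusion_dim = 8, bilstm_hidden = 4, mlp_hidden = 6,
                  extra_lstm_branch = TRUE, conv_dropout = 0,
                  transformer_dropout = 0, bilstm_dropout = 0,
                  mlp_dropout = 0)
  m <- with_seed(42, build_model(cfg))
  x <- with_seed(43, array(rnorm(3 * 64 * 3), dim = c(3, 64, 3)))
  y <- c(0L, 1L, 0L)
  loss_at <- function() {
    lg <- midecode:::model_forward(m, x, train = TRUE)
    midecode:::softmax_xent(lg, y)
  }
  midecode:::model_zero_grads(m)
  sx <- loss_at()
  midecode:::model_backward(m, sx$dlogits)
  eps <- 1e-5
  set.seed(44)
  for (u in midecode:::model_units(m)) {
    for (p in names(u$params)) {
      i <- sample(length(u$params[[p]]), 1)
      orig <- u$params[[p]][i]
      u$params[[p]][i] <- orig + eps; lp <- loss_at()$loss
      u$params[[p]][i] <- orig - eps; lm <- loss_at()$loss
      u$params[[p]][i] <- orig
      num <- (lp - lm) / (2 * eps)
      ana <- u$grads[[p]][i]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4,
                label = sprintf("gradient mismatch in %s/%s", u$name, p))
    }
  }
})

test_that("parameter counting matches independent shape arithmetic", {
  # a lone dense map R^128 -> R^4 with bias
  lin <- with_seed(1, midecode:::layer_dense("lin", 128, 4))
  expect_equal(sum(vapply(lin$params, length, numeric(1))), 516)
  for (extra in c(FALSE, TRUE)) {
    cfg <- tiny_cfg(extra_lstm_branch = extra)
    m <- with_seed(2, build_model(cfg))
    s <- count_parameters(m)
    expect_equal(s$n_parameters, expected_param_count(cfg))
    expect_equal(sum(s$layer_table$n_params), s$n_parameters)
    expect_equal(s$n_parameters_millions, round(s$n_parameters / 1e6, 2))
  }
})

test_that("parameter count is monotone in depth and width and activation-free", {
  base <- tiny_cfg()
  n0 <- expected_param_count(base)
  count_of <- function(...) {
    cfg <- tiny_cfg(...)
    m <- with_seed(3, build_model(cfg))
    count_parameters(m)$n_parameters
  }
  expect_equal(count_of(), n0)
  expect_gt(count_of(n_transformer_layers = 2), n0)
  expect_gt(count_of(bilstm_layers = 2), n0)
  expect_gt(count_of(width_multiplier = 2), n0)
  expect_gt(count_of(extra_lstm_branch = TRUE), n0)
  expect_equal(count_of(activation = "Tanh"), n0)
  expect_equal(count_of(activation = "ReLU"), n0)
})

test_that("presets encode the documented depth differences", {
  s <- make_preset("scratch_simplified")
  expect_equal(s$n_transformer_layers, 6L)
  expect_equal(s$bilstm_layers, 2L)
  expect_false(s$positional_encoding)
  tl <- make_preset("tl")
  expect_equal(tl$n_transformer_layers, 8L)
  expect_equal(tl$bilstm_layers, 3L)
  expect_true(tl$positional_encoding)
  # baseline and tl share the architecture (training regime differs)
  bl <- make_preset("baseline")
  expect_identical(bl[setdiff(names(bl), "variant_name")],
                   tl[setdiff(names(tl), "variant_name")])
  expect_true(make_preset("tl_lstm")$extra_lstm_branch)
  expect_error(make_preset("nope"), "available")
})

test_that("branch pooling mismatch is reported at construction", {
  cfg <- tiny_cfg()
  cfg$pool_product <- 3L   # incompatible with the deep branch's 2x2 pools
  expect_error(build_model(cfg), "branch temporal lengths")
})

test_that("checkpoints round-trip and reject mismatched configs", {
  cfg <- tiny_cfg()
  m <- with_seed(9, build_model(cfg))
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, path, provenance = list(seed = 9))
  back <- load_checkpoint(path, expected_config = cfg)
  expect_identical(param_snapshot(back), param_snapshot(m))
  expect_equal(attr(back, "provenance")$seed, 9)
  x <- with_seed(10, array(rnorm(3 * 256 * 2), dim = c(3, 256, 2)))
  expect_identical(midecode:::model_forward(back, x, FALSE),
                   midecode:::model_forward(m, x, FALSE))
  other <- tiny_cfg(n_classes = 4)
  expect_error(load_checkpoint(path, expected_config = other), "mismatch|match")
})
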