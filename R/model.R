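#' Hybrid network configuration
#'
#' Declarative record of one architecture in the family: two parallel
#' convolutional branches (a deep temporal branch and a shallow
#' spatial-then-temporal branch), feature fusion to `fusion_dim`, optional
#' sinusoidal positional encoding, a transformer encoder, a bidirectional
#' LSTM stack, temporal mean pooling, and an MLP classification head.
#'
#' `width_multiplier` scales `fusion_dim`, the transformer feed-forward
#' width and the BiLSTM hidden size (rounded to multiples of `n_heads`),
#' emulating enlarged variants; it does not change depth.
#'
#' @param variant_name label for reports.
#' @param n_channels,n_samples,n_classes input geometry and label count.
#' @param activation `"ELU"`, `"ReLU"` or `"Tanh"` (used everywhere except
#'   the transformer feed-forward blocks, which use GELU).
#' @param deep_block_filters integer pair: filters of the two deep blocks.
#' @param deep_kernels_t integer pair: temporal kernel lengths of the deep
#'   blocks.
#' @param shallow_spatial_filters filters of the shallow branch.
#' @param shallow_temporal_kernel_t temporal kernel of the shallow branch.
#' @param conv_dropout dropout in both convolutional branches.
#' @param pool_product shared temporal downsampling factor (deep: two
#'   max-pools of stride 2; shallow: one average-pool of stride
#'   `pool_product`).
#' @param fusion_dim model dimension after the 1x1 fusion convolution.
#' @param positional_encoding add fixed sinusoidal positional encoding?
#' @param n_transformer_layers,n_heads transformer encoder depth and heads.
#' @param transformer_ff_mult feed-forward width as a multiple of the model
#'   dimension.
#' @param transformer_dropout dropout on the attention and feed-forward
#'   residual paths.
#' @param bilstm_layers,bilstm_hidden,bilstm_dropout BiLSTM stack depth,
#'   hidden units per direction, and inter-layer dropout.
#' @param mlp_hidden,mlp_dropout classification head width and dropout.
#' @param extra_lstm_branch add a parallel unidirectional LSTM on the fused
#'   sequence, concatenated with the BiLSTM output before pooling?
#' @param width_multiplier positive real width scale.
#'
#' @return A `model_config` object.
#' @export
model_config <- function(variant_name = "custom",
                         n_channels = 3, n_samples = 1125, n_classes = 2,
                         activation = c("ELU", "ReLU", "Tanh"),
                         deep_block_filters = c(32, 64),
                         deep_kernels_t = c(7, 5),
                         shallow_spatial_filters = 80,
                         shallow_temporal_kernel_t = 25,
                         conv_dropout = 0.4,
                         pool_product = 4,
                         fusion_dim = 128,
                         positional_encoding = TRUE,
                         n_transformer_layers = 8,
                         n_heads = 4,
                         transformer_ff_mult = 2,
                         transformer_dropout = 0.1,
                         bilstm_layers = 3,
                         bilstm_hidden = 128,
                         bilstm_dropout = 0.3,
                         mlp_hidden = 128,
                         mlp_dropout = 0.5,
                         extra_lstm_branch = FALSE,
                         width_multiplier = 1.0) {
  activation <- match.arg(activation)
  check_scalar(n_channels, "n_channels", lower = 1, integer = TRUE)
  check_scalar(n_samples, "n_samples", lower = 1, integer = TRUE)
  check_scalar(n_classes, "n_classes", lower = 2, integer = TRUE)
  check_scalar(width_multiplier, "width_multiplier", lower = 0,
               strict_lower = TRUE)
  for (f in c("conv_dropout", "transformer_dropout", "bilstm_dropout",
              "mlp_dropout")) {
    check_scalar(get(f), f, lower = 0, upper = 1 - 1e-12)
  }
  check_scalar(pool_product, "pool_product", lower = 1, integer = TRUE)
  if (n_samples < pool_product * 8) {
    stop("field 'n_samples' must be at least 8 x pool_product")
  }
  scale_dim <- function(x) {
    max(n_heads, as.integer(round(x * width_multiplier / n_heads)) * n_heads)
  }
  fusion_dim_s <- scale_dim(fusion_dim)
  if (fusion_dim_s %% n_heads != 0) {
    stop("fusion_dim must be divisible by n_heads")
  }
  cfg <- list(variant_name = variant_name, n_channels = as.integer(n_channels),
              n_samples = as.integer(n_samples),
              n_classes = as.integer(n_classes), activation = activation,
              deep_block_filters = as.integer(deep_block_filters),
              deep_kernels_t = as.integer(deep_kernels_t),
              shallow_spatial_filters = as.integer(shallow_spatial_filters),
              shallow_temporal_kernel_t = as.integer(shallow_temporal_kernel_t),
              conv_dropout = conv_dropout, pool_product = as.integer(pool_product),
              fusion_dim = fusion_dim_s,
              positional_encoding = isTRUE(positional_encoding),
              n_transformer_layers = as.integer(n_transformer_layers),
              n_heads = as.integer(n_heads),
              transformer_ff_mult = transformer_ff_mult,
              transformer_dropout = transformer_dropout,
              bilstm_layers = as.integer(bilstm_layers),
              bilstm_hidden = scale_dim(bilstm_hidden),
              bilstm_dropout = bilstm_dropout,
              mlp_hidden = as.integer(mlp_hidden), mlp_dropout = mlp_dropout,
              extra_lstm_branch = isTRUE(extra_lstm_branch),
              width_multiplier = width_multiplier)
  structure(cfg, class = "model_config")
}

#' Named architecture presets
#'
#' * `"baseline"`, `"tl"`: the full architecture (8 transformer layers,
#'   3 BiLSTM layers, positional encoding, ELU). The two presets share the
#'   architecture and differ only in the training regime they are paired
#'   with (from-scratch versus pretrain + fine-tune).
#' * `"tl_relu"`, `"tl_tanh"`: activation swaps with enlarged widths
#'   (estimated multipliers; the enlargement is this package's own
#'   calibration, not a reported design).
#' * `"tl_lstm"`: adds the parallel unidirectional LSTM branch.
#' * `"scratch_simplified"`: 6 transformer layers, 2 BiLSTM layers,
#'   positional encoding disabled — the conservative from-scratch variant.
#'
#' @param name preset name.
#' @param n_channels,n_samples,n_classes input geometry (defaults: the
#'   22-channel, 4-class, 1125-sample setting).
#' @param ... further overrides passed to [model_config()].
#' @return A `model_config`.
#' @export
make_preset <- function(name, n_channels = 22, n_samples = 1125,
                        n_classes = 4, ...) {
  presets <- c("baseline", "tl", "tl_relu", "tl_tanh", "tl_lstm",
               "scratch_simplified")
  if (!name %in% presets) {
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(presets, collapse = ", ")))
  }
  args <- switch(name,
    baseline = list(),
    tl = list(),
    tl_relu = list(activation = "ReLU", width_multiplier = 2.05),
    tl_tanh = list(activation = "Tanh", width_multiplier = 1.78),
    tl_lstm = list(extra_lstm_branch = TRUE),
    scratch_simplified = list(n_transformer_layers = 6, bilstm_layers = 2,
                              positional_encoding = FALSE))
  args$variant_name <- name
  args$n_channels <- n_channels
  args$n_samples <- n_samples
  args$n_classes <- n_classes
  user <- list(...)
  args[names(user)] <- user
  do.call(model_config, args)
}

# fixed sinusoidal positional encoding, (d_model, T)
positional_encoding_matrix <- function(d_model, TT) {
  pe <- matrix(0, d_model, TT)
  pos <- seq_len(TT) - 1
  for (i in seq_len(ceiling(d_model / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / d_model)
    pe[2 * i - 1, ] <- sin(pos * freq)
    if (2 * i <= d_model) pe[2 * i, ] <- cos(pos * freq)
  }
  pe
}

#' Build a network from a configuration
#'
#' Instantiates every layer with fan-based uniform initialization drawn
#' from the current RNG state (seed with `set.seed()` or [with_seed()] for
#' reproducible builds). The forward contract maps a batch of trials
#' `[channels x samples x batch]` to logits `[n_classes x batch]`.
#'
#' @param cfg a [model_config()].
#' @return An object of class `mi_model`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  t_deep <- (cfg$n_samples %/% 2) %/% 2
  t_shallow <- cfg$n_samples %/% cfg$pool_product
  if (t_deep != t_shallow) {
    stop(sprintf(
      "branch temporal lengths differ (deep 2x2 pooling -> %d, shallow pool %d -> %d)",
      t_deep, cfg$pool_product, t_shallow))
  }
  act <- cfg$activation
  f1 <- cfg$deep_block_filters[1]; f2 <- cfg$deep_block_filters[2]
  d <- cfg$fusion_dim
  ff <- max(cfg$n_heads,
            as.integer(round(cfg$transformer_ff_mult * d)))
  L <- list()
  # deep branch: two temporal conv blocks (first spans all channels)
  L$deep_conv1 <- layer_conv1d("deep_conv1", cfg$n_channels, f1,
                               cfg$deep_kernels_t[1])
  L$deep_bn1 <- layer_batchnorm("deep_bn1", f1)
  L$deep_act1 <- layer_activation("deep_act1", act)
  L$deep_pool1 <- layer_pool("deep_pool1", 2, "max")
  L$deep_drop1 <- layer_dropout("deep_drop1", cfg$conv_dropout)
  L$deep_conv2 <- layer_conv1d("deep_conv2", f1, f2, cfg$deep_kernels_t[2])
  L$deep_bn2 <- layer_batchnorm("deep_bn2", f2)
  L$deep_act2 <- layer_activation("deep_act2", act)
  L$deep_pool2 <- layer_pool("deep_pool2", 2, "max")
  L$deep_drop2 <- layer_dropout("deep_drop2", cfg$conv_dropout)
  # shallow branch: spatial conv, temporal conv, average pool
  fs <- cfg$shallow_spatial_filters
  L$shallow_spatial <- layer_conv1d("shallow_spatial", cfg$n_channels, fs, 1)
  L$shallow_temporal <- layer_conv1d("shallow_temporal", fs, fs,
                                     cfg$shallow_temporal_kernel_t)
  L$shallow_bn <- layer_batchnorm("shallow_bn", fs)
  L$shallow_act <- layer_activation("shallow_act", act)
  L$shallow_pool <- layer_pool("shallow_pool", cfg$pool_product, "avg")
  L$shallow_drop <- layer_dropout("shallow_drop", cfg$conv_dropout)
  # fusion
  L$fusion <- layer_conv1d("fusion", f2 + fs, d, 1)
  # transformer encoder stack
  trans <- vector("list", cfg$n_transformer_layers)
  for (i in seq_len(cfg$n_transformer_layers)) {
    nm <- sprintf("transformer_%d", i)
    trans[[i]] <- list(
      attn = layer_mha(paste0(nm, "_attn"), d, cfg$n_heads),
      drop1 = layer_dropout(paste0(nm, "_drop1"), cfg$transformer_dropout),
      ln1 = layer_layernorm(paste0(nm, "_ln1"), d),
      ff1 = layer_dense(paste0(nm, "_ff1"), d, ff),
      ffact = layer_activation(paste0(nm, "_gelu"), "GELU"),
      ff2 = layer_dense(paste0(nm, "_ff2"), ff, d),
      drop2 = layer_dropout(paste0(nm, "_drop2"), cfg$transformer_dropout),
      ln2 = layer_layernorm(paste0(nm, "_ln2"), d))
  }
  # BiLSTM stack
  h <- cfg$bilstm_hidden
  bil <- vector("list", cfg$bilstm_layers)
  for (i in seq_len(cfg$bilstm_layers)) {
    n_in <- if (i == 1) d else 2 * h
    bil[[i]] <- list(
      fwd = layer_lstm_dir(sprintf("bilstm_%d_fwd", i), n_in, h, FALSE),
      bwd = layer_lstm_dir(sprintf("bilstm_%d_bwd", i), n_in, h, TRUE),
      drop = layer_dropout(sprintf("bilstm_%d_drop", i), cfg$bilstm_dropout))
  }
  extra <- if (cfg$extra_lstm_branch) {
    layer_lstm_dir("extra_lstm", d, h, FALSE)
  } else NULL
  feat <- 2 * h + if (cfg$extra_lstm_branch) h else 0
  L$mlp1 <- layer_dense("mlp1", feat, cfg$mlp_hidden)
  L$mlp_act <- layer_activation("mlp_act", act)
  L$mlp_drop <- layer_dropout("mlp_drop", cfg$mlp_dropout)
  L$mlp2 <- layer_dense("mlp2", cfg$mlp_hidden, cfg$n_classes)

  pe <- if (cfg$positional_encoding) {
    positional_encoding_matrix(d, t_shallow)
  } else NULL

  model <- structure(
    list(config = cfg, layers = L, transformer = trans, bilstm = bil,
         extra_lstm = extra, pe = pe, t_prime = t_shallow,
         state = new.env(parent = emptyenv())),
    class = "mi_model")
  model
}

# ordered flat list of parameter-owning layer environments
model_units <- function(model) {
  units <- Filter(function(l) length(l$params) > 0, model$layers)
  for (tl in model$transformer) {
    units <- c(units, Filter(function(l) length(l$params) > 0, tl))
  }
  for (bl in model$bilstm) {
    units <- c(units, list(bl$fwd, bl$bwd))
  }
  if (!is.null(model$extra_lstm)) units <- c(units, list(model$extra_lstm))
  names(units) <- vapply(units, function(u) u$name, character(1))
  units
}

# every layer with a forward pass (for cache clearing etc.)
model_all_layers <- function(model) {
  ls <- unname(model$layers)
  for (tl in model$transformer) ls <- c(ls, unname(tl))
  for (bl in model$bilstm) ls <- c(ls, unname(bl))
  if (!is.null(model$extra_lstm)) ls <- c(ls, list(model$extra_lstm))
  ls
}

model_zero_grads <- function(model) {
  for (u in model_units(model)) zero_grads(u)
  invisible(model)
}

#' Forward pass
#'
#' @param model an `mi_model`.
#' @param x numeric array `[n_channels, n_samples, batch]`.
#' @param train training mode (batch-norm batch statistics, dropout on)?
#' @return Logits matrix `[n_classes, batch]`.
#' @export
model_forward <- function(model, x, train = FALSE) {
  L <- model$layers
  dpath <- L$deep_drop1$fw(L$deep_pool1$fw(L$deep_act1$fw(
    L$deep_bn1$fw(L$deep_conv1$fw(x, train), train), train), train), train)
  dpath <- L$deep_drop2$fw(L$deep_pool2$fw(L$deep_act2$fw(
    L$deep_bn2$fw(L$deep_conv2$fw(dpath, train), train), train), train), train)
  spath <- L$shallow_drop$fw(L$shallow_pool$fw(L$shallow_act$fw(
    L$shallow_bn$fw(L$shallow_temporal$fw(
      L$shallow_spatial$fw(x, train), train), train), train), train), train)
  dd <- dim(dpath); ds <- dim(spath)
  z <- array(0, dim = c(dd[1] + ds[1], dd[2], dd[3]))
  z[seq_len(dd[1]), , ] <- dpath
  z[dd[1] + seq_len(ds[1]), , ] <- spath
  model$state$split_at <- dd[1]
  f <- L$fusion$fw(z, train)
  if (!is.null(model$pe)) {
    f <- f + array(model$pe, dim = dim(f))
  }
  fused <- f
  for (tl in model$transformer) {
    a <- tl$drop1$fw(tl$attn$fw(f, train), train)
    f <- tl$ln1$fw(f + a, train)
    m <- tl$drop2$fw(tl$ff2$fw(tl$ffact$fw(tl$ff1$fw(f, train), train),
                               train), train)
    f <- tl$ln2$fw(f + m, train)
  }
  r <- f
  for (i in seq_along(model$bilstm)) {
    bl <- model$bilstm[[i]]
    hf <- bl$fwd$fw(r, train)
    hb <- bl$bwd$fw(r, train)
    dh <- dim(hf)
    r <- array(0, dim = c(2 * dh[1], dh[2], dh[3]))
    r[seq_len(dh[1]), , ] <- hf
    r[dh[1] + seq_len(dh[1]), , ] <- hb
    if (i < length(model$bilstm)) r <- bl$drop$fw(r, train)
  }
  if (!is.null(model$extra_lstm)) {
    he <- model$extra_lstm$fw(fused, train)
    dr <- dim(r); dhe <- dim(he)
    r2 <- array(0, dim = c(dr[1] + dhe[1], dr[2], dr[3]))
    r2[seq_len(dr[1]), , ] <- r
    r2[dr[1] + seq_len(dhe[1]), , ] <- he
    r <- r2
  }
  dr <- dim(r)
  pooled <- matrix(0, dr[1], dr[3])
  for (b in seq_len(dr[3])) {
    pooled[, b] <- rowMeans(matrix(r[, , b], dr[1], dr[2]))
  }
  model$state$pool_T <- dr[2]
  logits <- L$mlp2$fw(L$mlp_drop$fw(L$mlp_act$fw(
    L$mlp1$fw(pooled, train), train), train), train)
  logits
}

# Backward pass for dLoss/dLogits (n_classes x batch). Call immediately
# after model_forward(..., train = TRUE); relies on the layer caches.
model_backward <- function(model, dlogits) {
  L <- model$layers
  g <- L$mlp1$bw(L$mlp_act$bw(L$mlp_drop$bw(L$mlp2$bw(dlogits))))
  dr1 <- nrow(g)
  # un-pool: distribute the temporal mean
  t_p <- model$state$pool_T
  B <- ncol(g)
  # reconstruct feature count before pooling
  feat <- dr1
  dR <- array(0, dim = c(feat, t_p, B))
  for (b in seq_len(B)) dR[, , b] <- g[, b] / t_p
  dfused_extra <- NULL
  if (!is.null(model$extra_lstm)) {
    h <- model$extra_lstm$hidden
    dhe <- dR[feat - h + seq_len(h), , , drop = FALSE]
    dR <- dR[seq_len(feat - h), , , drop = FALSE]
    dfused_extra <- model$extra_lstm$bw(dhe)
  }
  for (i in rev(seq_along(model$bilstm))) {
    bl <- model$bilstm[[i]]
    if (i < length(model$bilstm)) dR <- bl$drop$bw(dR)
    h <- bl$fwd$hidden
    dhf <- dR[seq_len(h), , , drop = FALSE]
    dhb <- dR[h + seq_len(h), , , drop = FALSE]
    dR <- bl$fwd$bw(dhf) + bl$bwd$bw(dhb)
  }
  df <- dR
  for (tl in rev(model$transformer)) {
    d2 <- tl$ln2$bw(df)
    dm <- tl$ff1$bw(tl$ffact$bw(tl$ff2$bw(tl$drop2$bw(d2))))
    df <- d2 + dm
    d1 <- tl$ln1$bw(df)
    da <- tl$attn$bw(tl$drop1$bw(d1))
    df <- d1 + da
  }
  if (!is.null(dfused_extra)) df <- df + dfused_extra
  dz <- L$fusion$bw(df)
  k <- model$state$split_at
  ddeep <- dz[seq_len(k), , , drop = FALSE]
  dshallow <- dz[k + seq_len(dim(dz)[1] - k), , , drop = FALSE]
  dxd <- L$deep_conv1$bw(L$deep_bn1$bw(L$deep_act1$bw(L$deep_pool1$bw(
    L$deep_drop1$bw(
      L$deep_conv2$bw(L$deep_bn2$bw(L$deep_act2$bw(L$deep_pool2$bw(
        L$deep_drop2$bw(ddeep))))))))))
  dxs <- L$shallow_spatial$bw(L$shallow_temporal$bw(L$shallow_bn$bw(
    L$shallow_act$bw(L$shallow_pool$bw(L$shallow_drop$bw(dshallow))))))
  dxd + dxs
}

softmax_xent <- function(logits, labels) {
  # logits: (K, B); labels: 0-based integer vector length B
  K <- nrow(logits); B <- ncol(logits)
  z <- sweep(logits, 2, apply(logits, 2, max))
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), `/`)
  idx <- cbind(labels + 1L, seq_len(B))
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / B
  list(loss = loss, dlogits = dlogits, probs = p)
}

#' Count trainable parameters
#'
#' Sums the sizes of all non-frozen parameter tensors and tabulates them
#' per layer; millions are reported to 2 decimals.
#'
#' @param model an `mi_model`.
#' @return A `model_summary`: `n_parameters`, `n_parameters_millions`,
#'   and `layer_table` (layer name, parameter shape note, count).
#' @export
count_parameters <- function(model) {
  units <- model_units(model)
  if (is.null(units[[1]]$out_shape)) {
    probe <- array(0, dim = c(model$config$n_channels,
                              model$config$n_samples, 1))
    invisible(model_forward(model, probe, train = FALSE))
  }
  rows <- lapply(units, function(u) {
    if (u$frozen) return(NULL)
    n <- sum(vapply(u$params, length, numeric(1)))
    out <- if (is.null(u$out_shape)) "" else {
      paste(u$out_shape, collapse = "x")
    }
    data.frame(name = u$name, output_shape = out, n_params = n,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(tab)) tab <- data.frame(name = character(0),
                                      output_shape = character(0),
                                      n_params = numeric(0))
  total <- sum(tab$n_params)
  structure(list(n_parameters = total,
                 n_parameters_millions = round(total / 1e6, 2),
                 layer_table = tab),
            class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf("<model_summary> %d trainable parameters (%.2f M) in %d units\n",
              x$n_parameters, x$n_parameters_millions, nrow(x$layer_table)))
  invisible(x)
}

#' @export
print.mi_model <- function(x, ...) {
  s <- count_parameters(x)
  cat(sprintf("<mi_model> variant '%s': %d ch x %d samples -> %d classes\n",
              x$config$variant_name, x$config$n_channels,
              x$config$n_samples, x$config$n_classes))
  cat(sprintf("  transformer %d x (d=%d, heads=%d), BiLSTM %d x %d/dir%s\n",
              x$config$n_transformer_layers, x$config$fusion_dim,
              x$config$n_heads, x$config$bilstm_layers,
              x$config$bilstm_hidden,
              if (x$config$extra_lstm_branch) " + extra LSTM branch" else ""))
  cat(sprintf("  %d trainable parameters (%.2f M)\n",
              s$n_parameters, s$n_parameters_millions))
  invisible(x)
}

#' Predict classes for a trial set
#'
#' Runs the network in evaluation mode (dropout off, batch-norm running
#' statistics) over mini-batches.
#'
#' @param object an `mi_model`.
#' @param ds an `eeg_trialset` or array `[trials, channels, samples]`.
#' @param type `"class"` for 0-based labels, `"logits"` for the raw matrix
#'   `[n_classes, trials]`.
#' @param batch_size mini-batch size.
#' @param ... unused.
#' @return Integer labels or a logits matrix.
#' @export
predict.mi_model <- function(object, ds, type = c("class", "logits"),
                             batch_size = 64, ...) {
  type <- match.arg(type)
  x <- if (inherits(ds, "eeg_trialset")) ds$data else ds
  n <- dim(x)[1]
  out <- matrix(0, object$config$n_classes, n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch_size - 1L)
    xb <- aperm(x[i:j, , , drop = FALSE], c(2, 3, 1))
    out[, i:j] <- model_forward(object, xb, train = FALSE)
    i <- j + 1L
  }
  if (type == "logits") out else as.integer(apply(out, 2, which.max) - 1L)
}

## ---- parameter plumbing (copy, checksum, checkpoint) --------------------

model_get_params <- function(model) {
  units <- model_units(model)
  lapply(units, function(u) u$params)
}

model_set_params <- function(model, snapshot) {
  units <- model_units(model)
  stopifnot(identical(names(units), names(snapshot)))
  for (nm in names(units)) units[[nm]]$params <- snapshot[[nm]]
  invisible(model)
}

model_get_buffers <- function(model) {
  units <- model_units(model)
  lapply(units, function(u) {
    if (!is.null(u$running_mean)) {
      list(running_mean = u$running_mean, running_var = u$running_var)
    } else NULL
  })
}

model_set_buffers <- function(model, snapshot) {
  units <- model_units(model)
  for (nm in names(snapshot)) {
    if (!is.null(snapshot[[nm]])) {
      units[[nm]]$running_mean <- snapshot[[nm]]$running_mean
      units[[nm]]$running_var <- snapshot[[nm]]$running_var
    }
  }
  invisible(model)
}

param_checksum <- function(model) {
  object_hash(model_get_params(model))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding every parameter array, the
#' batch-norm running statistics, the emitting `model_config` (also as
#' JSON), and optional provenance. Loading against an explicit config
#' fails loudly on any mismatch.
#'
#' @param model an `mi_model`.
#' @param path checkpoint file path.
#' @param provenance optional list stored verbatim (training plans, seeds).
#' @return `save_checkpoint` returns `path`; `load_checkpoint` returns the
#'   rebuilt `mi_model` with attribute `provenance`.
#' @export
save_checkpoint <- function(model, path, provenance = NULL) {
  saveRDS(list(params = model_get_params(model),
               buffers = model_get_buffers(model),
               config = model$config,
               config_json = jsonlite::toJSON(unclass(model$config),
                                              auto_unbox = TRUE),
               provenance = provenance),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expected_config optional `model_config` the checkpoint must match.
#' @export
load_checkpoint <- function(path, expected_config = NULL) {
  ck <- readRDS(path)
  if (!is.null(expected_config)) {
    if (!identical(unclass(ck$config), unclass(expected_config))) {
      stop("checkpoint config does not match the expected model_config")
    }
  }
  model <- build_model(ck$config)
  model_set_params(model, ck$params)
  model_set_buffers(model, ck$buffers)
  attr(model, "provenance") <- ck$provenance
  model
}
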