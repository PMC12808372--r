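#' Training plan
#'
#' The three regimes: from-scratch training (150 epochs at learning rate
#' 1e-3), aggressive full fine-tuning (150 epochs at 5e-4) and
#' conservative reduced fine-tuning (75 epochs at 5e-5). Optimizer is Adam
#' with cross-entropy loss, batch size 64.
#'
#' @param regime `"scratch"`, `"finetune_full"` or `"finetune_reduced"`.
#' @param epochs,learning_rate,batch_size overrides of the regime defaults.
#' @param freeze_policy a [freeze_policy()] (applied for fine-tuning
#'   regimes; the scratch regime trains everything).
#' @param seed integer seed controlling shuffling, dropout and (for
#'   scratch) initialization.
#' @param early_stop_patience optional: stop after this many epochs without
#'   validation improvement.
#' @return A `train_plan` object.
#' @export
train_plan <- function(regime = c("scratch", "finetune_full",
                                  "finetune_reduced"),
                       epochs = NULL, learning_rate = NULL, batch_size = 64,
                       freeze_policy = NULL, seed = 1,
                       early_stop_patience = NULL) {
  regime <- match.arg(regime)
  defaults <- switch(regime,
    scratch = list(epochs = 150, lr = 1e-3),
    finetune_full = list(epochs = 150, lr = 5e-4),
    finetune_reduced = list(epochs = 75, lr = 5e-5))
  if (is.null(epochs)) epochs <- defaults$epochs
  if (is.null(learning_rate)) learning_rate <- defaults$lr
  check_scalar(epochs, "epochs", lower = 0, integer = TRUE)
  check_scalar(learning_rate, "learning_rate", lower = 0,
               strict_lower = TRUE)
  check_scalar(batch_size, "batch_size", lower = 1, integer = TRUE)
  if (is.null(freeze_policy) && regime != "scratch") {
    freeze_policy <- freeze_policy()
  }
  structure(list(regime = regime, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 optimizer = "adam", loss = "cross_entropy",
                 freeze_policy = freeze_policy, seed = as.integer(seed),
                 early_stop_patience = early_stop_patience),
            class = "train_plan")
}

#' Selective layer freezing policy
#'
#' During fine-tuning the convolutional and recurrent layers stay fully
#' trainable while part of the transformer encoder is frozen to protect
#' the pretrained general representations (default: the lower half,
#' layers 0-3 of 8, 0-based).
#'
#' @param conv_frozen freeze both convolutional branches and the fusion?
#' @param bilstm_frozen freeze the BiLSTM stack (and extra LSTM branch)?
#' @param transformer_frozen_layers 0-based indices of frozen transformer
#'   encoder layers.
#' @param mlp_frozen freeze the classification head?
#' @return A `freeze_policy` object.
#' @export
freeze_policy <- function(conv_frozen = FALSE, bilstm_frozen = FALSE,
                          transformer_frozen_layers = 0:3,
                          mlp_frozen = FALSE) {
  structure(list(conv_frozen = isTRUE(conv_frozen),
                 bilstm_frozen = isTRUE(bilstm_frozen),
                 transformer_frozen_layers =
                   as.integer(transformer_frozen_layers),
                 mlp_frozen = isTRUE(mlp_frozen)),
            class = "freeze_policy")
}

# flag layer environments as frozen according to the policy
apply_freeze_policy <- function(model, policy) {
  if (is.null(policy)) return(invisible(model))
  if (length(policy$transformer_frozen_layers) > 0 &&
      any(policy$transformer_frozen_layers >=
            model$config$n_transformer_layers)) {
    stop("frozen transformer layer index exceeds the encoder depth")
  }
  conv_names <- c("deep_conv1", "deep_bn1", "deep_conv2", "deep_bn2",
                  "shallow_spatial", "shallow_temporal", "shallow_bn",
                  "fusion")
  for (nm in conv_names) model$layers[[nm]]$frozen <- policy$conv_frozen
  for (nm in c("mlp1", "mlp2")) {
    model$layers[[nm]]$frozen <- policy$mlp_frozen
  }
  for (i in seq_along(model$transformer)) {
    fr <- (i - 1L) %in% policy$transformer_frozen_layers
    for (u in model$transformer[[i]]) {
      if (length(u$params) > 0) u$frozen <- fr
    }
  }
  for (bl in model$bilstm) {
    bl$fwd$frozen <- policy$bilstm_frozen
    bl$bwd$frozen <- policy$bilstm_frozen
  }
  if (!is.null(model$extra_lstm)) {
    model$extra_lstm$frozen <- policy$bilstm_frozen
  }
  invisible(model)
}

unfreeze_all <- function(model) {
  for (u in model_units(model)) u$frozen <- FALSE
  invisible(model)
}

## ---- Adam ----------------------------------------------------------------

adam_state <- function(model) {
  units <- model_units(model)
  st <- lapply(units, function(u) {
    lapply(u$params, function(p) {
      list(m = array(0, dim = dim_or_len(p)),
           v = array(0, dim = dim_or_len(p)))
    })
  })
  list(units = st, t = 0L)
}

adam_step <- function(model, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  units <- model_units(model)
  for (nm in names(units)) {
    u <- units[[nm]]
    if (u$frozen) next
    for (p in names(u$params)) {
      g <- u$grads[[p]]
      s <- state$units[[nm]][[p]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      state$units[[nm]][[p]] <- s
      upd <- u$params[[p]] - lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
      dim(upd) <- dim_or_null(u$params[[p]])  # keep vectors vectors
      u$params[[p]] <- upd
    }
  }
  state
}

## ---- training loop --------------------------------------------------------

eval_on_set <- function(model, ds, batch_size = 64) {
  x <- ds$data
  n <- dim(x)[1]
  loss_sum <- 0; correct <- 0
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch_size - 1L)
    xb <- aperm(x[i:j, , , drop = FALSE], c(2, 3, 1))
    logits <- model_forward(model, xb, train = FALSE)
    sx <- softmax_xent(logits, ds$labels[i:j])
    loss_sum <- loss_sum + sx$loss * (j - i + 1L)
    pred <- apply(logits, 2, which.max) - 1L
    correct <- correct + sum(pred == ds$labels[i:j])
    i <- j + 1L
  }
  list(loss = loss_sum / n, accuracy = correct / n)
}

#' Train a model
#'
#' Mini-batch Adam with cross-entropy loss. The freeze policy of the plan
#' is applied before the first step; frozen tensors are bit-identical
#' before and after. Per-epoch train/validation loss and accuracy are
#' recorded, and the parameters achieving the best validation accuracy
#' (ties: earliest epoch) are restored at the end. Fully deterministic
#' under `plan$seed`.
#'
#' @param model an `mi_model` (modified in place and returned).
#' @param train_set,val_set standardized `eeg_trialset`s.
#' @param plan a [train_plan()].
#' @return A list: `model`, `history` (class `train_history`: per-epoch
#'   `train_loss`, `train_accuracy`, `val_loss`, `val_accuracy`,
#'   `best_epoch`).
#' @export
train_model <- function(model, train_set, val_set, plan) {
  stopifnot(inherits(model, "mi_model"), inherits(plan, "train_plan"))
  if (n_trials(train_set) == 0) stop("empty training set")
  if (any(train_set$labels >= model$config$n_classes) ||
      any(val_set$labels >= model$config$n_classes)) {
    stop("label out of range for the model's class count")
  }
  if (plan$regime != "scratch") {
    apply_freeze_policy(model, plan$freeze_policy)
  } else if (!is.null(plan$freeze_policy)) {
    apply_freeze_policy(model, plan$freeze_policy)
  }
  hist <- list(train_loss = numeric(0), train_accuracy = numeric(0),
               val_loss = numeric(0), val_accuracy = numeric(0))
  best <- list(acc = -Inf, epoch = NA_integer_, params = NULL,
               buffers = NULL)
  if (plan$epochs == 0) {
    hist$best_epoch <- NA_integer_
    return(list(model = model,
                history = structure(hist, class = "train_history")))
  }
  with_seed(plan$seed, {
    opt <- adam_state(model)
    n <- n_trials(train_set)
    since_best <- 0L
    for (ep in seq_len(plan$epochs)) {
      ord <- sample.int(n)
      loss_sum <- 0; correct <- 0
      i <- 1L
      while (i <= n) {
        j <- min(n, i + plan$batch_size - 1L)
        idx <- ord[i:j]
        xb <- aperm(train_set$data[idx, , , drop = FALSE], c(2, 3, 1))
        yb <- train_set$labels[idx]
        model_zero_grads(model)
        logits <- model_forward(model, xb, train = TRUE)
        sx <- softmax_xent(logits, yb)
        model_backward(model, sx$dlogits)
        opt <- adam_step(model, opt, plan$learning_rate)
        loss_sum <- loss_sum + sx$loss * length(idx)
        correct <- correct + sum((apply(logits, 2, which.max) - 1L) == yb)
        i <- j + 1L
      }
      ve <- eval_on_set(model, val_set, plan$batch_size)
      hist$train_loss <- c(hist$train_loss, loss_sum / n)
      hist$train_accuracy <- c(hist$train_accuracy, correct / n)
      hist$val_loss <- c(hist$val_loss, ve$loss)
      hist$val_accuracy <- c(hist$val_accuracy, ve$accuracy)
      if (ve$accuracy > best$acc) {
        best <- list(acc = ve$accuracy, epoch = ep,
                     params = model_get_params(model),
                     buffers = model_get_buffers(model))
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (!is.null(plan$early_stop_patience) &&
          since_best >= plan$early_stop_patience) break
    }
  })
  if (!is.null(best$params)) {
    model_set_params(model, best$params)
    model_set_buffers(model, best$buffers)
  }
  hist$best_epoch <- best$epoch
  list(model = model, history = structure(hist, class = "train_history"))
}

#' @export
print.train_history <- function(x, ...) {
  n <- length(x$train_loss)
  cat(sprintf("<train_history> %d epoch(s), best epoch %s\n", n,
              ifelse(is.na(x$best_epoch), "-", x$best_epoch)))
  if (n > 0) {
    cat(sprintf("  final: train loss %.4f acc %.3f | val loss %.4f acc %.3f\n",
                x$train_loss[n], x$train_accuracy[n],
                x$val_loss[n], x$val_accuracy[n]))
  }
  invisible(x)
}

#' Pretrain on source subjects, then fine-tune on a target
#'
#' Stage 1 trains a freshly initialized model on the pooled source
#' training data (scratch regime). Stage 2 applies the fine-tuning plan
#' (full or reduced) with its freeze policy on the target training data.
#' If the source and target channel counts differ, the spatial stage
#' (first layer of each convolutional branch) is rebuilt for the target
#' geometry and re-initialized while all temporal, transformer, recurrent
#' and head weights are transferred.
#'
#' @param cfg a [model_config()] describing the *target* geometry.
#' @param source_sets list with `train` and `val` `eeg_trialset`s (source
#'   subjects).
#' @param target_sets list with `train` and `val` `eeg_trialset`s (target).
#' @param pre_plan scratch-regime [train_plan()] for pretraining.
#' @param ft_plan fine-tuning [train_plan()] (`finetune_full` or
#'   `finetune_reduced`).
#' @return A list: `model` (fine-tuned), `pre_history`, `ft_history`,
#'   `provenance` (both plans and seeds).
#' @export
pretrain_then_finetune <- function(cfg, source_sets, target_sets,
                                   pre_plan, ft_plan) {
  stopifnot(inherits(cfg, "model_config"))
  if (!ft_plan$regime %in% c("finetune_full", "finetune_reduced")) {
    stop("ft_plan must be a fine-tuning regime")
  }
  src_ch <- dim(source_sets$train$data)[2]
  src_sam <- dim(source_sets$train$data)[3]
  if (src_sam != cfg$n_samples) {
    stop("source and target sample counts differ; no temporal adapter is provided")
  }
  src_classes <- max(source_sets$train$labels) + 1L
  src_cfg <- cfg
  src_cfg$n_channels <- as.integer(src_ch)
  src_cfg$n_classes <- as.integer(src_classes)
  src_model <- with_seed(pre_plan$seed, build_model(src_cfg))
  pre <- train_model(src_model, source_sets$train, source_sets$val, pre_plan)
  tgt_classes <- cfg$n_classes
  if (src_ch == cfg$n_channels && src_classes == tgt_classes) {
    model <- pre$model
    unfreeze_all(model)
  } else {
    model <- adapt_model_geometry(pre$model, cfg, ft_plan$seed)
  }
  ft <- train_model(model, target_sets$train, target_sets$val, ft_plan)
  list(model = ft$model, pre_history = pre$history,
       ft_history = ft$history,
       provenance = list(pre_plan = unclass(pre_plan),
                         ft_plan = unclass(ft_plan)))
}

# Cross-geometry weight transfer: rebuild for the target config, copy every
# unit whose shapes match, re-initialize the rest (spatial convs when the
# channel count changes, the head when the class count changes).
adapt_model_geometry <- function(src_model, tgt_cfg, seed) {
  tgt <- with_seed(seed, build_model(tgt_cfg))
  src_units <- model_units(src_model)
  tgt_units <- model_units(tgt)
  reinit <- character(0)
  for (nm in names(tgt_units)) {
    if (!nm %in% names(src_units)) { reinit <- c(reinit, nm); next }
    sp <- src_units[[nm]]$params
    tp <- tgt_units[[nm]]$params
    if (identical(lapply(sp, dim_or_len), lapply(tp, dim_or_len))) {
      tgt_units[[nm]]$params <- sp
      if (!is.null(src_units[[nm]]$running_mean)) {
        tgt_units[[nm]]$running_mean <- src_units[[nm]]$running_mean
        tgt_units[[nm]]$running_var <- src_units[[nm]]$running_var
      }
    } else {
      reinit <- c(reinit, nm)
    }
  }
  attr(tgt, "reinitialized_units") <- reinit
  tgt
}
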