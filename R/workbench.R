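#' Experiment specification
#'
#' Declares one of the five standard comparisons, at a configurable
#' (usually desk-scale synthetic) problem size:
#'
#' * **A** — from-scratch (simplified variant) vs transfer learning
#'   (pretrain on source subjects, full fine-tune), LOSO on the target
#'   subjects.
#' * **B** — aggressive (150 epochs, lr 5e-4) vs conservative (75 epochs,
#'   lr 5e-5) fine-tuning from the same pretrained weights.
#' * **C** — activation comparison: ELU vs ReLU vs Tanh, trained from
#'   scratch under identical seeds.
#' * **D** — cross-geometry validation: pretrain on the source dataset,
#'   adapt the spatial stage, fine-tune on a target with different
#'   channel/class geometry.
#' * **E** — flattened-trial random-forest baseline with subject-specific
#'   classifiers.
#'
#' @param experiment `"A"`..`"E"`.
#' @param dataset a [synth_spec()] (the dataset is generated) or a path to
#'   a trial-set bundle written by [write_trialset()].
#' @param source_dataset optional second `synth_spec`/path: pretraining
#'   source for experiments A, B and D (defaults to `dataset` subjects for
#'   A/B).
#' @param model_overrides named list merged into every [model_config()]
#'   (for scaled-down runs: smaller `fusion_dim`, fewer layers, ...).
#' @param train_overrides named list merged into every [train_plan()]
#'   (e.g. `epochs`).
#' @param seeds integer vector of replicate seeds (first is used for
#'   splits/LOSO).
#' @param output_dir directory for report files.
#' @return An `experiment_spec`.
#' @export
experiment_spec <- function(experiment = c("A", "B", "C", "D", "E"),
                            dataset = synth_spec(),
                            source_dataset = NULL,
                            model_overrides = list(),
                            train_overrides = list(),
                            seeds = 1L, output_dir = tempfile("exp")) {
  experiment <- match.arg(experiment)
  structure(list(experiment = experiment, dataset = dataset,
                 source_dataset = source_dataset,
                 model_overrides = model_overrides,
                 train_overrides = train_overrides,
                 seeds = as.integer(seeds), output_dir = output_dir),
            class = "experiment_spec")
}

resolve_dataset <- function(x) {
  if (inherits(x, "synth_spec")) return(generate_dataset(x))
  if (is.character(x)) return(read_trialset(x))
  if (inherits(x, "eeg_trialset")) return(x)
  stop("dataset must be a synth_spec, an eeg_trialset or a bundle path")
}

# model config for a dataset geometry + overrides
cfg_for <- function(ds, overrides, preset = "tl") {
  args <- list(name = preset, n_channels = dim(ds$data)[2],
               n_samples = dim(ds$data)[3], n_classes = ds$n_classes)
  do.call(make_preset, c(args, overrides))
}

plan_with <- function(regime, overrides, seed) {
  if (regime == "scratch") overrides$freeze_policy <- NULL
  args <- c(list(regime = regime, seed = seed), overrides)
  do.call(train_plan, args)
}

# deep-model LOSO factory: train from scratch
scratch_factory <- function(cfg, plan_overrides) {
  function(train_set, val_set, seed) {
    plan <- plan_with("scratch", plan_overrides, seed)
    model <- with_seed(seed, build_model(cfg))
    train_model(model, train_set, val_set, plan)$model
  }
}

# deep-model LOSO factory: pretrain on a fixed source, then fine-tune
tl_factory <- function(cfg, source_sets, pre_overrides, ft_overrides,
                       ft_regime = "finetune_full") {
  function(train_set, val_set, seed) {
    pre_plan <- plan_with("scratch", pre_overrides, seed)
    ft_plan <- plan_with(ft_regime, ft_overrides, seed)
    pretrain_then_finetune(cfg, source_sets,
                           list(train = train_set, val = val_set),
                           pre_plan, ft_plan)$model
  }
}

# stratified train/val split of a pooled set (for pretraining sources)
pooled_train_val <- function(ds, val_fraction = 0.2, seed = 1) {
  idx <- with_seed(seed, {
    unlist(lapply(0:(ds$n_classes - 1L), function(k) {
      pool <- which(ds$labels == k)
      sample(pool, max(1L, round(val_fraction * length(pool))))
    }))
  })
  list(train = ds[setdiff(seq_len(n_trials(ds)), idx)], val = ds[idx])
}

#' Run a standard experiment
#'
#' Executes every arm of the comparison under identical seeds and splits,
#' audits each LOSO report for self-consistency, and writes JSON + CSV
#' reports plus a provenance manifest to `spec$output_dir`.
#'
#' @param spec an [experiment_spec()].
#' @return Invisibly, a list with the per-arm `loso_report`s (or
#'   accuracy tables for E), `deltas` between designated arms, `eta` per
#'   arm, and the manifest. Files: `report.json`, one
#'   `per_subject_<arm>.csv` per arm, `confusions_<arm>.csv`,
#'   `manifest.json`.
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  dir.create(spec$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- spec$seeds[1]
  ds <- resolve_dataset(spec$dataset)
  ex <- spec$experiment
  arms <- list(); plans <- list()
  if (ex %in% c("A", "B", "D")) {
    src <- if (!is.null(spec$source_dataset)) {
      resolve_dataset(spec$source_dataset)
    } else ds
    src_sets <- pooled_train_val(src, seed = seed)
  }
  if (ex == "A") {
    cfg_s <- cfg_for(ds, spec$model_overrides, "scratch_simplified")
    cfg_t <- cfg_for(ds, spec$model_overrides, "tl")
    plans$scratch <- plan_with("scratch", spec$train_overrides, seed)
    plans$tl <- plan_with("finetune_full", spec$train_overrides, seed)
    arms$scratch <- loso_evaluate(
      scratch_factory(cfg_s, spec$train_overrides), ds, seed = seed)
    arms$tl <- loso_evaluate(
      tl_factory(cfg_t, src_sets, spec$train_overrides,
                 spec$train_overrides, "finetune_full"), ds, seed = seed)
  } else if (ex == "B") {
    cfg <- cfg_for(ds, spec$model_overrides, "tl")
    plans$finetune_full <- plan_with("finetune_full", spec$train_overrides,
                                     seed)
    plans$finetune_reduced <- plan_with("finetune_reduced",
                                        spec$train_overrides, seed)
    for (arm in c("finetune_full", "finetune_reduced")) {
      arms[[arm]] <- loso_evaluate(
        tl_factory(cfg, src_sets, spec$train_overrides,
                   spec$train_overrides, arm), ds, seed = seed)
    }
  } else if (ex == "C") {
    for (act in c("ELU", "ReLU", "Tanh")) {
      cfg <- cfg_for(ds, c(list(activation = act), spec$model_overrides),
                     "tl")
      plans[[act]] <- plan_with("scratch", spec$train_overrides, seed)
      arms[[act]] <- loso_evaluate(
        scratch_factory(cfg, spec$train_overrides), ds, seed = seed)
    }
  } else if (ex == "D") {
    if (is.null(spec$source_dataset)) {
      stop("experiment D needs a source_dataset with different geometry")
    }
    cfg <- cfg_for(ds, spec$model_overrides, "tl")
    cfg_s <- cfg_for(ds, spec$model_overrides, "scratch_simplified")
    plans$scratch <- plan_with("scratch", spec$train_overrides, seed)
    plans$tl <- plan_with("finetune_reduced", spec$train_overrides, seed)
    arms$scratch <- loso_evaluate(
      scratch_factory(cfg_s, spec$train_overrides), ds, seed = seed)
    arms$tl <- loso_evaluate(
      tl_factory(cfg, src_sets, spec$train_overrides, spec$train_overrides,
                 "finetune_reduced"), ds, seed = seed)
  } else if (ex == "E") {
    cfg_rf <- rf_config(seed = seed)
    plan <- split_scheme("IV-2a", seed = seed)
    sp <- stratified_split(ds, plan)
    tr_idx <- unlist(lapply(sp$subjects, function(p) c(p$train_idx, p$val_idx)))
    te_idx <- unlist(lapply(sp$subjects, function(p) p$test_idx))
    acc <- random_forest_baseline(ds[tr_idx], ds[te_idx], cfg_rf)
    arms$random_forest <- list(
      per_subject = acc, mean_accuracy = mean(acc$accuracy),
      sd_accuracy = stats::sd(acc$accuracy))
    plans$random_forest <- unclass(cfg_rf)
  }
  # deltas + efficiency per arm
  deltas <- NULL
  if (ex %in% c("A", "D")) {
    deltas <- improvement_deltas(arms$scratch, arms$tl)
  } else if (ex == "B") {
    deltas <- improvement_deltas(arms$finetune_full, arms$finetune_reduced)
  }
  eta <- list()
  for (arm in names(arms)) {
    if (inherits(arms[[arm]], "loso_report")) {
      audit_loso_report(arms[[arm]])
      cfg_arm <- if (ex == "A" && arm == "scratch") {
        cfg_for(ds, spec$model_overrides, "scratch_simplified")
      } else if (ex %in% c("A", "B", "D")) {
        cfg_for(ds, spec$model_overrides, "tl")
      } else {
        cfg_for(ds, c(list(activation = arm), spec$model_overrides), "tl")
      }
      pm <- with_seed(seed, count_parameters(build_model(cfg_arm)))
      eta[[arm]] <- efficiency_index(arms[[arm]]$mean_accuracy / 100,
                                     pm$n_parameters_millions)
    }
  }
  strip_classes <- function(x) {
    if (is.list(x)) structure(lapply(x, strip_classes), names = names(x))
    else x
  }
  manifest <- list(
    experiment = ex,
    seeds = spec$seeds,
    dataset_hash = object_hash(ds$data),
    model_overrides = strip_classes(spec$model_overrides),
    train_overrides = strip_classes(spec$train_overrides),
    plans = lapply(plans, function(p) {
      p <- unclass(p)
      if (!is.null(p$freeze_policy)) p$freeze_policy <- unclass(p$freeze_policy)
      p
    }),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("midecode")),
    config_hash = object_hash(list(spec$model_overrides,
                                   spec$train_overrides, spec$seeds)))
  result <- list(arms = arms, deltas = deltas, eta = eta,
                 manifest = manifest)
  write_experiment_report(result, spec$output_dir)
  invisible(result)
}

write_experiment_report <- function(result, dir) {
  summarize_arm <- function(a) {
    if (inherits(a, "loso_report")) {
      list(mean_accuracy = a$mean_accuracy, sd_accuracy = a$sd_accuracy,
           mean_f1 = a$mean_f1, mean_kappa = a$mean_kappa,
           per_subject = a$per_subject)
    } else {
      list(mean_accuracy = a$mean_accuracy, sd_accuracy = a$sd_accuracy,
           per_subject = a$per_subject)
    }
  }
  jsonlite::write_json(
    list(arms = lapply(result$arms, summarize_arm),
         deltas = result$deltas, eta = result$eta,
         manifest = result$manifest),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  for (arm in names(result$arms)) {
    a <- result$arms[[arm]]
    utils::write.csv(a$per_subject,
                     file.path(dir, sprintf("per_subject_%s.csv", arm)),
                     row.names = FALSE)
    if (inherits(a, "loso_report")) {
      cm_rows <- do.call(rbind, lapply(names(a$confusions), function(s) {
        cm <- a$confusions[[s]]
        data.frame(subject = s,
                   true = rep(seq_len(nrow(cm)) - 1L, ncol(cm)),
                   pred = rep(seq_len(ncol(cm)) - 1L, each = nrow(cm)),
                   count = as.vector(cm))
      }))
      utils::write.csv(cm_rows,
                       file.path(dir, sprintf("confusions_%s.csv", arm)),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load an experiment spec from YAML
#'
#' Fields: `experiment`, `seeds`, `output_dir`, optional `dataset` /
#' `source_dataset` (either a path string or a mapping of [synth_spec()]
#' fields), `model_overrides`, `train_overrides`. Unknown fields raise an
#' error.
#'
#' @param path YAML file path.
#' @return An `experiment_spec`.
#' @export
read_experiment_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("experiment", "seeds", "output_dir", "dataset",
               "source_dataset", "model_overrides", "train_overrides")
  bad <- setdiff(names(y), allowed)
  if (length(bad) > 0) {
    stop(sprintf("unknown experiment fields: %s", paste(bad, collapse = ", ")))
  }
  to_ds <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) return(x)
    do.call(synth_spec, x)
  }
  experiment_spec(
    experiment = y$experiment %||% "A",
    dataset = to_ds(y$dataset) %||% synth_spec(),
    source_dataset = to_ds(y$source_dataset),
    model_overrides = y$model_overrides %||% list(),
    train_overrides = y$train_overrides %||% list(),
    seeds = y$seeds %||% 1L,
    output_dir = y$output_dir %||% tempfile("exp"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
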