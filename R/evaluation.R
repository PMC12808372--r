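#' Confusion matrix
#'
#' @param true,pred integer vectors of true and predicted labels (0-based).
#' @param n_classes number of classes K.
#' @return A K x K integer matrix of counts, rows = true, columns =
#'   predicted, class `confusion_matrix`.
#' @export
confusion_matrix <- function(true, pred, n_classes = max(c(true, pred)) + 1L) {
  stopifnot(length(true) == length(pred))
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true)) {
    cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
  }
  structure(cm, class = c("confusion_matrix", "matrix"))
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || sum(cm) == 0) {
    stop("confusion matrix must be a square count matrix with > 0 trials")
  }
  invisible(cm)
}

#' Classification metrics from a confusion matrix
#'
#' `accuracy_pct` returns trace/total in percent. `macro_f1` returns the
#' unweighted mean of per-class F1 scores (a class with zero
#' precision + recall contributes 0). `cohen_kappa` returns
#' (p_o - p_e) / (1 - p_e) with expected agreement from the row/column
#' marginals.
#'
#' @param cm a square count matrix (rows = true, columns = predicted).
#' @return A numeric scalar.
#' @export
accuracy_pct <- function(cm) {
  check_cm(cm)
  100 * sum(diag(cm)) / sum(cm)
}

#' @rdname accuracy_pct
#' @export
macro_f1 <- function(cm) {
  check_cm(cm)
  K <- nrow(cm)
  f1 <- vapply(seq_len(K), function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[, k]) - tp
    fn <- sum(cm[k, ]) - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' @rdname accuracy_pct
#' @export
cohen_kappa <- function(cm) {
  check_cm(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(1)           # degenerate single-cell agreement
  (po - pe) / (1 - pe)
}

#' Efficiency index: accuracy per million parameters
#'
#' eta = A / P with A the mean accuracy as a fraction and P the trainable
#' parameter count in millions; reported to 3 decimals.
#'
#' @param A mean accuracy as a fraction in \[0,1\].
#' @param P trainable parameters in millions (> 0).
#' @return eta, rounded to 3 decimals.
#' @export
efficiency_index <- function(A, P) {
  check_scalar(A, "A", lower = 0, upper = 1)
  check_scalar(P, "P", lower = 0, strict_lower = TRUE)
  round(A / P, 3)
}

#' Variance-reduction ratio across subjects
#'
#' Percent decrease of the across-subject accuracy standard deviation of a
#' transfer-learning model relative to a baseline:
#' (sd_baseline - sd_tl) / sd_baseline * 100, reported to 1 decimal.
#'
#' @param sd_baseline baseline across-subject standard deviation
#'   (percentage points, > 0).
#' @param sd_tl transfer-learning across-subject standard deviation.
#' @return Percent reduction, rounded to 1 decimal.
#' @export
variance_reduction <- function(sd_baseline, sd_tl) {
  check_scalar(sd_baseline, "sd_baseline", lower = 0, strict_lower = TRUE)
  check_scalar(sd_tl, "sd_tl", lower = 0)
  round((sd_baseline - sd_tl) / sd_baseline * 100, 1)
}

#' Paired two-tailed t-test on subject-level accuracies
#'
#' Two-tailed p from the t distribution with n - 1 degrees of freedom on
#' the paired differences. Degenerate inputs are handled explicitly:
#' identical vectors give t = 0, p = 1; zero-variance differences with a
#' nonzero mean give p = 0 with a warning.
#'
#' @param acc_a,acc_b equal-length numeric vectors (length >= 2).
#' @return A list with `t`, `df`, `p`.
#' @export
paired_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b) || length(acc_a) < 2) {
    stop("need two equal-length vectors with at least 2 entries")
  }
  d <- acc_a - acc_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = length(d) - 1L, p = 1))
    warning("zero-variance nonzero differences: p reported as 0")
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Improvement of a transfer-learning report over a baseline
#'
#' @param base,tl `loso_report` objects (or lists with `mean_accuracy` and
#'   `sd_accuracy` in percent) on the same data.
#' @return A list: `absolute_points` (mean_tl - mean_base),
#'   `relative_percent` (absolute / mean_base x 100) and
#'   `variance_reduction_pct` (via [variance_reduction()]).
#' @export
improvement_deltas <- function(base, tl) {
  abs_pts <- tl$mean_accuracy - base$mean_accuracy
  rel <- abs_pts / base$mean_accuracy * 100
  dsig <- if (!is.null(base$sd_accuracy) && base$sd_accuracy > 0) {
    variance_reduction(base$sd_accuracy, tl$sd_accuracy)
  } else NA_real_
  list(absolute_points = abs_pts, relative_percent = rel,
       variance_reduction_pct = dsig)
}

#' Leave-one-subject-out evaluation
#'
#' One fold per subject: the held-out subject's trials are used only for
#' testing; a stratified validation fraction is carved from the remaining
#' subjects' trials (never the held-out subject). The factory contract
#' makes deep and shallow models interchangeable: `model_factory` is a
#' function `(train_set, val_set, fold_seed)` returning an object for
#' which `predict(object, test_set)` yields 0-based labels.
#'
#' A leakage assertion verifies per fold that no held-out trial index
#' enters training or validation.
#'
#' @param model_factory factory function (see above).
#' @param ds an `eeg_trialset` with >= 2 subjects, each having every class.
#' @param val_fraction stratified validation fraction carved from the
#'   training subjects.
#' @param seed integer seed; fold f uses `seed + f` for its factory.
#' @return A `loso_report`: `per_subject` (data.frame with subject,
#'   accuracy %, macro-F1, kappa), `confusions` (per-subject confusion
#'   matrices), `mean_accuracy`, `sd_accuracy`, `mean_f1`, `mean_kappa`.
#' @export
loso_evaluate <- function(model_factory, ds, val_fraction = 0.2, seed = 1) {
  stopifnot(inherits(ds, "eeg_trialset"))
  subjects <- sort(unique(ds$subjects))
  if (length(subjects) < 2) stop("LOSO needs at least 2 subjects")
  for (s in subjects) {
    present <- sort(unique(ds$labels[ds$subjects == s]))
    if (!identical(present, 0:(ds$n_classes - 1L))) {
      stop(sprintf("subject %s lacks at least one class", s))
    }
  }
  rows <- list(); cms <- list()
  for (f in seq_along(subjects)) {
    s <- subjects[f]
    test_idx <- which(ds$subjects == s)
    rest_idx <- which(ds$subjects != s)
    stopifnot(length(intersect(test_idx, rest_idx)) == 0)  # leakage guard
    val_idx <- with_seed(seed + f, {
      unlist(lapply(0:(ds$n_classes - 1L), function(k) {
        pool <- rest_idx[ds$labels[rest_idx] == k]
        sample(pool, max(1L, round(val_fraction * length(pool))))
      }))
    })
    train_idx <- setdiff(rest_idx, val_idx)
    stopifnot(!any(test_idx %in% c(train_idx, val_idx)))
    fitted <- model_factory(ds[train_idx], ds[val_idx], seed + f)
    pred <- predict(fitted, ds[test_idx])
    cm <- confusion_matrix(ds$labels[test_idx], pred, ds$n_classes)
    cms[[as.character(s)]] <- cm
    rows[[f]] <- data.frame(subject = s,
                            accuracy = accuracy_pct(cm),
                            macro_f1 = macro_f1(cm),
                            kappa = cohen_kappa(cm))
  }
  per_subject <- do.call(rbind, rows)
  structure(
    list(per_subject = per_subject, confusions = cms,
         mean_accuracy = mean(per_subject$accuracy),
         sd_accuracy = stats::sd(per_subject$accuracy),
         mean_f1 = mean(per_subject$macro_f1),
         mean_kappa = mean(per_subject$kappa)),
    class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  cat(sprintf(
    "<loso_report> %d subject folds: accuracy %.2f%% +/- %.2f, macro-F1 %.3f, kappa %.3f\n",
    nrow(x$per_subject), x$mean_accuracy,
    ifelse(is.na(x$sd_accuracy), 0, x$sd_accuracy),
    x$mean_f1, x$mean_kappa))
  invisible(x)
}

#' @export
summary.loso_report <- function(object, ...) {
  print(object)
  print(object$per_subject, row.names = FALSE)
  invisible(object)
}

# Recompute every aggregate from the stored confusion matrices and check
# agreement with the stored per-subject and mean values (self-consistency
# audit used by the workbench before a report is written).
audit_loso_report <- function(report, tol = 1e-9) {
  for (i in seq_len(nrow(report$per_subject))) {
    s <- as.character(report$per_subject$subject[i])
    cm <- report$confusions[[s]]
    stopifnot(abs(report$per_subject$accuracy[i] - accuracy_pct(cm)) < tol,
              abs(report$per_subject$macro_f1[i] - macro_f1(cm)) < tol,
              abs(report$per_subject$kappa[i] - cohen_kappa(cm)) < tol)
  }
  stopifnot(
    abs(report$mean_accuracy - mean(report$per_subject$accuracy)) < tol,
    abs(report$sd_accuracy - stats::sd(report$per_subject$accuracy)) < tol ||
      (is.na(report$sd_accuracy) && nrow(report$per_subject) < 2),
    abs(report$mean_f1 - mean(report$per_subject$macro_f1)) < tol,
    abs(report$mean_kappa - mean(report$per_subject$kappa)) < tol)
  invisible(TRUE)
}
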