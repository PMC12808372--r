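test_that("metrics reproduce the closed-form worked example", {
  cm <- matrix(c(40, 5, 10, 45), 2, 2)   # rows = true, cols = predicted
  expect_equal(accuracy_pct(cm), 85)
  expect_equal(macro_f1(cm), mean(c(80 / 95, 90 / 105)), tolerance = 1e-12)
  expect_equal(round(macro_f1(cm), 4), 0.8496)
  expect_equal(cohen_kappa(cm), 0.70, tolerance = 1e-12)
})

test_that("metric coherence: perfect, chance and empty-prediction cases", {
  perfect <- diag(c(10L, 12L, 9L))
  expect_equal(accuracy_pct(perfect), 100)
  expect_equal(macro_f1(perfect), 1)
  expect_equal(cohen_kappa(perfect), 1)
  uniform <- matrix(25L, 2, 2)
  expect_equal(cohen_kappa(uniform), 0)
  # a class with neither predictions nor instances contributes F1 = 0
  cm <- matrix(c(5L, 0L, 0L, 0L, 5L, 0L, 0L, 0L, 0L), 3, 3)
  expect_equal(macro_f1(cm), mean(c(1, 1, 0)))
  expect_error(accuracy_pct(matrix(0L, 2, 2)), "trials")
})

test_that("kappa of label-permuted predictions centers on zero", {
  true <- rep(0:1, each = 100)
  pred <- rep(0:1, 100)
  ks <- with_seed(99, vapply(1:200, function(i) {
    cohen_kappa(confusion_matrix(true, sample(pred)))
  }, numeric(1)))
  expect_lt(abs(mean(ks)), 0.05)
})

test_that("efficiency index reproduces printed table values", {
  expect_equal(efficiency_index(0.7222, 1.35), 0.535)
  expect_equal(efficiency_index(0.8385, 1.38), 0.608)
  expect_equal(efficiency_index(0, 5), 0)
  expect_error(efficiency_index(0.5, 0), "P")
  expect_error(efficiency_index(1.5, 1), "A")
})

test_that("variance reduction reproduces printed values and edge cases", {
  expect_equal(variance_reduction(20.49, 11.09), 45.9)
  expect_equal(variance_reduction(17.17, 10.30), 40.0)
  expect_equal(variance_reduction(12.3, 12.3), 0)
  expect_error(variance_reduction(0, 5), "sd_baseline")
})

test_that("paired t-test matches the closed-form oracle and symmetry", {
  # closed form: d = (1..5), t = mean/ (sd/sqrt(n)), p = 2 P(T_4 > |t|)
  a <- c(11, 12, 13, 14, 15); b <- c(10, 10, 10, 10, 10)
  r <- paired_ttest(a, b)
  t_oracle <- mean(a - b) / (stats::sd(a - b) / sqrt(5))
  expect_equal(r$t, t_oracle, tolerance = 1e-12)
  expect_equal(r$t, 4.2426, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * stats::pt(-abs(t_oracle), 4), tolerance = 1e-12)
  expect_equal(round(r$p, 4), 0.0132)
  rs <- paired_ttest(b, a)
  expect_equal(rs$t, -r$t)
  expect_equal(rs$p, r$p)
  ident <- paired_ttest(a, a)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_warning(rz <- paired_ttest(a, a - 2), "zero-variance")
  expect_equal(rz$p, 0)
})

test_that("improvement deltas reproduce the printed ablation summary", {
  base <- list(mean_accuracy = 72.22, sd_accuracy = 20.49)
  tl <- list(mean_accuracy = 79.44, sd_accuracy = 11.09)
  d <- improvement_deltas(base, tl)
  expect_equal(d$absolute_points, 7.22, tolerance = 1e-9)
  expect_equal(round(d$relative_percent, 1), 10.0)
  expect_equal(d$variance_reduction_pct, 45.9)
  d2 <- improvement_deltas(list(mean_accuracy = 75.10, sd_accuracy = 17.17),
                           list(mean_accuracy = 83.85, sd_accuracy = 10.30))
  expect_equal(d2$absolute_points, 8.75, tolerance = 1e-9)
  # 8.75 / 75.10 = 11.65%; agrees with the printed 11.6 to within the
  # print precision
  expect_equal(d2$relative_percent, 100 * 8.75 / 75.10, tolerance = 1e-9)
  expect_lt(abs(d2$relative_percent - 11.6), 0.1)
  expect_equal(d2$variance_reduction_pct, 40.0)
  same <- improvement_deltas(base, base)
  expect_equal(same$absolute_points, 0)
  expect_equal(same$relative_percent, 0)
})

test_that("LOSO runs one fold per subject and never shows it the held-out data", {
  ds <- tiny_separable_ds(n_subjects = 3, n_trials_per_class = 6,
                          epoch_window = c(-0.2, 0.824), seed = 41)
  log_env <- new.env(); log_env$seen <- integer(0)
  seen_by_fold <- list()
  factory <- function(train_set, val_set, seed) {
    seen_by_fold[[length(seen_by_fold) + 1]] <<-
      unique(c(train_set$subjects, val_set$subjects))
    constant_classifier_factory(0L)(train_set, val_set, seed)
  }
  rep <- loso_evaluate(factory, ds, seed = 2)
  expect_equal(nrow(rep$per_subject), 3)
  expect_setequal(rep$per_subject$subject, 1:3)
  for (f in seq_along(seen_by_fold)) {
    expect_false(rep$per_subject$subject[f] %in% seen_by_fold[[f]])
  }
  # constant classifier on balanced 2-class data: 50% everywhere, sd 0
  expect_true(all(rep$per_subject$accuracy == 50))
  expect_equal(rep$mean_accuracy, 50)
  expect_equal(rep$sd_accuracy, 0)
  audit_loso_report(rep)
})

test_that("LOSO rejects degenerate subject structure", {
  ds <- tiny_separable_ds(n_subjects = 1, n_trials_per_class = 4,
                          epoch_window = c(-0.2, 0.824))
  expect_error(loso_evaluate(constant_classifier_factory(), ds), "2 subjects")
  ds2 <- tiny_separable_ds(n_subjects = 2, n_trials_per_class = 4,
                           epoch_window = c(-0.2, 0.824))
  keep <- !(ds2$subjects == 2 & ds2$labels == 1)
  expect_error(loso_evaluate(constant_classifier_factory(), ds2[keep]),
               "lacks")
})

test_that("CSP+LDA separates strongly modulated synthetic subjects under LOSO", {
  ds <- tiny_separable_ds(n_subjects = 3, n_trials_per_class = 20,
                          erd_depth = 0.6, snr = 2, seed = 47)
  ds <- bandpass_filter(ds)
  rep <- loso_evaluate(csp_lda_factory(), ds, seed = 5)
  expect_gt(rep$mean_accuracy, 75)
  audit_loso_report(rep)
})
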