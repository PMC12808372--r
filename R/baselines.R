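#' Fit common spatial patterns (two classes)
#'
#' Per-trial channel covariances are normalized by their trace and
#' averaged within class; the filters jointly diagonalize the two class
#' covariances (whitened convention: for every component the eigenvalue
#' pair under the two classes sums to 1). `n_components/2` filters are
#' taken from each spectral extreme. Rank-deficient composite covariances
#' are ridge-regularized with a logged epsilon.
#'
#' @param trials numeric array `[n_trials, n_channels, n_samples]`,
#'   band-passed.
#' @param labels 0/1 integer labels.
#' @param n_components even number of spatial filters to retain.
#' @return A `csp_model`: `filters` (n_components x n_channels),
#'   `eigenvalues` (class-0 whitened eigenvalues of the retained
#'   components), `class_covariances`.
#' @export
csp_fit <- function(trials, labels, n_components = 4) {
  if (inherits(trials, "eeg_trialset")) {
    labels <- trials$labels
    trials <- trials$data
  }
  classes <- sort(unique(labels))
  if (length(classes) != 2) {
    stop("CSP requires exactly 2 classes (one-vs-rest is out of scope)")
  }
  check_scalar(n_components, "n_components", lower = 2, integer = TRUE)
  if (n_components %% 2 != 0) stop("n_components must be even")
  covs <- lapply(classes, function(k) {
    idx <- which(labels == k)
    acc <- 0
    for (i in idx) {
      x <- matrix(trials[i, , ], dim(trials)[2], dim(trials)[3])
      x <- x - rowMeans(x)
      C <- tcrossprod(x)
      acc <- acc + C / sum(diag(C))
    }
    acc / length(idx)
  })
  C1 <- covs[[1]]; C2 <- covs[[2]]
  Cc <- C1 + C2
  eps_used <- 0
  ev <- eigen(Cc, symmetric = TRUE)
  if (min(ev$values) < 1e-10 * max(ev$values)) {
    eps_used <- 1e-8 * mean(diag(Cc))
    Cc <- Cc + diag(eps_used, nrow(Cc))
    ev <- eigen(Cc, symmetric = TRUE)
    message(sprintf("csp_fit: rank-deficient covariance, ridge %.3g added",
                    eps_used))
  }
  # whiten the composite covariance, then diagonalize class 1
  Wh <- diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  S1 <- Wh %*% C1 %*% t(Wh)
  es <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)
  Wfull <- t(es$vectors) %*% Wh          # rows = filters, sorted by lambda desc
  n_ch <- nrow(Wfull)
  half <- n_components / 2
  pick <- c(seq_len(half), n_ch - half + seq_len(half))
  pick <- unique(pmin(pick, n_ch))
  structure(list(filters = Wfull[pick, , drop = FALSE],
                 eigenvalues = es$values[pick],
                 all_filters = Wfull, all_eigenvalues = es$values,
                 class_covariances = list(C1, C2),
                 n_components = as.integer(n_components),
                 ridge = eps_used),
            class = "csp_model")
}

#' Project trials through CSP filters
#'
#' @param model a `csp_model`.
#' @param trials array `[n_trials, n_channels, n_samples]` or
#'   `eeg_trialset`.
#' @return Matrix `[n_trials, n_components]` of log-variance features.
#' @export
csp_transform <- function(model, trials) {
  if (inherits(trials, "eeg_trialset")) trials <- trials$data
  n <- dim(trials)[1]
  out <- matrix(0, n, nrow(model$filters))
  for (i in seq_len(n)) {
    p <- model$filters %*% matrix(trials[i, , ], dim(trials)[2],
                                  dim(trials)[3])
    v <- apply(p, 1, stats::var)
    out[i, ] <- log(v / sum(v))
  }
  out
}

# LDA with a small ridge fallback on a degenerate pooled covariance
fit_lda_safe <- function(x, y, ridge = 1e-6) {
  fit <- tryCatch(MASS::lda(x, grouping = factor(y)),
                  error = function(e) NULL)
  if (!is.null(fit)) return(list(lda = fit, jitter = FALSE))
  xj <- x + matrix(stats::rnorm(length(x), sd = sqrt(ridge)),
                   nrow(x), ncol(x))
  list(lda = MASS::lda(xj, grouping = factor(y)), jitter = TRUE)
}

#' CSP + LDA model factory for LOSO evaluation
#'
#' Returns a factory `(train_set, val_set, seed) -> fitted object` whose
#' `predict` method emits 0-based labels, pluggable into
#' [loso_evaluate()] exactly like the deep models. Two-class data only.
#'
#' @param n_components CSP components.
#' @return A factory function.
#' @export
csp_lda_factory <- function(n_components = 4) {
  function(train_set, val_set, seed) {
    csp <- csp_fit(train_set$data, train_set$labels, n_components)
    feats <- csp_transform(csp, train_set$data)
    lda <- fit_lda_safe(feats, train_set$labels)
    structure(list(csp = csp, lda = lda$lda), class = "csp_lda_model")
  }
}

#' @export
predict.csp_lda_model <- function(object, ds, ...) {
  feats <- csp_transform(object$csp, ds)
  as.integer(as.character(stats::predict(object$lda, feats)$class))
}

#' Random-forest configuration
#'
#' @param n_estimators number of trees.
#' @param max_depth maximum tree depth (enforced via `maxnodes =
#'   2^max_depth`, capped by the training size).
#' @param seed integer seed.
#' @return An `rf_config`.
#' @export
rf_config <- function(n_estimators = 200, max_depth = 20, seed = 1) {
  check_scalar(n_estimators, "n_estimators", lower = 1, integer = TRUE)
  check_scalar(max_depth, "max_depth", lower = 1, integer = TRUE)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth), seed = as.integer(seed)),
            class = "rf_config")
}

#' Flattened-trial random-forest baseline
#'
#' Every trial is flattened to a `channels x samples` feature vector and
#' one subject-specific classifier is trained per subject present in the
#' training set, then scored on that subject's test trials. Deterministic
#' under the config seed.
#'
#' @param train,test standardized `eeg_trialset`s containing the same
#'   subjects.
#' @param cfg an [rf_config()].
#' @param max_features guard: error if `channels x samples x trials`
#'   exceeds this cap.
#' @return A data.frame with columns `subject` and `accuracy` (percent).
#' @export
random_forest_baseline <- function(train, test, cfg = rf_config(),
                                   max_features = 5e7) {
  stopifnot(inherits(train, "eeg_trialset"), inherits(test, "eeg_trialset"))
  d <- dim(train$data)
  if (d[1] * d[2] * d[3] > max_features) {
    stop("flattened feature matrix exceeds the memory cap; reduce trials or cap")
  }
  flatten <- function(ds) {
    x <- ds$data
    dim(x) <- c(dim(x)[1], dim(x)[2] * dim(x)[3])
    x
  }
  rows <- list()
  for (s in sort(unique(train$subjects))) {
    tr <- which(train$subjects == s)
    te <- which(test$subjects == s)
    if (length(te) == 0) next
    xtr <- flatten(train[tr]); xte <- flatten(test[te])
    fit <- with_seed(cfg$seed + s, {
      randomForest::randomForest(
        x = xtr, y = factor(train$labels[tr]),
        ntree = cfg$n_estimators,
        maxnodes = min(2^cfg$max_depth, max(2L, length(tr))))
    })
    pred <- as.integer(as.character(stats::predict(fit, xte)))
    rows[[as.character(s)]] <- data.frame(
      subject = s, accuracy = 100 * mean(pred == test$labels[te]))
  }
  do.call(rbind, rows)
}

#' Log band-power features
#'
#' Per trial: zero-phase band-pass in each requested band, then the log
#' variance per channel — the classic ERD feature.
#'
#' @param ds an `eeg_trialset` or data array.
#' @param bands list of length-2 numeric band edges (Hz).
#' @param fs sampling rate, taken from `ds` when it is a trial set.
#' @return Matrix `[n_trials, n_channels * n_bands]`.
#' @export
bandpower_features <- function(ds, bands = list(c(8, 12), c(13, 30)),
                               fs = NULL) {
  if (inherits(ds, "eeg_trialset")) {
    fs <- ds$fs
    x <- ds$data
  } else x <- ds
  d <- dim(x)
  out <- matrix(0, d[1], d[2] * length(bands))
  col <- 0L
  for (bd in bands) {
    bf <- signal::butter(4, bd / (fs / 2), type = "pass")
    for (ch in seq_len(d[2])) {
      col <- col + 1L
      for (i in seq_len(d[1])) {
        y <- zero_phase_filter(bf$b, bf$a, x[i, ch, ])
        out[i, col] <- log(stats::var(y))
      }
    }
  }
  out
}

#' Band-power + LDA probe
#'
#' The sanity probe used to validate synthetic data: log band-power
#' features in the mu and beta bands per channel, classified with LDA.
#' Also usable as a LOSO factory via [bandpower_lda_factory()].
#'
#' @param train,test two-class `eeg_trialset`s.
#' @param bands list of band edges in Hz.
#' @return Test accuracy as a fraction.
#' @export
bandpower_lda_probe <- function(train, test,
                                bands = list(c(8, 12), c(13, 30))) {
  ftr <- bandpower_features(train, bands)
  fte <- bandpower_features(test, bands)
  lda <- fit_lda_safe(ftr, train$labels)
  pred <- as.integer(as.character(stats::predict(lda$lda, fte)$class))
  mean(pred == test$labels)
}

#' @rdname bandpower_lda_probe
#' @export
bandpower_lda_factory <- function(bands = list(c(8, 12), c(13, 30))) {
  function(train_set, val_set, seed) {
    ftr <- bandpower_features(train_set, bands)
    lda <- fit_lda_safe(ftr, train_set$labels)
    structure(list(lda = lda$lda, bands = bands, fs = train_set$fs),
              class = "bandpower_lda_model")
  }
}

#' @export
predict.bandpower_lda_model <- function(object, ds, ...) {
  f <- bandpower_features(ds, object$bands, fs = object$fs)
  as.integer(as.character(stats::predict(object$lda, f)$class))
}
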