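#' Band-pass filter specification
#'
#' Defaults match the standard motor-imagery setting: 8-30 Hz (mu + beta
#' rhythms), fourth-order Butterworth prototype, zero-phase (forward plus
#' time-reversed) application.
#'
#' @param low_hz lower band edge (Hz).
#' @param high_hz upper band edge (Hz).
#' @param order Butterworth prototype order.
#' @param zero_phase apply forward-backward (zero net phase, squared
#'   magnitude response)?
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(low_hz = 8, high_hz = 30, order = 4,
                        zero_phase = TRUE) {
  check_scalar(low_hz, "low_hz", lower = 0, strict_lower = TRUE)
  check_scalar(high_hz, "high_hz", lower = low_hz, strict_lower = TRUE)
  check_scalar(order, "order", lower = 1, integer = TRUE)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# One channel, one trial: reflect-pad symmetrically, then apply the exact
# transfer of a forward-backward pass -- multiplication by |H(e^{jw})|^2 in
# the frequency domain (zero net phase, squared magnitude response). The
# symmetric padding and the real even kernel make the operation exactly
# equivariant under time reversal, which a finite causal two-pass
# realization only approximates at the epoch edges.
zero_phase_filter <- function(b, a, x, pad = NULL) {
  n <- length(x)
  order <- length(a) - 1L
  if (is.null(pad)) pad <- 3L * (order %/% 2 + 1L)
  pad <- min(n - 1L, pad)
  if (pad > 0) {
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  } else {
    xp <- x
  }
  m <- length(xp)
  w <- 2 * pi * (seq_len(m) - 1) / m
  z <- exp(-1i * w)
  H <- polyeval(b, z) / polyeval(a, z)
  g2 <- Mod(H)^2
  y <- Re(stats::fft(stats::fft(xp) * g2, inverse = TRUE)) / m
  y[(pad + 1):(pad + n)]
}

# Horner evaluation of polynomial with coefficients c(p0, p1, ...) in
# ascending powers of z^-1 (digital-filter convention).
polyeval <- function(p, z) {
  acc <- rep(p[length(p)] + 0i, length(z))
  zi <- 1 / z
  for (k in rev(seq_len(length(p) - 1L))) {
    acc <- acc * zi + p[k]
  }
  acc
}

#' Common-average re-reference
#'
#' Subtracts, at every trial and sample, the mean across EEG channels, so
#' that the per-sample channel mean of the output is zero.
#'
#' @param ds an `eeg_trialset` with at least 2 channels.
#' @return The re-referenced `eeg_trialset`.
#' @export
car_reference <- function(ds) {
  stopifnot(inherits(ds, "eeg_trialset"))
  if (dim(ds$data)[2] < 2) {
    stop("common-average reference is degenerate for a single channel")
  }
  m <- apply(ds$data, c(1, 3), mean)           # [trials x samples]
  for (ch in seq_len(dim(ds$data)[2])) {
    ds$data[, ch, ] <- ds$data[, ch, ] - m
  }
  ds
}

#' Epoch a continuous recording around cue onsets
#'
#' Cuts half-open sample windows `[cue + round(start*fs), cue +
#' round(end*fs))` out of a continuous multichannel recording. Cue
#' positions are 0-based sample indices. Cues whose window would leave the
#' recording are reported via a message and skipped; their positions are
#' returned in the `skipped` attribute.
#'
#' @param continuous numeric matrix `[channels x samples]`.
#' @param cue_samples integer vector of 0-based cue sample positions.
#' @param window length-2 numeric window in seconds relative to the cue.
#' @param fs sampling rate (Hz).
#' @param labels optional per-cue class labels (0-based).
#' @param subjects optional per-cue subject ids (default all 1).
#' @param channel_names optional channel names.
#' @return An `eeg_trialset` of the surviving epochs with attribute
#'   `skipped` (0-based cue positions that were dropped).
#' @export
epoch_trials <- function(continuous, cue_samples, window = c(-0.5, 4.0),
                         fs = 250, labels = NULL, subjects = NULL,
                         channel_names = NULL) {
  stopifnot(is.matrix(continuous))
  n_rec <- ncol(continuous)
  i0 <- as.integer(cue_samples) + round(window[1] * fs)
  i1 <- as.integer(cue_samples) + round(window[2] * fs)   # exclusive
  ok <- i0 >= 0 & i1 <= n_rec
  skipped <- as.integer(cue_samples[!ok])
  if (length(skipped) > 0) {
    message(sprintf("epoch_trials: skipped %d cue(s) too close to the edge: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  keep <- which(ok)
  n_samp <- round((window[2] - window[1]) * fs)
  data <- array(0, dim = c(length(keep), nrow(continuous), n_samp))
  for (j in seq_along(keep)) {
    k <- keep[j]
    data[j, , ] <- continuous[, (i0[k] + 1):i1[k], drop = FALSE]
  }
  if (is.null(labels)) labels <- integer(length(cue_samples))
  if (is.null(subjects)) subjects <- rep(1L, length(cue_samples))
  out <- eeg_trialset(data, labels[keep], subjects[keep],
                      channel_names = channel_names, fs = fs,
                      window = window)
  attr(out, "skipped") <- skipped
  out
}

#' Reject trials with large EOG deflections
#'
#' Drops every trial whose EOG trace exceeds `threshold_uv` microvolts in
#' absolute value (strict inequality: a trial peaking at exactly the
#' threshold is retained). In the pipeline this runs before band-pass
#' filtering. Datasets without an EOG block are returned unchanged with a
#' warning.
#'
#' @param ds an `eeg_trialset`.
#' @param threshold_uv rejection threshold in microvolts.
#' @return A list with `dataset` (surviving trials) and `rejected_idx`
#'   (1-based indices of rejected trials in the input).
#' @export
reject_eog_trials <- function(ds, threshold_uv = 100) {
  stopifnot(inherits(ds, "eeg_trialset"))
  check_scalar(threshold_uv, "threshold_uv", lower = 0)
  if (is.null(ds$eog)) {
    warning("dataset has no EOG block; nothing rejected")
    return(list(dataset = ds, rejected_idx = integer(0)))
  }
  peaks <- apply(abs(ds$eog), 1, max)
  rejected <- which(peaks > threshold_uv)
  kept <- setdiff(seq_len(n_trials(ds)), rejected)
  list(dataset = ds[kept], rejected_idx = rejected)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel of every trial with the Butterworth band-pass of
#' `spec`, applied forward and backward (zero net phase; effective
#' magnitude response is the squared one-pass response). Epochs are
#' reflect-padded before filtering to suppress edge transients.
#'
#' @param ds an `eeg_trialset`.
#' @param spec a [filter_spec()].
#' @return The filtered `eeg_trialset`.
#' @export
bandpass_filter <- function(ds, spec = filter_spec()) {
  stopifnot(inherits(ds, "eeg_trialset"), inherits(spec, "filter_spec"))
  if (spec$high_hz >= ds$fs / 2) {
    stop("filter band must lie strictly below the Nyquist frequency")
  }
  bf <- signal::butter(spec$order,
                       c(spec$low_hz, spec$high_hz) / (ds$fs / 2),
                       type = "pass")
  d <- dim(ds$data)
  for (i in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- ds$data[i, ch, ]
      ds$data[i, ch, ] <- if (spec$zero_phase) {
        zero_phase_filter(bf$b, bf$a, x)
      } else {
        as.numeric(signal::filter(bf$b, bf$a, x))
      }
    }
  }
  ds
}

#' Per-channel standardizer fitted on training data only
#'
#' Computes per-channel mean and standard deviation pooling all trials and
#' samples of the training set (intended to be one subject's training
#' portion), and applies the frozen transform to any other set. Channels
#' with (near-)zero variance fall back to `sd_floor` with a warning.
#'
#' @param train training `eeg_trialset`.
#' @param sd_floor minimum standard deviation.
#' @return `fit_standardizer` returns a `standardizer` (fields `mean`,
#'   `sd`); `apply_standardizer` returns the transformed `eeg_trialset`.
#' @export
fit_standardizer <- function(train, sd_floor = 1e-8) {
  stopifnot(inherits(train, "eeg_trialset"))
  if (n_trials(train) == 0) stop("cannot fit a standardizer on an empty set")
  n_ch <- dim(train$data)[2]
  mu <- numeric(n_ch); sd_ <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    v <- as.numeric(train$data[, ch, ])
    mu[ch] <- mean(v)
    s <- stats::sd(v) * sqrt((length(v) - 1) / length(v))  # population sd
    sd_[ch] <- s
  }
  if (any(sd_ < sd_floor)) {
    warning(sprintf("constant channel(s) %s: sd floored at %g",
                    paste(which(sd_ < sd_floor), collapse = ","), sd_floor))
    sd_ <- pmax(sd_, sd_floor)
  }
  structure(list(mean = mu, sd = sd_, sd_floor = sd_floor),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param s a fitted `standardizer`.
#' @param ds the `eeg_trialset` to transform (train, validation or test);
#'   fitted parameters are used unchanged.
#' @export
apply_standardizer <- function(s, ds) {
  stopifnot(inherits(s, "standardizer"), inherits(ds, "eeg_trialset"))
  if (dim(ds$data)[2] != length(s$mean)) {
    stop("standardizer channel count does not match the dataset")
  }
  for (ch in seq_along(s$mean)) {
    ds$data[, ch, ] <- (ds$data[, ch, ] - s$mean[ch]) / s$sd[ch]
  }
  ds
}

#' Stratified split scheme
#'
#' The two per-subject partition schemes: `"IV-2a"` reserves 20% of each
#' subject's trials for testing and 25% of the remainder for validation;
#' `"IV-2b"` reserves 15% for testing and 18% of the remainder for
#' validation. Splits are stratified by class and deterministic under the
#' seed.
#'
#' @param name `"IV-2a"` or `"IV-2b"`.
#' @param seed integer seed.
#' @return A `split_scheme` object.
#' @export
split_scheme <- function(name = c("IV-2a", "IV-2b"), seed = 1) {
  name <- match.arg(name)
  p <- if (name == "IV-2a") c(test = 0.20, val = 0.25) else c(test = 0.15, val = 0.18)
  structure(list(name = name, test_fraction = p[["test"]],
                 val_fraction_of_remainder = p[["val"]],
                 stratified = TRUE, seed = as.integer(seed)),
            class = "split_scheme")
}

#' Per-subject stratified train/validation/test split
#'
#' For each subject: `round(test_fraction * n)` trials go to test and
#' `round(val_fraction_of_remainder * (n - n_test))` of the remainder to
#' validation (round-half-to-even), allocated over classes by
#' largest-remainder apportionment so per-class counts stay within one
#' trial of exact proportionality. Index sets are disjoint and exhaustive.
#'
#' @param ds an `eeg_trialset`.
#' @param scheme a [split_scheme()].
#' @return A `split_plan`: per subject, integer vectors `train_idx`,
#'   `val_idx`, `test_idx` (1-based global trial indices).
#' @export
stratified_split <- function(ds, scheme) {
  stopifnot(inherits(ds, "eeg_trialset"), inherits(scheme, "split_scheme"))
  with_seed(scheme$seed, {
    plans <- lapply(sort(unique(ds$subjects)), function(s) {
      idx <- which(ds$subjects == s)
      split_one_subject(idx, ds$labels[idx], scheme$test_fraction,
                        scheme$val_fraction_of_remainder, ds$n_classes)
    })
    names(plans) <- as.character(sort(unique(ds$subjects)))
    structure(list(subjects = plans, scheme = scheme), class = "split_plan")
  })
}

split_one_subject <- function(idx, labels, test_frac, val_frac, n_classes) {
  n <- length(idx)
  classes <- sort(unique(labels))
  n_test <- round_half_even(test_frac * n)
  by_class <- lapply(classes, function(k) sample(idx[labels == k]))
  counts <- vapply(by_class, length, integer(1))
  if (any(counts < 2)) {
    stop(sprintf("class %s has fewer than 2 trials for this subject",
                 paste(classes[counts < 2], collapse = ",")))
  }
  q_test <- apportion(counts * n_test / n, n_test)
  test_idx <- unlist(lapply(seq_along(by_class), function(j) {
    if (q_test[j] > 0) by_class[[j]][seq_len(q_test[j])] else integer(0)
  }))
  remain <- lapply(seq_along(by_class), function(j) {
    by_class[[j]][setdiff(seq_along(by_class[[j]]), seq_len(q_test[j]))]
  })
  n_rem <- n - n_test
  n_val <- round_half_even(val_frac * n_rem)
  counts_r <- vapply(remain, length, integer(1))
  q_val <- apportion(counts_r * n_val / n_rem, n_val)
  val_idx <- unlist(lapply(seq_along(remain), function(j) {
    if (q_val[j] > 0) remain[[j]][seq_len(q_val[j])] else integer(0)
  }))
  train_idx <- unlist(lapply(seq_along(remain), function(j) {
    remain[[j]][setdiff(seq_along(remain[[j]]), seq_len(q_val[j]))]
  }))
  parts <- list(test = q_test, val = q_val,
                train = counts - q_test - q_val)
  for (p in names(parts)) {
    if (any(parts[[p]] < 1)) {
      stop(sprintf("class %s would receive no trials in the %s part",
                   paste(classes[parts[[p]] < 1], collapse = ","), p))
    }
  }
  list(train_idx = sort(as.integer(train_idx)),
       val_idx = sort(as.integer(val_idx)),
       test_idx = sort(as.integer(test_idx)))
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> scheme %s (test %.0f%%, val %.0f%% of remainder), %d subject(s)\n",
              x$scheme$name, 100 * x$scheme$test_fraction,
              100 * x$scheme$val_fraction_of_remainder, length(x$subjects)))
  for (s in names(x$subjects)) {
    p <- x$subjects[[s]]
    cat(sprintf("  subject %s: train %d / val %d / test %d\n", s,
                length(p$train_idx), length(p$val_idx), length(p$test_idx)))
  }
  invisible(x)
}

#' Run the fixed preprocessing pipeline
#'
#' Applies, in this order: common-average reference, EOG trial rejection
#' (strictly before filtering), zero-phase band-pass, and per-subject
#' stratified splitting. Standardization is fitted per subject on the
#' training indices only and applied to all three parts. Epoching is
#' assumed done (the container is already epoched).
#'
#' @param ds an `eeg_trialset`.
#' @param fspec a [filter_spec()].
#' @param scheme a [split_scheme()].
#' @param reject_uv EOG rejection threshold (microvolts); `NULL` skips
#'   rejection.
#' @param car apply common-average referencing (needs >= 2 channels)?
#' @return A list: `dataset` (preprocessed, standardized trials), `plan`
#'   (the `split_plan`), `rejected_idx`, `standardizers` (per subject),
#'   and `log` (ordered record of the stages applied).
#' @export
preprocess_pipeline <- function(ds, fspec = filter_spec(),
                                scheme = split_scheme("IV-2a"),
                                reject_uv = 100, car = TRUE) {
  log <- character(0)
  if (car) {
    ds <- car_reference(ds)
    log <- c(log, "car")
  }
  rejected <- integer(0)
  if (!is.null(reject_uv) && !is.null(ds$eog)) {
    r <- reject_eog_trials(ds, reject_uv)
    ds <- r$dataset
    rejected <- r$rejected_idx
    log <- c(log, sprintf("reject_eog>%g", reject_uv))
  }
  ds <- bandpass_filter(ds, fspec)
  log <- c(log, sprintf("bandpass%g-%g", fspec$low_hz, fspec$high_hz))
  plan <- stratified_split(ds, scheme)
  log <- c(log, sprintf("split:%s", scheme$name))
  standardizers <- list()
  for (s in names(plan$subjects)) {
    p <- plan$subjects[[s]]
    std <- fit_standardizer(ds[p$train_idx])
    standardizers[[s]] <- std
    all_idx <- c(p$train_idx, p$val_idx, p$test_idx)
    sub <- apply_standardizer(std, ds[all_idx])
    ds$data[all_idx, , ] <- sub$data
  }
  log <- c(log, "standardize(train-only fit)")
  list(dataset = ds, plan = plan, rejected_idx = rejected,
       standardizers = standardizers, log = log)
}
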