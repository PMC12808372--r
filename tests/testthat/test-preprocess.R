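make_ds <- function(data, fs = 250, window = NULL, eog = NULL) {
  d <- dim(data)
  if (is.null(window)) window <- c(0, d[3] / fs)
  eeg_trialset(data, rep(0L, d[1]), rep(1L, d[1]), fs = fs,
               window = window, eog = eog)
}

test_that("common-average reference zeroes the channel mean", {
  set.seed(4)
  x <- array(rnorm(2 * 4 * 100), dim = c(2, 4, 100))
  ds <- make_ds(x, fs = 100, window = c(0, 1))
  out <- car_reference(ds)
  expect_lt(max(abs(apply(out$data, c(1, 3), mean))), 1e-9)
  # already centered input is unchanged
  again <- car_reference(out)
  expect_equal(again$data, out$data, tolerance = 1e-12)
  # constant offset on all channels is removed
  shifted <- ds
  shifted$data <- shifted$data + 7.5
  expect_equal(car_reference(shifted)$data, out$data, tolerance = 1e-9)
  one_ch <- make_ds(array(0, dim = c(2, 1, 100)), fs = 100, window = c(0, 1))
  expect_error(car_reference(one_ch), "single channel")
})

test_that("epoching cuts exact half-open windows and logs skipped cues", {
  fs <- 250
  cont <- matrix(rnorm(2 * 3000), nrow = 2)
  cues <- c(200, 1500)
  ep <- epoch_trials(cont, cues, window = c(-0.5, 4.0), fs = fs)
  expect_equal(dim(ep$data)[3], 1125)           # 4.5 s x 250 Hz
  for (j in seq_along(cues)) {
    i0 <- cues[j] + round(-0.5 * fs)
    expect_equal(ep$data[j, , ], cont[, (i0 + 1):(i0 + 1125)])
  }
  expect_message(
    ep2 <- epoch_trials(cont, c(0, 1500), window = c(-0.5, 4.0), fs = fs),
    "skipped")
  expect_equal(dim(ep2$data)[1], 1)
  expect_identical(attr(ep2, "skipped"), 0L)
})

test_that("EOG rejection uses a strict threshold and reports indices", {
  n <- 5; ns <- 250
  eog <- array(stats::runif(n * 1 * ns, -50, 50), dim = c(n, 1, ns))
  eog[2, 1, 100] <- 150
  eog[4, 1, 10] <- 100          # exactly at threshold: retained
  ds <- make_ds(array(0, dim = c(n, 3, ns)), fs = 250, window = c(0, 1),
                eog = eog)
  r <- reject_eog_trials(ds, 100)
  expect_identical(r$rejected_idx, 2L)
  expect_equal(n_trials(r$dataset), 4)
  no_eog <- make_ds(array(0, dim = c(n, 3, ns)), fs = 250, window = c(0, 1))
  expect_warning(r2 <- reject_eog_trials(no_eog, 100), "no EOG")
  expect_identical(r2$rejected_idx, integer(0))
})

test_that("band-pass gains match the analytic Butterworth response", {
  fs <- 250; n <- 1000
  t <- (seq_len(n) - 1) / fs
  # analytic squared magnitude of the order-4 band-pass prototype,
  # doubled by the forward-backward pass
  h2 <- function(f, lo = 8, hi = 30, ord = 4) {
    1 / (1 + ((f^2 - lo * hi) / (f * (hi - lo)))^(2 * ord))
  }
  mid <- 251:750                                 # steady-state region
  for (f0 in c(20, 2)) {
    x <- sin(2 * pi * f0 * t)
    ds <- make_ds(array(x, dim = c(1, 1, n)), fs = fs, window = c(0, 4))
    y <- bandpass_filter(ds, filter_spec())$data[1, 1, ]
    gain <- sqrt(mean(y[mid]^2)) / sqrt(mean(x[mid]^2))
    expect_lt(abs(gain - h2(f0)), 0.02)
  }
  x20 <- sin(2 * pi * 20 * t)
  ds <- make_ds(array(x20, dim = c(1, 1, n)), fs = fs, window = c(0, 4))
  y <- bandpass_filter(ds, filter_spec())$data[1, 1, ]
  expect_gte(sqrt(mean(y[mid]^2)) / sqrt(mean(x20[mid]^2)), 0.95)
  x2 <- sin(2 * pi * 2 * t)
  ds$data[1, 1, ] <- x2
  y2 <- bandpass_filter(ds, filter_spec())$data[1, 1, ]
  expect_lte(sqrt(mean(y2[mid]^2)) / sqrt(mean(x2[mid]^2)), 0.01)
  # zero in, zero out; Nyquist violation errors
  ds$data[1, 1, ] <- 0
  expect_equal(max(abs(bandpass_filter(ds, filter_spec())$data)), 0)
  expect_error(bandpass_filter(ds, filter_spec(8, 130)), "Nyquist")
})

test_that("zero-phase filtering commutes with time reversal", {
  set.seed(8)
  x <- rnorm(600)
  ds <- make_ds(array(x, dim = c(1, 1, 600)), fs = 250,
                window = c(0, 2.4))
  dsr <- ds
  dsr$data[1, 1, ] <- rev(x)
  y <- bandpass_filter(ds, filter_spec())$data[1, 1, ]
  yr <- bandpass_filter(dsr, filter_spec())$data[1, 1, ]
  expect_lt(max(abs(rev(yr) - y)) / max(abs(y)), 1e-9)
})

test_that("standardizer fits on train only and transfers frozen parameters", {
  set.seed(6)
  x <- array(rnorm(20 * 2 * 250, mean = 5, sd = 2), dim = c(20, 2, 250))
  train <- make_ds(x, fs = 250, window = c(0, 1))
  s <- fit_standardizer(train)
  z <- apply_standardizer(s, train)
  for (ch in 1:2) {
    v <- as.numeric(z$data[, ch, ])
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(stats::sd(v) - 1), 1e-3)
  }
  # shifted test set: mean moves by shift / sd_train, proving no re-fit
  test <- train
  test$data <- test$data + 10
  zt <- apply_standardizer(s, test)
  for (ch in 1:2) {
    expect_equal(mean(zt$data[, ch, ]) - mean(z$data[, ch, ]),
                 10 / s$sd[ch], tolerance = 1e-9)
  }
  # mutating test data cannot change fitted parameters
  before <- list(s$mean, s$sd)
  test$data[] <- 999
  expect_identical(list(s$mean, s$sd), before)
  # constant channel falls back to the floor
  const <- make_ds(array(3, dim = c(4, 1, 250)), fs = 250, window = c(0, 1))
  expect_warning(sc <- fit_standardizer(const), "floored")
  expect_equal(max(abs(apply_standardizer(sc, const)$data)), 0)
})

test_that("stratified splits reproduce the documented arithmetic", {
  mk <- function(n) {
    eeg_trialset(array(0, dim = c(n, 2, 50)),
                 labels = rep(0:1, each = n / 2),
                 subjects = rep(1L, n), fs = 50, window = c(0, 1))
  }
  plan_a <- stratified_split(mk(40), split_scheme("IV-2a", seed = 3))
  p <- plan_a$subjects[["1"]]
  expect_equal(length(p$test_idx), 8)    # 0.20 x 40
  expect_equal(length(p$val_idx), 8)     # 0.25 x 32
  expect_equal(length(p$train_idx), 24)
  labs <- rep(0:1, each = 20)
  expect_equal(as.integer(table(labs[p$test_idx])), c(4L, 4L))
  plan_b <- stratified_split(mk(200), split_scheme("IV-2b", seed = 3))
  p <- plan_b$subjects[["1"]]
  expect_equal(length(p$test_idx), 30)   # 0.15 x 200
  expect_equal(length(p$val_idx), 31)    # round(0.18 x 170)
  expect_equal(length(p$train_idx), 139)
})

test_that("splits are deterministic, disjoint and exhaustive for arbitrary shapes", {
  plan1 <- NULL
  for (rep_i in 1:2) {
    set.seed(100 + rep_i)  # outer RNG state must not matter
    cases <- list(c(n = 30, K = 2), c(n = 47, K = 2), c(n = 60, K = 4))
    plans <- lapply(cases, function(cs) {
      n <- cs["n"]; K <- cs["K"]
      labs <- rep(seq_len(K) - 1L, length.out = n)
      ds <- eeg_trialset(array(0, dim = c(n, 2, 50)), labs,
                         rep(1L, n), fs = 50, window = c(0, 1))
      stratified_split(ds, split_scheme("IV-2a", seed = 7))
    })
    for (j in seq_along(plans)) {
      p <- plans[[j]]$subjects[["1"]]
      n <- cases[[j]]["n"]
      all_idx <- sort(c(p$train_idx, p$val_idx, p$test_idx))
      expect_identical(all_idx, seq_len(as.integer(n)))
      expect_equal(length(intersect(p$train_idx, p$test_idx)), 0)
      expect_equal(length(intersect(p$train_idx, p$val_idx)), 0)
      expect_equal(length(intersect(p$val_idx, p$test_idx)), 0)
      # per-class proportionality within one trial
      K <- cases[[j]]["K"]
      labs <- rep(seq_len(K) - 1L, length.out = n)
      for (part in list(p$test_idx, p$val_idx)) {
        counts <- table(factor(labs[part], levels = 0:(K - 1)))
        expect_lte(max(counts) - min(counts), 1)
      }
    }
    if (rep_i == 1) plan1 <- plans else expect_identical(plans, plan1)
  }
})

test_that("pipeline applies stages in the contracted order without leakage", {
  ds <- generate_dataset(synth_spec(n_subjects = 2, n_trials_per_class = 10,
                                    artifact_fraction = 0.1,
                                    artifact_amplitude = 150,
                                    epoch_window = c(-0.2, 0.824),
                                    seed = 21))
  out <- preprocess_pipeline(ds, scheme = split_scheme("IV-2a", seed = 1))
  expect_identical(out$log[1], "car")
  expect_match(out$log[2], "reject_eog")
  expect_match(out$log[3], "bandpass")
  expect_match(out$log[4], "split")
  expect_match(out$log[5], "standardize")
  expect_gt(length(out$rejected_idx), 0)
  # per-subject training portions are standardized
  for (s in names(out$plan$subjects)) {
    p <- out$plan$subjects[[s]]
    tr <- out$dataset[p$train_idx]
    for (ch in seq_len(dim(tr$data)[2])) {
      expect_lt(abs(mean(tr$data[, ch, ])), 1e-6)
    }
  }
})
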