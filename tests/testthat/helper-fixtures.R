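# Shared fixtures: all synthetic, generated at test time.

# A small separable 2-class dataset (strong ERD, decent SNR).
tiny_separable_ds <- function(n_subjects = 3, n_trials_per_class = 10,
                              erd_depth = 0.6, snr = 2, seed = 11,
                              epoch_window = c(-0.5, 4.0), ...) {
  generate_dataset(synth_spec(
    n_subjects = n_subjects, n_trials_per_class = n_trials_per_class,
    n_classes = 2, n_channels = 3, erd_depth = erd_depth, snr = snr,
    artifact_fraction = 0, subject_gain_sd = 0.1,
    epoch_window = epoch_window, seed = seed, ...))
}

# Tiny network configuration for fast training tests; any model_config
# field can be overridden through `...`.
tiny_cfg <- function(n_channels = 3, n_samples = 256, n_classes = 2, ...) {
  args <- list(variant_name = "tiny", n_channels = n_channels,
               n_samples = n_samples, n_classes = n_classes,
               deep_block_filters = c(8, 12), shallow_spatial_filters = 12,
               shallow_temporal_kernel_t = 13, fusion_dim = 16,
               n_transformer_layers = 1, n_heads = 2, bilstm_layers = 1,
               bilstm_hidden = 8, mlp_hidden = 16)
  user <- list(...)
  args[names(user)] <- user
  do.call(model_config, args)
}

# Standardize a whole trial set against itself (sufficient for sanity
# tests that do not exercise the split contract).
self_standardize <- function(ds) {
  apply_standardizer(fit_standardizer(ds), ds)
}

# Welch power spectral density, written independently of the package
# internals: mean periodogram over half-overlapping Hann segments.
welch_psd <- function(x, fs, seg_len = 256) {
  seg_len <- min(seg_len, length(x))
  hop <- seg_len %/% 2
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  starts <- seq(1, length(x) - seg_len + 1, by = hop)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)] * win
    acc <- acc + Mod(stats::fft(seg))^2
  }
  p <- acc / (length(starts) * sum(win^2) * fs)
  n_half <- seg_len %/% 2
  list(freq = (seq_len(n_half) - 1) * fs / seg_len,
       psd = p[seq_len(n_half)])
}

# Band power from the Welch PSD (test-side oracle).
welch_bandpower <- function(x, fs, band, seg_len = 256) {
  w <- welch_psd(x, fs, seg_len)
  sel <- w$freq >= band[1] & w$freq <= band[2]
  sum(w$psd[sel])
}

# Closed-form parameter counts from the layer shape arithmetic,
# independent of the builder's bookkeeping.
expected_param_count <- function(cfg) {
  conv <- function(ci, co, k) co * ci * k + co
  bn <- function(f) 2 * f
  dense <- function(i, o) o * i + o
  ln <- function(d) 2 * d
  mha <- function(d) 4 * (d * d + d)
  lstm <- function(i, h) 4 * h * (i + h) + 4 * h
  d <- cfg$fusion_dim
  ff <- round(cfg$transformer_ff_mult * d)
  h <- cfg$bilstm_hidden
  f1 <- cfg$deep_block_filters[1]; f2 <- cfg$deep_block_filters[2]
  fs <- cfg$shallow_spatial_filters
  total <-
    conv(cfg$n_channels, f1, cfg$deep_kernels_t[1]) + bn(f1) +
    conv(f1, f2, cfg$deep_kernels_t[2]) + bn(f2) +
    conv(cfg$n_channels, fs, 1) +
    conv(fs, fs, cfg$shallow_temporal_kernel_t) + bn(fs) +
    conv(f2 + fs, d, 1) +
    cfg$n_transformer_layers * (mha(d) + 2 * ln(d) +
                                  dense(d, ff) + dense(ff, d))
  for (i in seq_len(cfg$bilstm_layers)) {
    n_in <- if (i == 1) d else 2 * h
    total <- total + 2 * lstm(n_in, h)
  }
  if (cfg$extra_lstm_branch) total <- total + lstm(d, h)
  feat <- 2 * h + if (cfg$extra_lstm_branch) h else 0
  total + dense(feat, cfg$mlp_hidden) + dense(cfg$mlp_hidden, cfg$n_classes)
}

# Flat list of all parameter arrays of a model (for bit-identity checks).
param_snapshot <- function(model) {
  midecode:::model_get_params(model)
}

# Constant classifier for LOSO protocol tests.
constant_classifier_factory <- function(class = 0L) {
  function(train_set, val_set, seed) {
    structure(list(class = class), class = "constant_clf")
  }
}
predict.constant_clf <- function(object, ds, ...) {
  rep(object$class, n_trials(ds))
}
registerS3method("predict", "constant_clf", predict.constant_clf,
                 envir = asNamespace("stats"))

# Factory that records which subjects it was trained/validated on.
recording_factory <- function(log_env) {
  function(train_set, val_set, seed) {
    log_env$seen <- c(log_env$seen,
                      unique(c(train_set$subjects, val_set$subjects)))
    structure(list(), class = "constant_clf2")
  }
}
predict.constant_clf2 <- function(object, ds, ...) {
  rep(0L, n_trials(ds))
}
registerS3method("predict", "constant_clf2", predict.constant_clf2,
                 envir = asNamespace("stats"))
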