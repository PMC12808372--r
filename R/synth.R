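#' Specification for the synthetic motor-imagery EEG generator
#'
#' Describes a synthetic dataset of cue-locked motor-imagery epochs. Each
#' trial is a 1/f^alpha background plus band-limited mu (8-12 Hz) and beta
#' (13-30 Hz) rhythms on every channel; the class-assigned contralateral
#' channel has its rhythm amplitude attenuated by `erd_depth` in the
#' post-cue interval (event-related desynchronization). Per-subject
#' log-normal gains emulate inter-subject amplitude variability, and an
#' optional fraction of trials carries a large slow electrooculogram (EOG)
#' deflection.
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_class trials per class per subject.
#' @param n_classes 2 or 4.
#' @param n_channels EEG channel count (default 3, emulating C3/Cz/C4).
#' @param fs sampling rate in Hz.
#' @param epoch_window seconds relative to cue, default `c(-0.5, 4)`.
#' @param erd_depth fraction in \[0,1\]: relative rhythm attenuation in the
#'   modulated channel after the cue. 0 disables class modulation.
#' @param background_exponent spectral slope alpha of the 1/f^alpha
#'   background.
#' @param snr rhythm-to-background amplitude (RMS) ratio.
#' @param subject_gain_sd standard deviation (log scale) of the per-subject
#'   multiplicative gain.
#' @param artifact_fraction fraction of trials receiving an EOG artifact.
#' @param artifact_amplitude EOG artifact peak amplitude in microvolts.
#' @param n_eog number of EOG channels.
#' @param class_channel_map optional integer vector (length `n_classes`,
#'   1-based channel indices) assigning each class its modulated channel;
#'   defaults to round-robin over the motor channels (for 3 channels these
#'   are C3 and C4, i.e. channels 1 and 3).
#' @param seed integer seed; identical specs (including seed) generate
#'   bit-identical datasets.
#'
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(n_subjects = 3, n_trials_per_class = 20,
                       n_classes = 2, n_channels = 3, fs = 250,
                       epoch_window = c(-0.5, 4.0), erd_depth = 0.5,
                       background_exponent = 1, snr = 1.5,
                       subject_gain_sd = 0.2, artifact_fraction = 0.05,
                       artifact_amplitude = 150, n_eog = 3,
                       class_channel_map = NULL, seed = 1) {
  check_scalar(n_subjects, "n_subjects", lower = 1, integer = TRUE)
  check_scalar(n_trials_per_class, "n_trials_per_class", lower = 1,
               integer = TRUE)
  check_scalar(n_classes, "n_classes", integer = TRUE)
  if (!n_classes %in% c(2L, 4L)) stop("field 'n_classes' must be 2 or 4")
  check_scalar(n_channels, "n_channels", lower = 1, integer = TRUE)
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  if (length(epoch_window) != 2 || epoch_window[1] >= epoch_window[2]) {
    stop("field 'epoch_window' must satisfy start < end")
  }
  check_scalar(erd_depth, "erd_depth", lower = 0, upper = 1)
  check_scalar(background_exponent, "background_exponent", lower = 0)
  check_scalar(snr, "snr", lower = 0)
  check_scalar(subject_gain_sd, "subject_gain_sd", lower = 0)
  check_scalar(artifact_fraction, "artifact_fraction", lower = 0, upper = 1)
  check_scalar(artifact_amplitude, "artifact_amplitude", lower = 0)
  check_scalar(n_eog, "n_eog", lower = 1, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  if (is.null(class_channel_map)) {
    motor <- if (n_channels == 3) c(1L, 3L) else seq_len(n_channels)
    class_channel_map <- motor[((seq_len(n_classes) - 1L) %% length(motor)) + 1L]
  }
  class_channel_map <- as.integer(class_channel_map)
  if (length(class_channel_map) != n_classes ||
      any(class_channel_map < 1) || any(class_channel_map > n_channels)) {
    stop("field 'class_channel_map' must give one valid channel per class")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_trials_per_class = as.integer(n_trials_per_class),
         n_classes = as.integer(n_classes),
         n_channels = as.integer(n_channels), fs = fs,
         epoch_window = as.numeric(epoch_window), erd_depth = erd_depth,
         background_exponent = background_exponent, snr = snr,
         subject_gain_sd = subject_gain_sd,
         artifact_fraction = artifact_fraction,
         artifact_amplitude = artifact_amplitude, n_eog = as.integer(n_eog),
         class_channel_map = class_channel_map, seed = as.integer(seed)),
    class = "synth_spec")
}

# Baseline RMS of the 1/f background, in microvolts. The rhythm RMS is
# snr * BACKGROUND_RMS_UV split evenly (in power) over the mu and beta bands.
BACKGROUND_RMS_UV <- 10

#' 1/f^alpha background noise
#'
#' Spectrally shaped Gaussian noise: white noise is transformed to the
#' frequency domain, scaled by f^(-alpha/2), and transformed back, then
#' rescaled to the requested RMS. The DC bin is zeroed.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param alpha spectral exponent (power spectrum ~ 1/f^alpha).
#' @param rms target root-mean-square amplitude.
#' @return Numeric vector of length `n`.
#' @export
one_over_f_noise <- function(n, fs, alpha = 1, rms = 1) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  # two-sided frequency axis: fold above Nyquist
  f <- pmin(f, fs - f)
  scale <- c(0, f[-1]^(-alpha / 2))
  y <- Re(stats::fft(xf * scale, inverse = TRUE)) / n
  y <- y - mean(y)
  y * (rms / stats::sd(y))
}

#' Band-limited noise rhythm
#'
#' White Gaussian noise band-passed with a zero-phase Butterworth filter and
#' rescaled to a target RMS; the building block for the mu and beta rhythm
#' components (amplitude-modulated band-limited noise rather than a
#' sinusoid, so ERD shows up as a band-power change, not a phase cue).
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param band length-2 numeric band edges in Hz.
#' @param rms target RMS amplitude.
#' @param order Butterworth prototype order.
#' @return Numeric vector of length `n`.
#' @export
band_limited_noise <- function(n, fs, band, rms = 1, order = 4) {
  x <- stats::rnorm(n)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- zero_phase_filter(bf$b, bf$a, x)
  y <- y - mean(y)
  y * (rms / stats::sd(y))
}

#' Generate a synthetic motor-imagery dataset
#'
#' Draws balanced cue-locked trials for every subject according to a
#' [synth_spec()]. See that constructor for the generative model. The
#' returned set always carries EOG channels: low-amplitude slow noise, with
#' `artifact_fraction` of the trials given a half-sine blink-like
#' deflection of peak amplitude `artifact_amplitude` via
#' [inject_eog_artifacts()].
#'
#' @param spec a `synth_spec`.
#' @return An [eeg_trialset()].
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, generate_dataset_impl(spec))
}

generate_dataset_impl <- function(spec) {
  w <- spec$epoch_window
  n_samp <- round((w[2] - w[1]) * spec$fs)
  t_axis <- w[1] + (seq_len(n_samp) - 1) / spec$fs
  post <- t_axis >= 0     # ERD applies to the post-cue interval only
  n_per_subj <- spec$n_trials_per_class * spec$n_classes
  n_total <- n_per_subj * spec$n_subjects
  band_rms <- spec$snr * BACKGROUND_RMS_UV / sqrt(2)

  data <- array(0, dim = c(n_total, spec$n_channels, n_samp))
  eog <- array(0, dim = c(n_total, spec$n_eog, n_samp))
  labels <- integer(n_total)
  subjects <- integer(n_total)
  trial <- 0L
  for (s in seq_len(spec$n_subjects)) {
    gain <- stats::rlnorm(1, meanlog = 0, sdlog = spec$subject_gain_sd)
    # balanced labels, shuffled within subject
    lab <- sample(rep(seq_len(spec$n_classes) - 1L,
                      each = spec$n_trials_per_class))
    for (k in seq_len(n_per_subj)) {
      trial <- trial + 1L
      cls <- lab[k]
      mod_ch <- spec$class_channel_map[cls + 1L]
      for (ch in seq_len(spec$n_channels)) {
        bg <- one_over_f_noise(n_samp, spec$fs, spec$background_exponent,
                               rms = BACKGROUND_RMS_UV)
        mu <- band_limited_noise(n_samp, spec$fs, c(8, 12), rms = band_rms)
        beta <- band_limited_noise(n_samp, spec$fs, c(13, 30), rms = band_rms)
        env <- rep(1, n_samp)
        if (ch == mod_ch) env[post] <- 1 - spec$erd_depth
        data[trial, ch, ] <- gain * (bg + env * (mu + beta))
      }
      for (e in seq_len(spec$n_eog)) {
        eog[trial, e, ] <- one_over_f_noise(n_samp, spec$fs, 2, rms = 5)
      }
      labels[trial] <- cls
      subjects[trial] <- s
    }
  }
  ds <- eeg_trialset(data, labels, subjects,
                     channel_names = default_channel_names(spec$n_channels),
                     fs = spec$fs, eog = eog, window = w)
  n_art <- floor(spec$artifact_fraction * n_total)
  if (n_art > 0) {
    idx <- sort(sample(n_total, n_art))
    ds <- inject_eog_artifacts(ds, idx, spec$artifact_amplitude)
  }
  ds
}

default_channel_names <- function(n_channels) {
  if (n_channels == 3) c("C3", "Cz", "C4") else paste0("Ch", seq_len(n_channels))
}

#' Inject ocular artifacts into EOG channels
#'
#' Adds a half-sine deflection of 0.5 s duration at a random onset to the
#' EOG traces of the selected trials. The deflection's sign is matched to
#' the trace value at its peak so the resulting trace is guaranteed to
#' reach at least `amplitude` in absolute value; other trials are returned
#' untouched. Onset positions are drawn from the current RNG state.
#'
#' @param ds an `eeg_trialset` with an `eog` block.
#' @param indices 1-based trial indices to receive an artifact.
#' @param amplitude peak deflection amplitude in microvolts.
#' @return A copy of `ds` with modified EOG traces.
#' @export
inject_eog_artifacts <- function(ds, indices, amplitude) {
  stopifnot(inherits(ds, "eeg_trialset"))
  if (is.null(ds$eog)) stop("dataset has no EOG block to inject into")
  check_scalar(amplitude, "amplitude", lower = 0)
  indices <- as.integer(indices)
  if (length(indices) == 0) return(ds)
  if (any(indices < 1) || any(indices > n_trials(ds))) {
    stop("artifact trial indices out of range")
  }
  n_samp <- dim(ds$eog)[3]
  dur <- max(2L, min(n_samp, round(0.5 * ds$fs)))
  shape <- sin(pi * (seq_len(dur) - 1) / (dur - 1))   # half-sine, peak 1
  peak_off <- which.max(shape)
  for (i in indices) {
    onset <- sample.int(n_samp - dur + 1L, 1L)
    span <- onset:(onset + dur - 1L)
    for (e in seq_len(dim(ds$eog)[2])) {
      at_peak <- ds$eog[i, e, onset + peak_off - 1L]
      sgn <- if (at_peak >= 0) 1 else -1
      ds$eog[i, e, span] <- ds$eog[i, e, span] + sgn * amplitude * shape
    }
  }
  ds
}
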