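#' Epoched EEG trial set
#'
#' The universal exchange container of the package: a set of cue-locked EEG
#' epochs with class labels and subject identifiers. All preprocessing,
#' training and evaluation functions consume and return this class.
#'
#' @param data numeric array `[n_trials, n_channels, n_samples]`, microvolts.
#' @param labels integer vector of class labels, values `0 .. K-1`.
#' @param subjects integer vector of subject identifiers, one per trial.
#' @param channel_names character vector of channel names.
#' @param fs sampling rate in Hz.
#' @param eog optional numeric array `[n_trials, n_eog, n_samples]` of
#'   electrooculogram traces (microvolts), used only for artifact rejection.
#' @param window length-2 numeric, epoch window in seconds relative to the
#'   cue (start < end).
#'
#' @return An object of class `eeg_trialset`: a list with the fields above
#'   plus `n_classes`.
#' @export
eeg_trialset <- function(data, labels, subjects, channel_names = NULL,
                         fs = 250, eog = NULL, window = c(-0.5, 4.0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("'data' must be a 3-d array [trials x channels x samples]")
  }
  n_trials <- dim(data)[1]
  n_channels <- dim(data)[2]
  n_samples <- dim(data)[3]
  labels <- as.integer(labels)
  subjects <- as.integer(subjects)
  if (length(labels) != n_trials || length(subjects) != n_trials) {
    stop("'labels' and 'subjects' must match the first dimension of 'data'")
  }
  if (any(!is.finite(data))) stop("'data' contains non-finite values")
  if (n_trials > 0 && any(labels < 0)) stop("labels must be >= 0")
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  if (length(window) != 2L || window[1] >= window[2]) {
    stop("'window' must be (start, end) seconds with start < end")
  }
  expected <- round((window[2] - window[1]) * fs)
  if (n_samples != expected) {
    stop(sprintf(
      "n_samples (%d) != round((window_end - window_start) * fs) = %d",
      n_samples, expected))
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("Ch", seq_len(n_channels))
  }
  if (length(channel_names) != n_channels) {
    stop("'channel_names' must have one entry per channel")
  }
  if (!is.null(eog)) {
    if (!is.array(eog) || length(dim(eog)) != 3L ||
        dim(eog)[1] != n_trials || dim(eog)[3] != n_samples) {
      stop("'eog' must be [n_trials x n_eog x n_samples]")
    }
    if (any(!is.finite(eog))) stop("'eog' contains non-finite values")
  }
  n_classes <- if (n_trials > 0) max(labels) + 1L else 0L
  structure(
    list(data = data, labels = labels, subjects = subjects,
         channel_names = as.character(channel_names), fs = fs,
         eog = eog, window = as.numeric(window), n_classes = n_classes),
    class = "eeg_trialset")
}

#' @export
print.eeg_trialset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_trialset> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  classes: %d  subjects: %d  window: [%g, %g] s  eog: %s\n",
              x$n_classes, length(unique(x$subjects)),
              x$window[1], x$window[2],
              if (is.null(x$eog)) "none" else dim(x$eog)[2]))
  invisible(x)
}

#' Subset trials of an `eeg_trialset`
#'
#' @param x an `eeg_trialset`.
#' @param i integer trial indices (1-based) or logical mask.
#' @param ... unused.
#' @return An `eeg_trialset` containing the selected trials.
#' @export
`[.eeg_trialset` <- function(x, i, ...) {
  eeg_trialset(
    data = x$data[i, , , drop = FALSE],
    labels = x$labels[i],
    subjects = x$subjects[i],
    channel_names = x$channel_names,
    fs = x$fs,
    eog = if (is.null(x$eog)) NULL else x$eog[i, , , drop = FALSE],
    window = x$window)
}

#' Number of trials
#' @param ds an `eeg_trialset`.
#' @return Integer trial count.
#' @export
n_trials <- function(ds) dim(ds$data)[1]

#' Concatenate trial sets
#'
#' Binds the trials of several `eeg_trialset` objects sharing channel
#' geometry, sampling rate and window.
#'
#' @param ... `eeg_trialset` objects.
#' @return The combined `eeg_trialset`.
#' @export
bind_trialsets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "eeg_trialset")) {
    sets <- sets[[1]]
  }
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(dim(s$data)[2:3], dim(ref$data)[2:3]) ||
        s$fs != ref$fs || !identical(s$window, ref$window)) {
      stop("trial sets have incompatible geometry")
    }
  }
  has_eog <- all(vapply(sets, function(s) !is.null(s$eog), logical(1)))
  comb <- function(get) do.call(abind3, lapply(sets, get))
  eeg_trialset(
    data = comb(function(s) s$data),
    labels = unlist(lapply(sets, function(s) s$labels)),
    subjects = unlist(lapply(sets, function(s) s$subjects)),
    channel_names = ref$channel_names, fs = ref$fs,
    eog = if (has_eog) comb(function(s) s$eog) else NULL,
    window = ref$window)
}

# rbind for 3-d arrays along the first (trial) axis
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1]
    if (k > 0) out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}

#' Write / read a trial-set bundle
#'
#' Serializes an `eeg_trialset` as a single compressed file of named arrays
#' (`data`, `labels`, `subjects`, `channel_names`, `fs`, `eog`, `window`),
#' the package's dataset exchange format.
#'
#' @param ds an `eeg_trialset`.
#' @param path file path for the bundle.
#' @return `write_trialset` returns `path` invisibly; `read_trialset`
#'   returns the reconstructed `eeg_trialset`.
#' @export
write_trialset <- function(ds, path) {
  stopifnot(inherits(ds, "eeg_trialset"))
  saveRDS(list(data = ds$data, labels = ds$labels, subjects = ds$subjects,
               channel_names = ds$channel_names, fs = ds$fs, eog = ds$eog,
               window = ds$window),
          path)
  invisible(path)
}

#' @rdname write_trialset
#' @export
read_trialset <- function(path) {
  b <- readRDS(path)
  eeg_trialset(b$data, b$labels, b$subjects, b$channel_names, b$fs,
               b$eog, b$window)
}
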