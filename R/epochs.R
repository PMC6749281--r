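#' Construct an epoch set
#'
#' An `epoch_set` is the unit every other function in the package operates
#' on: a 3-d array of pre-cut EEG trials (`trials x channels x samples`, in
#' microvolts), a binary label vector and the sampling rate.  Both classes
#' must be present and every trial must share the same channel count, sample
#' count and sampling rate.
#'
#' @param data numeric array `trials x channels x samples`, finite.
#' @param labels integer vector of length `trials` with values in `{1, 2}`;
#'   may be `NULL` for unlabelled epochs passed to [predict.fbcsp()].
#' @param fs sampling rate in Hz.
#' @param channel_names optional character vector of channel names; defaults
#'   to `ch01, ch02, ...`.
#' @return an object of class `epoch_set` (a list with elements `data`,
#'   `labels`, `fs`, `channel_names`).
#' @examples
#' x <- array(rnorm(10 * 3 * 50), c(10, 3, 50))
#' es <- epoch_set(x, labels = rep(1:2, each = 5), fs = 100)
#' es
#' @export
epoch_set <- function(data, labels = NULL, fs, channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-d array (trials x channels x samples)")
  if (!all(is.finite(data)))
    stop("epoch data contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number")
  dm <- dim(data)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != dm[1L])
      stop("length(labels) must equal the number of trials (", dm[1L], ")")
    if (!all(labels %in% c(1L, 2L)))
      stop("labels must take values in {1, 2}")
    if (length(unique(labels)) != 2L)
      stop("both classes must be present")
  }
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(dm[2L]))
  if (length(channel_names) != dm[2L])
    stop("length(channel_names) must equal the number of channels")
  structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         channel_names = as.character(channel_names)),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  dm <- dim(x$data)
  cat("<epoch_set> ", dm[1L], " trials x ", dm[2L], " channels x ",
      dm[3L], " samples @ ", x$fs, " Hz\n", sep = "")
  if (is.null(x$labels)) {
    cat("  unlabelled\n")
  } else {
    cat("  labels: class 1 n=", sum(x$labels == 1L),
        ", class 2 n=", sum(x$labels == 2L), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_trials   <- function(es) dim(es$data)[1L]
n_channels <- function(es) dim(es$data)[2L]
n_samples  <- function(es) dim(es$data)[3L]

# index subsets used throughout: trials (i) and/or channels (k)
subset_epochs <- function(es, trials = NULL, channels = NULL) {
  i <- if (is.null(trials)) seq_len(n_trials(es)) else trials
  k <- if (is.null(channels)) seq_len(n_channels(es)) else channels
  epoch_set(es$data[i, k, , drop = FALSE],
            labels = if (is.null(es$labels)) NULL else {
              lab <- es$labels[i]
              if (length(unique(lab)) == 2L) lab else NULL
            },
            fs = es$fs, channel_names = es$channel_names[k])
}

# trial i as a channels x samples matrix
trial_matrix <- function(es, i) {
  matrix(es$data[i, , ], nrow = n_channels(es), ncol = n_samples(es))
}

class_indices <- function(labels) {
  list(which(labels == 1L), which(labels == 2L))
}

#' Cut epochs out of a continuous multichannel recording
#'
#' Extracts one fixed-length epoch per cue.  The window `[t0, t1)` is
#' interpreted relative to each cue time, with 0-based half-open sample
#' indexing: an epoch holds samples `round((cue + t0) * fs)` up to (but not
#' including) that start plus `round((t1 - t0) * fs)`.  The conventional
#' motor-imagery window is 0.5-2.5 s after the visual cue.
#'
#' @param continuous numeric matrix `channels x time` (a continuous
#'   recording), or the list returned by [read_edf()].
#' @param cue_times numeric vector of cue onsets in seconds.
#' @param window length-2 numeric `c(t0, t1)` in seconds relative to cue,
#'   `t0 < t1`.
#' @param fs sampling rate in Hz (taken from `continuous$fs` when an EDF
#'   recording is given).
#' @param labels optional class labels, one per cue.
#' @param channel_names optional channel names.
#' @return an [epoch_set()] with `round((t1 - t0) * fs)` samples per trial.
#' @examples
#' rec <- matrix(rnorm(2 * 1000), 2)  # 2 channels, 10 s at 100 Hz
#' es <- extract_epochs(rec, cue_times = c(1, 4, 7), window = c(0.5, 2.5),
#'                      fs = 100, labels = c(1, 2, 1))
#' dim(es)   # 3 trials x 2 channels x 200 samples
#' @export
extract_epochs <- function(continuous, cue_times, window, fs = NULL,
                           labels = NULL, channel_names = NULL) {
  if (is.list(continuous) && !is.null(continuous$signals)) {
    if (is.null(fs)) fs <- continuous$fs
    if (is.null(channel_names)) channel_names <- continuous$channel_names
    continuous <- continuous$signals
  }
  if (is.null(fs)) stop("'fs' is required when 'continuous' is a matrix")
  if (!is.matrix(continuous)) stop("'continuous' must be a channels x time matrix")
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("'window' must be c(t0, t1) with t0 < t1")
  n_time <- ncol(continuous)
  n_win <- round((window[2L] - window[1L]) * fs)
  if (n_win < 1L) stop("window shorter than one sample at fs = ", fs)
  starts <- round((cue_times + window[1L]) * fs)  # 0-based
  bad <- which(starts < 0L | starts + n_win > n_time)
  if (length(bad))
    stop("epoch window exceeds the recording for cue at t = ",
         cue_times[bad[1L]], " s (samples ", starts[bad[1L]], "..",
         starts[bad[1L]] + n_win - 1L, " of ", n_time, ")")
  K <- nrow(continuous)
  out <- array(NA_real_, c(length(cue_times), K, n_win))
  for (i in seq_along(cue_times))
    out[i, , ] <- continuous[, (starts[i] + 1L):(starts[i] + n_win), drop = FALSE]
  epoch_set(out, labels = labels, fs = fs, channel_names = channel_names)
}
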