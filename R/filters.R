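#' Band specification and filter banks
#'
#' `band_spec()` describes one Butterworth bandpass (passband edges in Hz and
#' even filter order); `filter_bank()` bundles an ordered list of bands;
#' `default_filterbank()` returns the standard motor-imagery bank of eight
#' contiguous 4-Hz bands spanning 4-36 Hz.
#'
#' @param low_hz,high_hz passband edges in Hz, `0 < low_hz < high_hz`.
#' @param order filter order; even and at least 2.  The default (4) matches
#'   the fourth-order Butterworth broadband filter used for the time-domain
#'   parameter path.
#' @return `band_spec()`: an object of class `band_spec`; `filter_bank()`
#'   and `default_filterbank()`: an object of class `filter_bank` (a list of
#'   `band_spec`).
#' @examples
#' default_filterbank()
#' band_spec(0.5, 40)   # the broadband filter for the TDP/correlation path
#' @export
band_spec <- function(low_hz, high_hz, order = 4L) {
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      low_hz <= 0 || high_hz <= low_hz)
    stop("need 0 < low_hz < high_hz")
  order <- as.integer(order)
  if (order < 2L || order %% 2L != 0L)
    stop("'order' must be an even integer >= 2")
  structure(list(low_hz = as.numeric(low_hz), high_hz = as.numeric(high_hz),
                 order = order),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat("<band_spec> ", x$low_hz, "-", x$high_hz, " Hz, Butterworth order ",
      x$order, "\n", sep = "")
  invisible(x)
}

#' @rdname band_spec
#' @param bands a list of `band_spec` objects (at least 2 for a bank).
#' @export
filter_bank <- function(bands) {
  if (!is.list(bands) || length(bands) < 2L)
    stop("a filter bank needs at least 2 bands")
  if (!all(vapply(bands, inherits, logical(1), "band_spec")))
    stop("all elements must be band_spec objects")
  structure(bands, class = "filter_bank")
}

#' @rdname band_spec
#' @export
default_filterbank <- function() {
  edges <- seq(4, 36, by = 4)
  filter_bank(lapply(seq_len(8L), function(m)
    band_spec(edges[m], edges[m + 1L], order = 4L)))
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("<filter_bank> M =", length(x), "bands:",
      paste(vapply(x, function(b) paste0("[", b$low_hz, ",", b$high_hz, "]"),
                   character(1)), collapse = " "), "Hz\n")
  invisible(x)
}

# ---- zero-phase IIR application ------------------------------------------
#
# The filter is designed with signal::butter; the application below is a
# matrix-vectorized forward-backward pass (columns = independent signals)
# with odd-reflection edge padding and steady-state initial conditions, so
# a whole epoch set is filtered in one call.

butter_coefs <- function(band, fs) {
  nyq <- fs / 2
  if (!(band$low_hz > 0 && band$high_hz < nyq))
    stop("band [", band$low_hz, ",", band$high_hz,
         "] Hz is invalid for fs = ", fs, " Hz (Nyquist ", nyq, " Hz)")
  bf <- signal::butter(band$order / 2L, c(band$low_hz, band$high_hz) / nyq,
                       type = "pass")
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

# steady-state state vector of the direct-form-II-transposed filter for a
# unit-step input; multiplied by x[1] it removes the start-up transient
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  A <- matrix(0, n - 1L, n - 1L)
  A[, 1L] <- -a[-1L]
  if (n > 2L) A[cbind(seq_len(n - 2L), seq_len(n - 2L) + 1L)] <- 1
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - A, B)
}

# causal IIR filter on each column of X (direct form II transposed);
# zi: (n-1) x ncol matrix of initial states, or NULL for zero state
lfilter_mat <- function(b, a, X, zi = NULL) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  N <- nrow(X); C <- ncol(X)
  Y <- matrix(0, N, C)
  Z <- if (is.null(zi)) matrix(0, n - 1L, C) else zi
  for (t in seq_len(N)) {
    xt <- X[t, ]
    yt <- b[1L] * xt + Z[1L, ]
    if (n > 2L) {
      Z[seq_len(n - 2L), ] <- Z[seq_len(n - 2L) + 1L, , drop = FALSE] +
        outer(b[2L:(n - 1L)], xt) - outer(a[2L:(n - 1L)], yt)
    }
    Z[n - 1L, ] <- b[n] * xt - a[n] * yt
    Y[t, ] <- yt
  }
  Y
}

# zero-phase (forward-backward) filtering of each column of X
filtfilt_mat <- function(b, a, X) {
  N <- nrow(X)
  ntaps <- max(length(a), length(b))
  pad <- 3L * (ntaps - 1L)
  if (N <= pad + 1L)
    stop("signal too short for stable zero-phase filtering (need > ",
         pad + 1L, " samples, got ", N, ")")
  zi <- lfilter_zi(b, a)
  # odd reflection about the end points
  front <- 2 * X[rep(1L, pad), , drop = FALSE] - X[(pad + 1L):2L, , drop = FALSE]
  back  <- 2 * X[rep(N, pad), , drop = FALSE] - X[(N - 1L):(N - pad), , drop = FALSE]
  ext <- rbind(front, X, back)
  y <- lfilter_mat(b, a, ext, zi = outer(zi, ext[1L, ]))
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- lfilter_mat(b, a, y, zi = outer(zi, y[1L, ]))
  y <- y[nrow(y):1L, , drop = FALSE]
  y[(pad + 1L):(pad + N), , drop = FALSE]
}

#' Zero-phase Butterworth bandpass of an epoch set
#'
#' Filters every trial and channel independently with the Butterworth
#' bandpass described by `band`, applied forward and backward so the output
#' has no group delay (important for 2-s epochs).  Epochs shorter than three
#' filter lengths are rejected rather than padded.
#'
#' @param epoch_set an [epoch_set()].
#' @param band a [band_spec()]; both edges must lie below the Nyquist
#'   frequency `fs/2`.
#' @return a new `epoch_set` of identical shape.
#' @examples
#' es <- simulate_session(synth_config(trials_per_class = 5))$epochs
#' mu <- bandpass(es, band_spec(8, 12))
#' @export
bandpass <- function(epoch_set, band) {
  stopifnot(inherits(epoch_set, "epoch_set"), inherits(band, "band_spec"))
  co <- butter_coefs(band, epoch_set$fs)
  dm <- dim(epoch_set$data)
  # samples x (trial*channel) columns
  X <- t(matrix(epoch_set$data, nrow = dm[1L] * dm[2L], ncol = dm[3L]))
  Y <- filtfilt_mat(co$b, co$a, X)
  out <- epoch_set
  out$data <- array(t(Y), dm)
  out
}

# filter a channels x samples matrix (single trial) with a designed filter
filtfilt_trial <- function(co, X) {
  t(filtfilt_mat(co$b, co$a, t(X)))
}
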