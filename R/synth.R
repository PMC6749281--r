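#' Configuration for the synthetic ERD session generator
#'
#' Describes a two-class motor-imagery-like session: every source channel
#' carries 1/f background activity plus a band-limited stochastic
#' oscillation (mu rhythm by default); on the designated ERD channels the
#' oscillation's variance is reduced by `erd_depth` in class-1 trials
#' (event-related desynchronization).  Sources are linearly mixed across
#' channels to emulate volume conduction, and white sensor noise is added.
#' The defaults are the "easy preset": 18 channels, 100 trials per class,
#' 2-s epochs at 100 Hz, ERD of depth 0.6 at 8-12 Hz on channel 9.
#'
#' @param K number of channels.
#' @param trials_per_class trials per class (labels are balanced).
#' @param N samples per trial.
#' @param fs sampling rate, Hz.
#' @param erd_channels source indices carrying the class-dependent ERD;
#'   defaults to the middle channel (`ceiling(K / 2)`, channel 9 of the
#'   easy preset).
#' @param erd_band oscillation passband `c(low, high)` in Hz.
#' @param erd_depth fractional band-power reduction in class 1, in (0, 1).
#' @param mixing `"default"` for the exponential-falloff volume-conduction
#'   matrix `exp(-|a-b|/2)` (row-normalized), or a user `K x K` invertible
#'   matrix.
#' @param osc_sd oscillation amplitude (standard deviation) at the ERD
#'   sources, before class modulation.
#' @param osc_sd_other oscillation amplitude on the remaining sources: the
#'   mu rhythm is focal over sensorimotor cortex, so background sites carry
#'   a weaker rhythm.
#' @param background_sd 1/f background amplitude at the source.
#' @param noise_sd white sensor-noise amplitude added after mixing.
#' @param seed integer seed; the session is fully determined by it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(K = 18L, trials_per_class = 100L, N = 200L,
                         fs = 100, erd_channels = ceiling(K / 2),
                         erd_band = c(8, 12),
                         erd_depth = 0.6, mixing = "default",
                         osc_sd = 1, osc_sd_other = 0.2,
                         background_sd = 0.5, noise_sd = 0.1,
                         seed = 1L) {
  if (erd_depth <= 0 || erd_depth >= 1) stop("'erd_depth' must lie in (0, 1)")
  if (any(erd_channels < 1L) || any(erd_channels > K))
    stop("'erd_channels' out of range 1..K")
  if (is.matrix(mixing)) {
    if (!all(dim(mixing) == c(K, K))) stop("'mixing' must be K x K")
    if (qr(mixing)$rank < K) stop("'mixing' matrix is singular")
  } else if (!identical(mixing, "default")) {
    stop("'mixing' must be \"default\" or a K x K matrix")
  }
  structure(list(K = as.integer(K),
                 trials_per_class = as.integer(trials_per_class),
                 N = as.integer(N), fs = fs,
                 erd_channels = as.integer(erd_channels),
                 erd_band = erd_band, erd_depth = erd_depth,
                 mixing = mixing, osc_sd = osc_sd,
                 osc_sd_other = osc_sd_other,
                 background_sd = background_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Default volume-conduction mixing matrix
#'
#' Exponential falloff by channel-index distance, `exp(-|a - b| / 2)`, rows
#' normalized to sum 1: diagonally dominant, so each output channel is
#' dominated by its own source but smeared towards its neighbours, the way
#' scalp EEG smears cortical sources.
#'
#' @param K number of channels.
#' @param falloff e-folding distance in channel indices (default 2).
#' @return a `K x K` matrix.
#' @export
default_mixing <- function(K, falloff = 2) {
  W <- exp(-abs(outer(seq_len(K), seq_len(K), "-")) / falloff)
  W / rowSums(W)
}

# 1/f-amplitude noise via spectral shaping of white noise (columns of X)
pink_noise <- function(N, ncols) {
  X <- matrix(stats::rnorm(N * ncols), N, ncols)
  f <- c(1, seq_len(N - 1L))                 # avoid the DC singularity
  shape <- 1 / sqrt(pmin(f, N - f + 1))      # symmetric in the FFT bins
  Y <- Re(stats::mvfft(stats::mvfft(X) * shape, inverse = TRUE)) / N
  Y / stats::sd(Y)
}

#' Generate a synthetic two-class ERD session
#'
#' Draws a seeded session from the generative model described in
#' [synth_config()] and returns both the observable epochs and the ground
#' truth needed for recovery scoring: which channels truly carry the ERD,
#' the mixing matrix, the per-trial realized oscillation band powers, and
#' the output channels where each ERD source lands most strongly.
#'
#' @param config a [synth_config()].
#' @return a list of class `synth_session`: `epochs` (an [epoch_set()]),
#'   `truth` (list: `erd_channels`, `mixing`, `band_power`
#'   (trials x ERD-sources matrix), `dominant_outputs`), and `config`.
#' @examples
#' ses <- simulate_session(synth_config(trials_per_class = 10, seed = 42))
#' ses$epochs
#' ses$truth$dominant_outputs
#' @export
simulate_session <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  K <- config$K; N <- config$N; tpc <- config$trials_per_class
  ntr <- 2L * tpc
  W <- if (is.matrix(config$mixing)) config$mixing else default_mixing(K)
  labels <- sample(rep(1:2, tpc))

  # sources, laid out as N x (K * ntr): column (t-1)*K + k is source k of trial t
  bg <- pink_noise(N, K * ntr) * config$background_sd
  co <- butter_coefs(band_spec(config$erd_band[1L], config$erd_band[2L]),
                     config$fs)
  osc <- filtfilt_mat(co$b, co$a, matrix(stats::rnorm(N * K * ntr), N))
  # each source oscillation is normalized to its exact target variance per
  # trial: the class effect is a power modulation, so realized band power
  # (not just its expectation) carries the ERD
  target_sd <- rep(config$osc_sd_other, K)
  target_sd[config$erd_channels] <- config$osc_sd
  osc <- sweep(osc, 2L, rep(target_sd, ntr) / sqrt(colvar_pop(osc)), "*")
  # ERD: shrink the oscillation on the ERD sources in class-1 trials
  shrink <- sqrt(1 - config$erd_depth)
  erd_cols <- as.vector(outer(config$erd_channels,
                              (which(labels == 1L) - 1L) * K, "+"))
  osc[, erd_cols] <- osc[, erd_cols] * shrink

  # realized per-trial oscillation band power on the ERD sources
  all_erd_cols <- as.vector(outer(config$erd_channels,
                                  (seq_len(ntr) - 1L) * K, "+"))
  bp <- matrix(colvar_pop(osc[, all_erd_cols, drop = FALSE]),
               nrow = ntr, byrow = TRUE)

  S <- bg + osc                               # N x (K*ntr)
  # mix within each trial: reshape to K x (N*ntr), one multiply
  Sk <- matrix(aperm(array(S, c(N, K, ntr)), c(2L, 1L, 3L)), nrow = K)
  X <- W %*% Sk + config$noise_sd * matrix(stats::rnorm(K * N * ntr), K)
  data <- aperm(array(X, c(K, N, ntr)), c(3L, 1L, 2L))

  epochs <- epoch_set(data, labels = labels, fs = config$fs)
  truth <- list(erd_channels = config$erd_channels, mixing = W,
                band_power = bp,
                dominant_outputs = vapply(config$erd_channels,
                                          function(k) which.max(W[, k]),
                                          integer(1)))
  structure(list(epochs = epochs, truth = truth, config = config),
            class = "synth_session")
}

#' @export
print.synth_session <- function(x, ...) {
  cat("<synth_session> seed", x$config$seed, "| ERD depth",
      x$config$erd_depth, "in", x$config$erd_band[1L], "-",
      x$config$erd_band[2L], "Hz on source(s)",
      paste(x$truth$erd_channels, collapse = " "), "\n")
  print(x$epochs)
  invisible(x)
}
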