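# shared fixture builders; every fixture is generated in code

# small synthetic session for fast module tests
tiny_session <- function(seed = 1, K = 8, tpc = 20, ...) {
  simulate_session(synth_config(K = K, trials_per_class = tpc, seed = seed, ...))
}

# epochs holding a pure sinusoid on every trial/channel
sinusoid_epochs <- function(freq, fs = 100, N = 500, trials = 4, channels = 2,
                            amplitude = 1) {
  t <- (seq_len(N) - 1) / fs
  x <- amplitude * sin(2 * pi * freq * t)
  data <- array(rep(x, each = trials * channels), c(trials, channels, N))
  epoch_set(data, labels = rep(1:2, length.out = trials), fs = fs)
}

# random symmetric positive-definite matrix
random_psd <- function(d, jitter = 0.1) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) + jitter * diag(d)
}

# squared amplitude response of a designed bandpass at frequency f
# (forward-backward filtering applies |H|^2)
filtfilt_gain <- function(band, fs, f) {
  co <- fbcsp:::butter_coefs(band, fs)
  z <- exp(-1i * 2 * pi * f / fs)
  H <- sum(co$b * z^(0:(length(co$b) - 1))) /
       sum(co$a * z^(0:(length(co$a) - 1)))
  Mod(H)^2
}

rms <- function(x) sqrt(mean(x^2))
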