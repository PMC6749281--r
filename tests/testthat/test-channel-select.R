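# independent oracle: differences, population variance, natural log
oracle_tdp <- function(x, p) {
  d <- x
  for (j in seq_len(p)) d <- d[-1] - d[-length(d)]
  v <- mean((d - mean(d))^2)
  log(max(v, 1e-12))
}

test_that("tdp matches an independently coded oracle", {
  expect_equal(tdp(rep(c(1, -1), 10), p = 0), 0)             # unit variance
  expect_equal(tdp(0:49, p = 1), log(1e-12))                 # floored
  x <- c(0.5, -1.2, 0.3, 2.0, -0.7)
  for (p in 0:2) expect_equal(tdp(x, p), oracle_tdp(x, p), tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:20) {
    y <- rnorm(sample(10:50, 1))
    p <- sample(0:2, 1)
    expect_equal(tdp(y, p), oracle_tdp(y, p), tolerance = 1e-12)
  }
  expect_error(tdp(c(1, 2), p = 1), "too short")
})

test_that("tdp_matrix agrees with per-signal tdp", {
  ses <- tiny_session(seed = 2, K = 3, tpc = 3)
  tm <- tdp_matrix(ses$epochs)
  for (i in 1:6) for (k in 1:3) for (p in 0:2)
    expect_equal(tm[i, k, p + 1], tdp(ses$epochs$data[i, k, ], p),
                 tolerance = 1e-12)
})

test_that("fisher ratio obeys its algebraic identities", {
  # toy with a hand-computable value: class means 1 vs 11, within-class
  # population variance 1 per class per type -> 3*(10^2) / (3*2) = 50
  tdps <- array(NA_real_, c(4, 1, 3))
  for (p in 1:3) tdps[, 1, p] <- c(0, 2, 10, 12)
  labels <- c(1, 1, 2, 2)
  expect_equal(fisher_ratio(tdps, labels, 1), 50, tolerance = 1e-12)

  # identical class distributions -> 0
  tdps0 <- array(rep(c(1, 2, 1, 2), 3), c(4, 1, 3))
  expect_equal(fisher_ratio(tdps0, labels, 1), 0)

  # shift invariance: add a per-type constant
  shifted <- tdps
  for (p in 1:3) shifted[, 1, p] <- shifted[, 1, p] + p * 7
  expect_equal(fisher_ratio(shifted, labels, 1), fisher_ratio(tdps, labels, 1),
               tolerance = 1e-12)

  # scaling: numerator and denominator both scale by a^2
  scaled <- tdps * 3.7
  expect_equal(fisher_ratio(scaled, labels, 1), fisher_ratio(tdps, labels, 1),
               tolerance = 1e-12)

  # degenerate channel: all TDPs constant within both classes
  flat <- array(5, c(4, 1, 3))
  expect_error(fisher_ratio(flat, labels, 1), "degenerate")
})

test_that("principle channel selection finds the discriminative channel", {
  set.seed(3)
  # channel 1: variance shift between classes; channel 2: same for both
  I <- 40; N <- 100
  data <- array(rnorm(I * 2 * N), c(I, 2, N))
  labels <- rep(1:2, each = I / 2)
  data[labels == 2, 1, ] <- data[labels == 2, 1, ] * 3
  es <- epoch_set(data, labels = labels, fs = 100)
  sel <- select_principle_channel(es)
  expect_equal(sel$principle, 1L)
  expect_length(sel$fisher, 2L)

  # identical channels tie -> lowest index
  data2 <- array(rnorm(I * N), c(I, 1, N))[, c(1, 1, 1), ]
  dim(data2) <- c(I, 3, N)
  es2 <- epoch_set(data2, labels = labels, fs = 100)
  expect_equal(select_principle_channel(es2)$principle, 1L)
})

test_that("pearson equals the textbook formula and is affine-invariant", {
  expect_equal(pearson(1:10, 1:10), 1)
  expect_equal(pearson(1:10, -(1:10)), -1)

  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), oracle, tolerance = 1e-12)

  set.seed(9)
  for (rep in 1:50) {
    a <- rnorm(30); b <- rnorm(30)
    expect_equal(pearson(a, b), cor(a, b), tolerance = 1e-12)
    expect_equal(pearson(2.5 * a + 3, b), pearson(a, b), tolerance = 1e-10)
    expect_equal(pearson(-a, b), -pearson(a, b), tolerance = 1e-12)
  }
  expect_error(pearson(rep(1, 5), rnorm(5)), "constant")
})

test_that("supporting set follows the class-mean correlation rule", {
  set.seed(21)
  I <- 20; N <- 200
  base <- matrix(rnorm(I * N), I, N)
  data <- array(NA_real_, c(I, 4, N))
  data[, 1, ] <- base
  data[, 2, ] <- 2 * base + 0.05 * rnorm(I * N)   # scaled copy
  data[, 3, ] <- 0.5 * base + 0.05 * rnorm(I * N) # scaled copy
  data[, 4, ] <- rnorm(I * N)                     # independent
  labels <- rep(1:2, each = I / 2)
  es <- epoch_set(data, labels = labels, fs = 100)

  cs <- supporting_set(es, principle = 1, threshold = 0.6)
  expect_identical(cs$support, c(1L, 2L, 3L))

  # independent direct evaluation of the class-mean correlation rule
  for (q in 2:4) {
    rho_i <- sapply(seq_len(I), function(i) cor(data[i, 1, ], data[i, q, ]))
    m1 <- mean(rho_i[labels == 1]); m2 <- mean(rho_i[labels == 2])
    expect_equal(unname(cs$mean_corr[q, 1]), m1, tolerance = 1e-10)
    expect_equal(unname(cs$mean_corr[q, 2]), m2, tolerance = 1e-10)
    expect_equal(q %in% cs$support, m1 >= 0.6 && m2 >= 0.6)
  }

  # permissive threshold keeps everything positively correlated
  cs_all <- supporting_set(es, principle = 1, threshold = 1e-6)
  expect_true(all(c(1, 2, 3) %in% cs_all$support))

  # threshold 1 with noisy channels collapses the set
  expect_error(supporting_set(es, principle = 4, threshold = 1),
               "lower the threshold")
  expect_error(supporting_set(es, principle = 1, threshold = 1.2), "\\(0, 1]")
})

test_that("supporting set shrinks monotonically in the threshold", {
  for (seed in 1:3) {
    ses <- tiny_session(seed = seed, K = 10, tpc = 15)
    bb <- bandpass(ses$epochs, band_spec(0.5, 40))
    sel <- select_principle_channel(bb)
    prev <- NULL
    for (thr in c(0.3, 0.5, 0.7, 0.9)) {
      s <- tryCatch(supporting_set(bb, sel$principle, thr)$support,
                    error = function(e) integer(0))
      if (!is.null(prev)) expect_true(all(s %in% prev))
      prev <- s
    }
  }
})
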