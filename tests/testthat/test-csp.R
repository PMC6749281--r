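test_that("normalized covariance has unit trace and matches the element oracle", {
  # orthogonal unit-norm rows: equal-power uncorrelated channels
  X <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  expect_equal(normalized_covariance(X), diag(2) / 2)

  set.seed(4)
  Y <- matrix(rnorm(3 * 50), 3, 50)
  E <- normalized_covariance(Y)
  expect_equal(sum(diag(E)), 1, tolerance = 1e-12)
  # brute-force elementwise sums
  raw <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) raw[a, b] <- sum(Y[a, ] * Y[b, ])
  expect_equal(E, raw / sum(diag(raw)), tolerance = 1e-12)

  expect_error(normalized_covariance(matrix(0, 2, 10)), "trace")
})

test_that("class-mean covariance is the arithmetic per-class mean", {
  A <- diag(c(0.7, 0.3)); B <- matrix(c(0.5, 0.1, 0.1, 0.5), 2)
  expect_equal(class_mean_covariance(list(A, B, A, A), c(1, 1, 2, 2))[[1]],
               (A + B) / 2)
  expect_equal(class_mean_covariance(list(A, B, A, A), c(1, 1, 2, 2))[[2]], A)

  set.seed(8)
  covs <- replicate(10, {
    E <- random_psd(3); E / sum(diag(E))
  }, simplify = FALSE)
  mns <- class_mean_covariance(covs, rep(1:2, 5))
  expect_equal(sum(diag(mns[[1]])), 1, tolerance = 1e-12)
  expect_equal(sum(diag(mns[[2]])), 1, tolerance = 1e-12)
  expect_error(class_mean_covariance(covs, rep(1, 10)), "non-empty")
})

test_that("solve_csp recovers the diagonal closed form and isotropic case", {
  pr <- solve_csp(diag(c(0.8, 0.2)), diag(c(0.2, 0.8)))
  expect_equal(pr$j_max, 4, tolerance = 1e-12)
  expect_equal(pr$j_min, 0.25, tolerance = 1e-12)
  expect_equal(abs(pr$p_max) / max(abs(pr$p_max)), c(1, 0), tolerance = 1e-8)
  expect_equal(abs(pr$p_min) / max(abs(pr$p_min)), c(0, 1), tolerance = 1e-8)

  iso <- solve_csp(diag(3) / 3, diag(3) / 3)
  expect_equal(iso$j_max, 1, tolerance = 1e-12)
  expect_equal(iso$j_min, 1, tolerance = 1e-12)

  expect_error(solve_csp(diag(2), diag(3)), "equal size")
  expect_error(solve_csp(matrix(c(1, 2, 0, 1), 2), diag(2)), "symmetric")
})

test_that("solved filters bound the variance ratio over random directions", {
  set.seed(12)
  for (rep in 1:5) {
    d <- sample(2:5, 1)
    E1 <- random_psd(d); E2 <- random_psd(d)
    pr <- solve_csp(E1, E2)
    P <- matrix(rnorm(1e4 * d), ncol = d)
    J <- rowSums((P %*% E1) * P) / rowSums((P %*% E2) * P)
    expect_gte(pr$j_max, max(J) - 1e-9)
    expect_lte(pr$j_min, min(J) + 1e-9)
    # generalized eigen identity for both extremes
    r1 <- E1 %*% pr$p_max - pr$j_max * E2 %*% pr$p_max
    r2 <- E1 %*% pr$p_min - pr$j_min * E2 %*% pr$p_min
    expect_lt(max(abs(r1)) / max(abs(E1 %*% pr$p_max)), 1e-8)
    expect_lt(max(abs(r2)) / max(abs(E2 %*% pr$p_min)), 1e-8)
    # swapping the classes inverts the spectrum
    sw <- solve_csp(E2, E1)
    expect_equal(sw$j_max, 1 / pr$j_min, tolerance = 1e-9)
    expect_equal(sw$j_min, 1 / pr$j_max, tolerance = 1e-9)
  }
})

test_that("log-variance features follow the projection oracle", {
  set.seed(13)
  X <- matrix(rnorm(3 * 100), 3, 100)
  E1 <- random_psd(3); E2 <- random_psd(3)
  pr <- solve_csp(E1, E2)
  bf <- band_features(X, pr)
  # independent two-step oracle: project, then population log-variance
  for (side in c("p_max", "p_min")) {
    y <- as.numeric(pr[[side]] %*% X)
    v <- log(mean((y - mean(y))^2))
    got <- if (side == "p_max") bf$v_max else bf$v_min
    expect_equal(got, v, tolerance = 1e-12)
  }

  # unit-variance channel picked out by a basis filter
  Xu <- matrix(rnorm(2 * 400), 2, 400)
  Xu[1, ] <- (Xu[1, ] - mean(Xu[1, ])) / sqrt(mean((Xu[1, ] - mean(Xu[1, ]))^2))
  e1 <- structure(list(p_max = c(1, 0), p_min = c(0, 1), j_max = 1, j_min = 1,
                       band = 1L), class = "spatial_filter_pair")
  expect_equal(band_features(Xu, e1)$v_max, 0, tolerance = 1e-10)

  # scaling the trial by 2 raises both features by log 4
  bf2 <- band_features(2 * X, pr)
  expect_equal(bf2$v_max - bf$v_max, log(4), tolerance = 1e-10)
  expect_equal(bf2$v_min - bf$v_min, log(4), tolerance = 1e-10)

  # sign of the filter is irrelevant
  neg <- pr; neg$p_max <- -pr$p_max; neg$p_min <- -pr$p_min
  expect_equal(band_features(X, neg), band_features(X, pr), tolerance = 1e-12)

  expect_error(band_features(matrix(rnorm(8), 2), pr), "channels")
})
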