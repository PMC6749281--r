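# true mutual information of a balanced two-Gaussian mixture, by quadrature
gaussian_mixture_mi <- function(mu1, mu2, sd1 = 1, sd2 = 1) {
  integrand <- function(x) {
    f1 <- dnorm(x, mu1, sd1); f2 <- dnorm(x, mu2, sd2)
    f <- 0.5 * f1 + 0.5 * f2
    p1 <- ifelse(f > 0, 0.5 * f1 / f, 0.5)
    p2 <- 1 - p1
    h <- -(ifelse(p1 > 0, p1 * log2(p1), 0) + ifelse(p2 > 0, p2 * log2(p2), 0))
    f * h
  }
  lo <- min(mu1, mu2) - 8 * max(sd1, sd2)
  hi <- max(mu1, mu2) + 8 * max(sd1, sd2)
  1 - integrate(integrand, lo, hi, rel.tol = 1e-9)$value
}

test_that("mutual information behaves at the independence and separation limits", {
  set.seed(31)
  labels <- rep(1:2, each = 100)
  indep <- rnorm(200)
  expect_lte(mutual_information(indep, labels), 0.05)

  sep <- c(rnorm(100, -10), rnorm(100, 10))
  expect_gte(mutual_information(sep, labels), 0.95)

  expect_equal(mutual_information(rep(3.3, 200), labels), 0)
  expect_error(mutual_information(rnorm(200), rep(1, 200)), "non-empty")
})

test_that("mutual information approximates the quadrature oracle", {
  truth <- gaussian_mixture_mi(0, 3)
  set.seed(32)
  labels <- rep(1:2, each = 250)
  est <- mutual_information(c(rnorm(250, 0), rnorm(250, 3)), labels)
  expect_lt(abs(est - truth), 0.1)

  truth2 <- gaussian_mixture_mi(0, 5)
  est2 <- mutual_information(c(rnorm(250, 0), rnorm(250, 5)), labels)
  expect_lt(abs(est2 - truth2), 0.1)
})

test_that("mutual information is affine-invariant and bounded for binary labels", {
  set.seed(33)
  labels <- rep(1:2, each = 80)
  f <- c(rnorm(80, 0), rnorm(80, 1.5))
  base <- mutual_information(f, labels)
  expect_lt(abs(mutual_information(3 * f + 10, labels) - base), 0.02)
  expect_gte(base, 0)
  expect_lte(base, 1.05)
})

test_that("band selection picks the informative bands and is permutation-equivariant", {
  set.seed(34)
  I <- 60; labels <- rep(1:2, each = I / 2)
  noise_band <- function() cbind(rnorm(I), rnorm(I))
  info_band <- function() cbind(ifelse(labels == 1, -3, 3) + 0.3 * rnorm(I),
                                ifelse(labels == 1, 2, -2) + 0.3 * rnorm(I))

  pb <- replicate(6, noise_band(), simplify = FALSE)
  pb[[3]] <- info_band()
  sel <- select_bands(pb, labels)
  expect_equal(sel$bands[1], 3L)

  pb2 <- replicate(6, noise_band(), simplify = FALSE)
  pb2[[2]] <- info_band(); pb2[[5]] <- info_band()
  sel2 <- select_bands(pb2, labels)
  expect_setequal(sel2$bands, c(2L, 5L))

  # permuting band order permutes the selection
  perm <- c(4, 1, 6, 2, 5, 3)
  sel3 <- select_bands(pb2[perm], labels)
  expect_setequal(perm[sel3$bands], sel2$bands)
})

test_that("tied band scores break to the lower band index", {
  I <- 40; labels <- rep(1:2, each = I / 2)
  same <- cbind(ifelse(labels == 1, -1, 1), ifelse(labels == 1, 1, -1))
  sel <- select_bands(list(same, same, same), labels)
  expect_equal(sel$bands, c(1L, 2L))
})

test_that("assemble concatenates features in the contracted order", {
  pb <- list(list(v_max = 1, v_min = 2), list(v_max = 3, v_min = 4),
             list(v_max = 5, v_min = 6))
  expect_equal(assemble(c(1L, 3L), pb), c(1, 2, 5, 6))
  expect_equal(assemble(c(3L, 1L), pb), c(5, 6, 1, 2))  # follows pair order
  expect_error(assemble(c(2L, 2L), pb), "distinct")
  expect_error(assemble(c(1L, 4L), pb), "out of range")
})
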