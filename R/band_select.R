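#' Mutual information between a scalar feature and the class label
#'
#' Parzen-window estimate of `I(feature; class)` in bits for binary labels:
#' class-conditional densities are estimated with a Gaussian kernel and
#' Silverman's bandwidth on each class's training values, and the mutual
#' information is the label entropy minus the mean conditional entropy of
#' the posterior `P(class | feature)` evaluated at the sample points.
#' A constant feature carries no information and returns 0.
#'
#' @param feature_values numeric vector, one value per trial.
#' @param labels class labels in `{1, 2}`.
#' @return a scalar in bits, `>= 0` (clamped at 0 against small negative
#'   estimation noise).
#' @examples
#' set.seed(1)
#' f <- c(rnorm(50, -10), rnorm(50, 10))
#' mutual_information(f, rep(1:2, each = 50))   # ~1 bit
#' @export
mutual_information <- function(feature_values, labels) {
  labels <- as.integer(labels)
  idx <- class_indices(labels)
  if (!length(idx[[1L]]) || !length(idx[[2L]]))
    stop("both classes must be non-empty")
  I <- length(feature_values)
  if (I < 4L) stop("need at least 4 trials for a density estimate")
  if (max(feature_values) - min(feature_values) < .Machine$double.eps * 10)
    return(0)
  silverman <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) s <- .Machine$double.eps
    1.06 * s * length(x)^(-1/5)
  }
  dens <- function(x_train, h, at) {
    # mean Gaussian kernel over the class's training points
    sapply(at, function(v) mean(stats::dnorm(v, mean = x_train, sd = h)))
  }
  priors <- c(length(idx[[1L]]), length(idx[[2L]])) / I
  h1 <- silverman(feature_values[idx[[1L]]])
  h2 <- silverman(feature_values[idx[[2L]]])
  f1 <- dens(feature_values[idx[[1L]]], h1, feature_values)
  f2 <- dens(feature_values[idx[[2L]]], h2, feature_values)
  num <- cbind(priors[1L] * f1, priors[2L] * f2)
  tot <- rowSums(num)
  ok <- tot > 0
  post <- num[ok, , drop = FALSE] / tot[ok]
  # conditional label entropy given the feature, averaged over samples
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  h_cond <- -mean(rowSums(plogp(post)))
  h_class <- -sum(plogp(priors))
  max(h_class - h_cond, 0)
}

#' Select the two most informative filter-bank bands
#'
#' Scores each band by the summed mutual information of its two CSP
#' log-variance features with the class label, and returns the indices of
#' the two highest-scoring bands (`m1` the best; ties break to the lower
#' band index).
#'
#' @param per_band_features numeric array `M x trials x 2`
#'   (`[, , 1] = v_max`, `[, , 2] = v_min`), or a list of M `trials x 2`
#'   matrices.
#' @param labels class labels in `{1, 2}`.
#' @return a list with `bands = c(m1, m2)` and `scores` (length-M vector of
#'   band MI scores in bits).
#' @export
select_bands <- function(per_band_features, labels) {
  if (is.list(per_band_features)) {
    M <- length(per_band_features)
    scores <- vapply(per_band_features, function(fm)
      mutual_information(fm[, 1L], labels) +
      mutual_information(fm[, 2L], labels), numeric(1))
  } else {
    M <- dim(per_band_features)[1L]
    scores <- vapply(seq_len(M), function(m)
      mutual_information(per_band_features[m, , 1L], labels) +
      mutual_information(per_band_features[m, , 2L], labels), numeric(1))
  }
  if (M < 2L) stop("need at least 2 bands")
  ord <- order(-scores, seq_len(M))   # ties -> lower band index first
  list(bands = ord[1:2], scores = scores)
}

#' Assemble the final 4-dimensional feature vector
#'
#' Concatenates the two chosen bands' CSP features in the fixed order
#' `[v_max(m1), v_min(m1), v_max(m2), v_min(m2)]`.
#'
#' @param final_bands integer pair `c(m1, m2)`.
#' @param per_band list of per-band feature lists (each with `v_max`,
#'   `v_min`), indexed by band.
#' @return a numeric vector of length 4.
#' @export
assemble <- function(final_bands, per_band) {
  if (length(final_bands) != 2L || final_bands[1L] == final_bands[2L])
    stop("'final_bands' must be two distinct band indices")
  if (any(final_bands < 1L) || any(final_bands > length(per_band)))
    stop("band index out of range: ", paste(final_bands, collapse = ", "))
  v1 <- per_band[[final_bands[1L]]]
  v2 <- per_band[[final_bands[2L]]]
  if (is.null(v1) || is.null(v2)) stop("missing band features")
  c(v1$v_max, v1$v_min, v2$v_max, v2$v_min)
}
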