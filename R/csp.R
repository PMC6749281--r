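#' Trace-normalized sample covariance of one trial
#'
#' `X %*% t(X) / trace(X %*% t(X))`: the spatial covariance of a band-
#' filtered trial, normalized so trials with different overall power
#' contribute equally to the class mean.
#'
#' @param X numeric matrix `channels x samples`.
#' @return a symmetric positive semi-definite matrix with unit trace.
#' @export
normalized_covariance <- function(X) {
  if (!is.matrix(X) || !all(is.finite(X))) stop("'X' must be a finite matrix")
  C <- tcrossprod(X)
  tr <- sum(diag(C))
  if (tr <= 0) stop("all-zero trial: covariance trace is 0")
  C / tr
}

#' Class-mean covariance matrices
#'
#' Arithmetic mean of per-trial normalized covariances within each class.
#'
#' @param covs list of `|S| x |S|` per-trial covariance matrices.
#' @param labels class labels in `{1, 2}`, one per matrix.
#' @return a list of two matrices (class 1, class 2).
#' @export
class_mean_covariance <- function(covs, labels) {
  idx <- class_indices(labels)
  if (!length(idx[[1L]]) || !length(idx[[2L]]))
    stop("both classes must be non-empty")
  lapply(idx, function(i) Reduce(`+`, covs[i]) / length(i))
}

# condition-based ridge: stabilizes E2 when few trials / small |S| make it
# near rank-deficient
ridge_if_needed <- function(E2, tol = 1e10) {
  ev <- eigen(E2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > tol)
    E2 <- E2 + diag(1e-10 * sum(diag(E2)), nrow(E2))
  E2
}

# deterministic sign: first component of p with |p| > tol becomes positive
fix_sign <- function(p, tol = 1e-12) {
  nz <- which(abs(p) > tol)
  if (length(nz) && p[nz[1L]] < 0) -p else p
}

#' Common spatial pattern filter pair
#'
#' Finds the spatial filters that maximize and minimize the class variance
#' ratio `J(p) = (p' E1 p) / (p' E2 p)` over nonzero `p`.  Solved exactly as
#' the symmetric-definite generalized eigenproblem `E1 p = lambda E2 p` via
#' Cholesky whitening of `E2`: `j_max`/`j_min` are the extreme generalized
#' eigenvalues and `p_max`/`p_min` the corresponding eigenvectors.  A ridge
#' of `1e-10 * trace` is added to `E2`'s diagonal when its condition number
#' exceeds `1e10`.  Filter signs are fixed by making the first nonzero
#' component positive (features are sign-invariant).
#'
#' @param E1,E2 symmetric positive semi-definite matrices of equal size
#'   (class-mean covariances).
#' @param band optional band index carried along for bookkeeping.
#' @return an object of class `spatial_filter_pair` with `p_max`, `p_min`,
#'   `j_max`, `j_min`, `band`.
#' @examples
#' pr <- solve_csp(diag(c(0.8, 0.2)), diag(c(0.2, 0.8)))
#' pr$j_max   # 4: variance ratio attained along the first axis
#' @export
solve_csp <- function(E1, E2, band = NA_integer_) {
  if (!is.matrix(E1) || !is.matrix(E2) || !all(dim(E1) == dim(E2)))
    stop("'E1' and 'E2' must be matrices of equal size")
  if (max(abs(E1 - t(E1))) > 1e-8 * max(1, max(abs(E1))) ||
      max(abs(E2 - t(E2))) > 1e-8 * max(1, max(abs(E2))))
    stop("'E1' and 'E2' must be symmetric")
  E1 <- (E1 + t(E1)) / 2
  E2 <- ridge_if_needed((E2 + t(E2)) / 2)
  R <- tryCatch(chol(E2),
                error = function(e) stop("E2 is numerically singular ",
                                         "beyond the ridge tolerance"))
  Ri <- backsolve(R, diag(nrow(E2)))
  M <- crossprod(Ri, E1) %*% Ri      # t(Ri) E1 Ri, symmetric
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  p_max <- fix_sign(as.numeric(Ri %*% eg$vectors[, 1L]))
  p_min <- fix_sign(as.numeric(Ri %*% eg$vectors[, nrow(E2)]))
  structure(list(p_max = p_max, p_min = p_min,
                 j_max = eg$values[1L], j_min = eg$values[nrow(E2)],
                 band = band),
            class = "spatial_filter_pair")
}

#' @export
print.spatial_filter_pair <- function(x, ...) {
  cat("<spatial_filter_pair>",
      if (!is.na(x$band)) paste0("band ", x$band, " |") else "",
      "j_max =", format(x$j_max, digits = 4),
      "j_min =", format(x$j_min, digits = 4), "\n")
  invisible(x)
}

# variance ratio of one filter against a covariance pair
variance_ratio <- function(p, E1, E2) {
  as.numeric((t(p) %*% E1 %*% p) / (t(p) %*% E2 %*% p))
}

#' Per-band CSP log-variance features of one trial
#'
#' Projects the band-filtered trial onto the filter pair and takes the log
#' population variance of each projection: `v_max = log var(p_max' X)`,
#' `v_min = log var(p_min' X)` (natural log, variance floored at `1e-12`).
#'
#' @param X numeric matrix `|S| x samples` (band-filtered trial on the
#'   supporting set).
#' @param pair a [solve_csp()] result of matching dimension.
#' @return a list `v_max`, `v_min`, `band`.
#' @export
band_features <- function(X, pair) {
  if (!is.matrix(X) || nrow(X) != length(pair$p_max))
    stop("trial has ", nrow(X), " channels but the filter pair expects ",
         length(pair$p_max))
  lv <- function(p) {
    y <- as.numeric(p %*% X)
    log(max(sum((y - mean(y))^2) / length(y), VAR_FLOOR))
  }
  list(v_max = lv(pair$p_max), v_min = lv(pair$p_min), band = pair$band)
}
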