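#' Time-domain parameter (TDP) of a signal
#'
#' The type-`p` TDP is the natural log of the population variance of the
#' `p`-th discrete (forward) difference of the signal, for `p = 0, 1, 2` —
#' the log analogues of the Hjorth activity, mobility and complexity
#' descriptors.  The variance is normalized by the differenced length
#' (`1/(N - p)`) and floored at `1e-12` before the log so that constant or
#' linear channels yield a finite value instead of `-Inf`.
#'
#' @param signal numeric vector of samples.
#' @param p derivative order, 0, 1 or 2.
#' @return a scalar, `log(max(var_pop(diff(signal, differences = p)), 1e-12))`.
#' @examples
#' tdp(rep(c(1, -1), 50), p = 0)   # unit population variance -> 0
#' tdp(0:99, p = 1)                # constant first difference -> log(1e-12)
#' @export
tdp <- function(signal, p) {
  p <- as.integer(p)
  if (!p %in% 0:2) stop("'p' must be 0, 1 or 2")
  n <- length(signal) - p
  if (n < 2L) stop("signal too short for derivative order p = ", p)
  d <- if (p == 0L) signal else diff(signal, differences = p)
  v <- sum((d - mean(d))^2) / n
  log(max(v, 1e-12))
}

VAR_FLOOR <- 1e-12

# population variance along rows of an N x C matrix (per column), floored
colvar_pop <- function(X) {
  n <- nrow(X)
  v <- colSums(X^2) / n - (colSums(X) / n)^2
  pmax(v, 0)
}

#' TDP matrix of an epoch set
#'
#' Computes all three TDP types for every trial and channel.  Expects
#' broadband-filtered epochs (the 0.5-40 Hz path): TDPs and the Fisher ratio
#' are defined on the wide-band signal, not on filter-bank outputs.
#'
#' @param epoch_set an [epoch_set()].
#' @return a `trials x channels x 3` array of TDP values; type `p` is slice
#'   `p + 1`.
#' @export
tdp_matrix <- function(epoch_set) {
  dm <- dim(epoch_set$data)
  I <- dm[1L]; K <- dm[2L]; N <- dm[3L]
  out <- array(NA_real_, c(I, K, 3L))
  # samples x (trial*channel) layout once, difference in place
  X <- t(matrix(epoch_set$data, nrow = I * K, ncol = N))
  for (p in 0:2) {
    D <- if (p == 0L) X else X[-1L, , drop = FALSE] - X[-nrow(X), , drop = FALSE]
    if (p > 0L) X <- D
    out[, , p + 1L] <- matrix(log(pmax(colvar_pop(D), VAR_FLOOR)), I, K)
  }
  out
}

#' Fisher ratio of the three TDP types for one channel
#'
#' Between-class over within-class scatter of the channel's TDPs, summed
#' over the three types: numerator `sum_p (mean_1 - mean_2)^2`, denominator
#' `sum_p sum_c var_c` with population within-class variances.  Invariant to
#' adding a per-type constant and to common scaling of the TDPs.
#'
#' @param tdps `trials x channels x 3` array from [tdp_matrix()].
#' @param labels class labels in `{1, 2}`.
#' @param k channel index.
#' @return a non-negative scalar; errors if the channel is degenerate (all
#'   TDPs constant within both classes).
#' @export
fisher_ratio <- function(tdps, labels, k) {
  idx <- class_indices(labels)
  if (!length(idx[[1L]]) || !length(idx[[2L]]))
    stop("both classes must be non-empty")
  num <- 0; den <- 0
  for (p in 1:3) {
    t1 <- tdps[idx[[1L]], k, p]; t2 <- tdps[idx[[2L]], k, p]
    num <- num + (mean(t1) - mean(t2))^2
    den <- den + mean((t1 - mean(t1))^2) + mean((t2 - mean(t2))^2)
  }
  if (den == 0)
    stop("degenerate channel ", k, ": TDPs constant within both classes")
  num / den
}

#' Select the principle channel by TDP Fisher ratio
#'
#' Computes the Fisher ratio of every channel and returns the argmax — the
#' channel whose wide-band time-domain parameters separate the two classes
#' best.  Ties break to the lowest channel index.  A channel that is
#' degenerate (zero within-class TDP scatter) is dropped from contention
#' with a warning; if every channel is degenerate the error propagates.
#'
#' @param epoch_set a labelled, broadband-filtered [epoch_set()].
#' @return a list with `fisher` (length-K vector, `NA` for degenerate
#'   channels) and `principle` (the selected channel index).
#' @examples
#' ses <- simulate_session(synth_config(trials_per_class = 20))
#' bb <- bandpass(ses$epochs, band_spec(0.5, 40))
#' select_principle_channel(bb)$principle
#' @export
select_principle_channel <- function(epoch_set) {
  if (is.null(epoch_set$labels)) stop("epoch set must be labelled")
  tdps <- tdp_matrix(epoch_set)
  K <- n_channels(epoch_set)
  fisher <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    fisher[k] <- tryCatch(fisher_ratio(tdps, epoch_set$labels, k),
                          error = function(e) NA_real_)
  }
  if (all(is.na(fisher)))
    stop("all channels are degenerate: no principle channel can be selected")
  if (anyNA(fisher))
    warning("degenerate channel(s) excluded from principle-channel selection: ",
            paste(which(is.na(fisher)), collapse = ", "))
  principle <- which(fisher == max(fisher, na.rm = TRUE))[1L]
  list(fisher = fisher, principle = principle)
}

#' Pearson correlation via centered cross- and auto-sums
#'
#' The per-trial channel-similarity statistic: centered cross-sum over the
#' root product of centered auto-sums.  The sample-size normalization
#' cancels, so this equals the Pearson correlation coefficient.
#'
#' @param x,y numeric vectors of equal length `>= 2`, neither constant.
#' @return a scalar in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("'x' and 'y' must have equal length >= 2")
  cx <- x - mean(x); cy <- y - mean(y)
  px <- sum(cx^2); py <- sum(cy^2)
  if (px == 0 || py == 0)
    stop("constant input vector: correlation undefined")
  sum(cx * cy) / sqrt(px * py)
}

# correlations of channel q's trials with the principle channel, all trials
# at once: es$data is I x K x N
trial_correlations <- function(epoch_set, principle) {
  dm <- dim(epoch_set$data)
  I <- dm[1L]; K <- dm[2L]; N <- dm[3L]
  # center each trial/channel along samples
  X <- epoch_set$data
  mu <- rowMeans(matrix(X, I * K, N))
  Xc <- X - array(mu, dm)
  P <- matrix(rowSums(matrix(Xc^2, I * K, N)), I, K)   # auto-sums
  xp <- Xc[, principle, , drop = FALSE]                # I x 1 x N
  Cq <- matrix(0, I, K)
  for (q in seq_len(K))
    Cq[, q] <- rowSums(matrix(Xc[, q, ] * xp[, 1L, ], I, N))
  Cq / sqrt(P * P[, principle])
}

#' Supporting channel set from class-mean correlations
#'
#' For every channel `q`, per-trial Pearson correlations with the principle
#' channel are averaged within each class; `q` enters the supporting set S
#' when both class means reach the threshold (signed comparison, no absolute
#' value).  The principle channel itself always belongs to S (its
#' self-correlation is identically 1).  S is the channel subset handed to
#' the per-band CSP.
#'
#' @param epoch_set a labelled [epoch_set()] (broadband-filtered).
#' @param principle principle channel index (from
#'   [select_principle_channel()]).
#' @param threshold correlation threshold `rho_thr` in `(0, 1]`.
#' @param fisher optional Fisher-ratio vector to carry in the result.
#' @return an object of class `channel_selection`: `fisher`, `principle`,
#'   `mean_corr` (K x 2 matrix of class-mean correlations), `threshold`,
#'   `support` (ascending channel indices).  Errors when `|S| < 2`, with
#'   advice to lower the threshold.
#' @export
supporting_set <- function(epoch_set, principle, threshold, fisher = NULL) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]")
  if (is.null(epoch_set$labels)) stop("epoch set must be labelled")
  rho <- trial_correlations(epoch_set, principle)
  idx <- class_indices(epoch_set$labels)
  mean_corr <- cbind(colMeans(rho[idx[[1L]], , drop = FALSE]),
                     colMeans(rho[idx[[2L]], , drop = FALSE]))
  colnames(mean_corr) <- c("class1", "class2")
  keep <- mean_corr[, 1L] >= threshold & mean_corr[, 2L] >= threshold
  keep[principle] <- TRUE
  support <- sort(which(keep))
  if (length(support) < 2L)
    stop("supporting set has fewer than 2 channels at rho_thr = ", threshold,
         "; lower the threshold (CSP needs at least 2 channels)")
  structure(list(fisher = fisher, principle = principle,
                 mean_corr = mean_corr, threshold = threshold,
                 support = support),
            class = "channel_selection")
}

#' @export
print.channel_selection <- function(x, ...) {
  cat("<channel_selection> principle channel:", x$principle,
      "| rho_thr:", x$threshold,
      "| support (", length(x$support), "): ",
      paste(x$support, collapse = " "), "\n")
  invisible(x)
}
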