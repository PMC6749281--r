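#' Pipeline configuration
#'
#' Collects every tunable of the classification pipeline: epoching window,
#' broadband filter for the TDP/correlation path, the CSP filter bank, the
#' correlation-threshold grid searched by nested cross-validation, the CV
#' protocol and the margin parameter of the linear classifier.
#'
#' @param window epoch window `c(t0, t1)` in seconds after the cue
#'   (default 0.5-2.5 s).
#' @param broadband [band_spec()] for the TDP/correlation path (default
#'   fourth-order Butterworth 0.5-40 Hz).
#' @param filterbank a [filter_bank()]; default eight 4-Hz bands, 4-36 Hz.
#' @param rho_grid candidate correlation thresholds searched when no fixed
#'   threshold is given.
#' @param cv_folds,cv_repeats stratified cross-validation protocol
#'   (default 5 x 5).
#' @param cost margin parameter C of the linear maximum-margin classifier.
#' @param seed integer seed governing fold shuffling.
#' @return an object of class `fbcsp_config`.
#' @export
fbcsp_config <- function(window = c(0.5, 2.5),
                         broadband = band_spec(0.5, 40),
                         filterbank = default_filterbank(),
                         rho_grid = seq(0.6, 0.9, by = 0.05),
                         cv_folds = 5L, cv_repeats = 5L,
                         cost = 1, seed = 1L) {
  stopifnot(inherits(broadband, "band_spec"), inherits(filterbank, "filter_bank"))
  if (any(rho_grid <= 0 | rho_grid > 1)) stop("rho_grid values must lie in (0, 1]")
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  structure(list(window = window, broadband = broadband,
                 filterbank = filterbank, rho_grid = rho_grid,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 cost = cost, seed = as.integer(seed)),
            class = "fbcsp_config")
}

# ---- prepared session ----------------------------------------------------
#
# All label-free per-trial quantities, computed once so that repeated fits
# on trial subsets (cross-validation) do not refilter the data.  Everything
# here is a deterministic per-trial transform, so reusing it across folds
# leaks nothing: class labels enter only in fit_prepared().

prepare_session <- function(es, config) {
  bb <- bandpass(es, config$broadband)
  I <- n_trials(es); K <- n_channels(es); N <- n_samples(es)
  tdps <- tdp_matrix(bb)
  rho <- array(NA_real_, c(I, K, K))
  for (i in seq_len(I))
    rho[i, , ] <- stats::cor(t(trial_matrix(bb, i)))
  M <- length(config$filterbank)
  G <- vector("list", M); mu <- vector("list", M)
  for (m in seq_len(M)) {
    bm <- bandpass(es, config$filterbank[[m]])
    Gm <- array(NA_real_, c(K, K, I))
    mum <- matrix(NA_real_, I, K)
    for (i in seq_len(I)) {
      X <- trial_matrix(bm, i)
      Gm[, , i] <- tcrossprod(X)
      mum[i, ] <- rowMeans(X)
    }
    G[[m]] <- Gm; mu[[m]] <- mum
  }
  list(tdps = tdps, rho = rho, G = G, mu = mu,
       labels = es$labels, I = I, K = K, N = N, fs = es$fs,
       channel_names = es$channel_names, config = config)
}

# Fisher ratios + principle channel from precomputed TDPs on a trial subset
principle_from_tdps <- function(tdps, labels, idx) {
  K <- dim(tdps)[2L]
  sub <- tdps[idx, , , drop = FALSE]
  fisher <- rep(NA_real_, K)
  for (k in seq_len(K))
    fisher[k] <- tryCatch(fisher_ratio(sub, labels[idx], k),
                          error = function(e) NA_real_)
  if (all(is.na(fisher)))
    stop("all channels are degenerate: no principle channel can be selected")
  list(fisher = fisher, principle = which(fisher == max(fisher, na.rm = TRUE))[1L])
}

support_from_rho <- function(rho, labels, idx, principle, threshold) {
  if (threshold <= 0 || threshold > 1) stop("'threshold' must lie in (0, 1]")
  r <- rho[idx, , principle, drop = TRUE]
  if (is.null(dim(r))) r <- matrix(r, nrow = length(idx))
  ci <- class_indices(labels[idx])
  mean_corr <- cbind(colMeans(r[ci[[1L]], , drop = FALSE]),
                     colMeans(r[ci[[2L]], , drop = FALSE]))
  colnames(mean_corr) <- c("class1", "class2")
  keep <- mean_corr[, 1L] >= threshold & mean_corr[, 2L] >= threshold
  keep[principle] <- TRUE
  support <- sort(which(keep))
  if (length(support) < 2L)
    stop("supporting set has fewer than 2 channels at rho_thr = ", threshold,
         "; lower the threshold (CSP needs at least 2 channels)")
  list(mean_corr = mean_corr, support = support)
}

# per-band log-variance CSP features for trials idx, from precomputed
# cross-products: var(p'X) = (p'Gp - N (p'mu)^2) / N
features_from_prepared <- function(prep, idx, support, filters, bands) {
  N <- prep$N
  out <- matrix(NA_real_, length(idx), 2L * length(bands))
  col <- 0L
  for (m in bands) {
    pr <- filters[[m]]
    for (p in list(pr$p_max, pr$p_min)) {
      col <- col + 1L
      g <- apply(prep$G[[m]][support, support, idx, drop = FALSE], 3L,
                 function(Gm) as.numeric(t(p) %*% Gm %*% p))
      pm <- as.numeric(prep$mu[[m]][idx, support, drop = FALSE] %*% p)
      out[, col] <- log(pmax((g - N * pm^2) / N, VAR_FLOOR))
    }
  }
  out
}

fit_prepared <- function(prep, idx, threshold) {
  labels <- prep$labels[idx]
  if (length(unique(labels)) != 2L) stop("training subset must contain both classes")
  sel <- principle_from_tdps(prep$tdps, prep$labels, idx)
  sup <- support_from_rho(prep$rho, prep$labels, idx, sel$principle, threshold)
  S <- sup$support
  M <- length(prep$config$filterbank)
  filters <- vector("list", M)
  per_band_feats <- vector("list", M)
  for (m in seq_len(M)) {
    covs <- lapply(idx, function(i) {
      Gs <- prep$G[[m]][S, S, i]
      Gs / sum(diag(Gs))
    })
    Ebar <- class_mean_covariance(covs, labels)
    filters[[m]] <- solve_csp(Ebar[[1L]], Ebar[[2L]], band = m)
    per_band_feats[[m]] <- features_from_prepared(prep, idx, S,
                                                  filters, m)
  }
  bsel <- select_bands(per_band_feats, labels)
  feats <- cbind(per_band_feats[[bsel$bands[1L]]],
                 per_band_feats[[bsel$bands[2L]]])
  ctr <- colMeans(feats)
  scl <- apply(feats, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(feats, center = ctr, scale = scl)
  m_svm <- e1071::svm(x = Xs, y = factor(labels, levels = c(1L, 2L)),
                      kernel = "linear", cost = prep$config$cost,
                      scale = FALSE)
  w <- as.numeric(t(m_svm$coefs) %*% m_svm$SV)
  b <- -m_svm$rho
  dv <- as.numeric(Xs %*% w) + b
  dvn <- colnames(attr(stats::predict(m_svm, Xs, decision.values = TRUE),
                       "decision.values"))
  pos_label <- as.integer(sub("/.*", "", dvn))
  neg_label <- as.integer(sub(".*/", "", dvn))
  structure(list(
    selection = structure(list(fisher = sel$fisher, principle = sel$principle,
                               mean_corr = sup$mean_corr,
                               threshold = threshold, support = S),
                          class = "channel_selection"),
    filters = filters, bands = bsel$bands, mi_scores = bsel$scores,
    feat_center = ctr, feat_scale = scl,
    svm = list(w = w, b = b, pos_label = pos_label, neg_label = neg_label,
               cost = prep$config$cost),
    n_channels = prep$K, n_samples = prep$N, fs = prep$fs,
    channel_names = prep$channel_names,
    config = prep$config, n_train = length(idx),
    train_decision = dv),
    class = "fbcsp")
}

predict_prepared <- function(model, prep, idx) {
  feats <- cbind(
    features_from_prepared(prep, idx, model$selection$support,
                           model$filters, model$bands[1L]),
    features_from_prepared(prep, idx, model$selection$support,
                           model$filters, model$bands[2L]))
  Xs <- scale(feats, center = model$feat_center, scale = model$feat_scale)
  dv <- as.numeric(Xs %*% model$svm$w) + model$svm$b
  ifelse(dv > 0, model$svm$pos_label, model$svm$neg_label)
}

#' Fit the channel-selected filter-bank CSP classifier
#'
#' Runs the full training pipeline on pre-cut, labelled epochs, in order:
#' broadband filtering (TDP/correlation path), Fisher-ratio selection of
#' the principle channel, construction of the supporting channel set at
#' `threshold`, filter-bank decomposition of the supporting set, one CSP
#' filter pair per band, mutual-information selection of the best two
#' bands, and a linear maximum-margin classifier on the standardized
#' 4-dimensional feature vector.  Every statistic — channel choice, spatial
#' filters, band choice, feature scaling, the hyperplane — is computed from
#' the training epochs alone, so the fitted model predicts new epochs with
#' no access to training data.
#'
#' @param x a labelled [epoch_set()] of raw (unfiltered) epochs.
#' @param threshold correlation threshold `rho_thr` in `(0, 1]` for the
#'   supporting set (default 0.7).  For data-driven selection over
#'   `config$rho_grid`, use [fbcsp_cv()].
#' @param config an [fbcsp_config()].
#' @return an object of class `fbcsp`; see [predict.fbcsp()],
#'   [summary.fbcsp()], [coef.fbcsp()], [plot.fbcsp()].
#' @examples
#' ses <- simulate_session(synth_config(trials_per_class = 20))
#' fit <- fbcsp_fit(ses$epochs, threshold = 0.7)
#' fit
#' mean(predict(fit, ses$epochs) == ses$epochs$labels)
#' @export
fbcsp_fit <- function(x, threshold = 0.7, config = fbcsp_config()) {
  stopifnot(inherits(x, "epoch_set"))
  if (is.null(x$labels)) stop("epochs must be labelled to fit")
  prep <- prepare_session(x, config)
  fit_prepared(prep, seq_len(n_trials(x)), threshold)
}

#' Predict class labels for new epochs
#'
#' @param object a fitted [fbcsp_fit()] model.
#' @param newdata an [epoch_set()] with the same channel count and order as
#'   the training data (labels, if present, are ignored).
#' @param type `"class"` for labels in `{1, 2}`, `"decision"` for the
#'   signed distance to the separating hyperplane.
#' @param ... unused.
#' @return an integer label vector, or a numeric decision-value vector.
#' @export
predict.fbcsp <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "epoch_set"))
  if (n_channels(newdata) != object$n_channels)
    stop("channel mismatch: model was trained on ", object$n_channels,
         " channels (", paste(utils::head(object$channel_names, 4L),
                              collapse = ", "),
         ", ...) but newdata has ", n_channels(newdata))
  S <- object$selection$support
  sub <- subset_epochs(newdata, channels = S)
  feats <- NULL
  for (m in object$bands) {
    bm <- bandpass(sub, object$config$filterbank[[m]])
    fm <- t(vapply(seq_len(n_trials(bm)), function(i) {
      bf <- band_features(trial_matrix(bm, i), object$filters[[m]])
      c(bf$v_max, bf$v_min)
    }, numeric(2)))
    feats <- cbind(feats, fm)
  }
  Xs <- scale(feats, center = object$feat_center, scale = object$feat_scale)
  dv <- as.numeric(Xs %*% object$svm$w) + object$svm$b
  if (type == "decision") return(dv)
  as.integer(ifelse(dv > 0, object$svm$pos_label, object$svm$neg_label))
}

#' @export
print.fbcsp <- function(x, ...) {
  cat("Channel-selected filter-bank CSP model\n")
  cat("  principle channel : ", x$selection$principle, " (",
      x$channel_names[x$selection$principle], ")\n", sep = "")
  cat("  rho_thr           : ", x$selection$threshold, "\n", sep = "")
  cat("  supporting set    : ", length(x$selection$support), " channels: ",
      paste(x$selection$support, collapse = " "), "\n", sep = "")
  bn <- vapply(x$config$filterbank[x$bands],
               function(b) paste0("[", b$low_hz, ",", b$high_hz, "] Hz"),
               character(1))
  cat("  selected bands    : m1 =", x$bands[1L], bn[1L],
      "| m2 =", x$bands[2L], bn[2L], "\n")
  cat("  trained on        : ", x$n_train, " trials\n", sep = "")
  invisible(x)
}

#' Summary of a fitted model
#'
#' @param object a fitted [fbcsp_fit()] model.
#' @param ... unused.
#' @return the model, invisibly; prints per-channel Fisher ratios,
#'   class-mean correlations over the supporting set, per-band mutual
#'   information, and the classifier hyperplane.
#' @export
summary.fbcsp <- function(object, ...) {
  print(object)
  cat("\nPer-channel Fisher ratios (* = principle):\n")
  f <- object$selection$fisher
  tags <- ifelse(seq_along(f) == object$selection$principle, "*", " ")
  print(data.frame(channel = object$channel_names,
                   fisher = round(f, 4), sel = tags), row.names = FALSE)
  cat("\nPer-band mutual information (bits, summed over the filter pair):\n")
  bt <- vapply(object$config$filterbank,
               function(b) paste0(b$low_hz, "-", b$high_hz), character(1))
  print(data.frame(band = bt, mi = round(object$mi_scores, 4),
                   chosen = ifelse(seq_along(bt) %in% object$bands, "x", "")),
        row.names = FALSE)
  cat("\nLinear classifier: w =", format(object$svm$w, digits = 4),
      " b =", format(object$svm$b, digits = 4), "\n")
  invisible(object)
}

#' Model coefficients: the spatial filter pairs of the selected bands
#'
#' @param object a fitted [fbcsp_fit()] model.
#' @param ... unused.
#' @return a matrix with one row per supporting channel and one column per
#'   selected spatial filter (`m1.max`, `m1.min`, `m2.max`, `m2.min`).
#' @export
coef.fbcsp <- function(object, ...) {
  out <- cbind(object$filters[[object$bands[1L]]]$p_max,
               object$filters[[object$bands[1L]]]$p_min,
               object$filters[[object$bands[2L]]]$p_max,
               object$filters[[object$bands[2L]]]$p_min)
  rownames(out) <- object$channel_names[object$selection$support]
  colnames(out) <- c("m1.max", "m1.min", "m2.max", "m2.min")
  out
}

#' Diagnostic plot of a fitted model
#'
#' Left: per-channel Fisher ratio of the time-domain parameters with the
#' principle channel and supporting set highlighted.  Right: per-band
#' mutual information with the two selected bands highlighted.
#'
#' @param x a fitted [fbcsp_fit()] model.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.fbcsp <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  K <- x$n_channels
  cols <- rep("grey70", K)
  cols[x$selection$support] <- "steelblue"
  cols[x$selection$principle] <- "firebrick"
  graphics::barplot(x$selection$fisher, names.arg = seq_len(K), col = cols,
                    xlab = "channel", ylab = "Fisher ratio of TDPs",
                    main = "channel selection", ...)
  M <- length(x$mi_scores)
  bcols <- rep("grey70", M)
  bcols[x$bands] <- "steelblue"
  bt <- vapply(x$config$filterbank,
               function(b) paste0(b$low_hz, "-", b$high_hz), character(1))
  graphics::barplot(x$mi_scores, names.arg = bt, col = bcols, las = 2,
                    xlab = "", ylab = "mutual information (bits)",
                    main = "band selection", ...)
  invisible(x)
}
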