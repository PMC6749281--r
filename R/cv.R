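# stratified fold assignment: per class, a seeded permutation dealt
# round-robin into folds
stratified_folds <- function(labels, folds) {
  out <- integer(length(labels))
  for (cl in 1:2) {
    idx <- which(labels == cl)
    if (length(idx) < folds)
      stop("class ", cl, " has ", length(idx), " trials; need at least ",
           folds, " for ", folds, "-fold stratified CV")
    out[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  out
}

# accuracy of one train/test split at one threshold; NA when the threshold
# leaves fewer than 2 supporting channels
split_accuracy <- function(prep, train, test, threshold) {
  tryCatch({
    model <- fit_prepared(prep, train, threshold)
    mean(predict_prepared(model, prep, test) == prep$labels[test]) * 100
  }, error = function(e) NA_real_)
}

#' Repeated stratified cross-validation with nested threshold selection
#'
#' Estimates out-of-sample accuracy of the full pipeline by
#' `cv_repeats x cv_folds` stratified cross-validation (default 5 x 5).
#' The correlation threshold `rho_thr` is either fixed (`threshold` given:
#' constant-threshold mode) or chosen per outer training fold by an inner
#' stratified `cv_folds`-fold grid search over `config$rho_grid` (nested
#' mode, the default) so that the reported accuracy never uses held-out
#' trials for any selection step.  Grid values at which the supporting set
#' collapses below 2 channels are skipped.  A per-threshold table of outer
#' accuracies and supporting-set sizes (each grid value applied as a
#' constant threshold) is reported alongside.
#'
#' @param x a labelled [epoch_set()].
#' @param config an [fbcsp_config()]; `config$seed` makes folds and hence
#'   the whole result reproducible.
#' @param threshold optional fixed `rho_thr`; `NULL` (default) selects it
#'   by nested CV.
#' @param per_threshold_table set `FALSE` to skip the per-threshold sweep
#'   (faster).
#' @return an object of class `fbcsp_cv`: `fold_acc`
#'   (`cv_repeats x cv_folds` accuracies in percent), `mean`, `sd`,
#'   `chosen_thresholds`, `threshold_table`, `config`.
#' @examples
#' \donttest{
#' ses <- simulate_session(synth_config(trials_per_class = 25))
#' cv <- fbcsp_cv(ses$epochs, threshold = 0.7, per_threshold_table = FALSE)
#' cv
#' }
#' @export
fbcsp_cv <- function(x, config = fbcsp_config(), threshold = NULL,
                     per_threshold_table = TRUE) {
  stopifnot(inherits(x, "epoch_set"))
  if (is.null(x$labels)) stop("epochs must be labelled")
  prep <- prepare_session(x, config)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  cv_run(prep, config, threshold, per_threshold_table)
}

# CV engine on a prepared session; uses the current RNG state for fold
# shuffling so callers control seeding
cv_run <- function(prep, config, threshold = NULL,
                   per_threshold_table = TRUE, allow_na = FALSE) {
  R <- config$cv_repeats; Fo <- config$cv_folds
  grid <- config$rho_grid
  fold_acc <- matrix(NA_real_, R, Fo)
  chosen <- matrix(NA_real_, R, Fo)
  thr_acc <- array(NA_real_, c(length(grid), R, Fo))
  thr_size <- array(NA_real_, c(length(grid), R, Fo))

  for (r in seq_len(R)) {
    folds <- stratified_folds(prep$labels, Fo)
    for (fo in seq_len(Fo)) {
      test <- which(folds == fo)
      train <- which(folds != fo)
      if (is.null(threshold)) {
        inner_folds <- stratified_folds(prep$labels[train], Fo)
        inner_mean <- vapply(grid, function(g) {
          accs <- vapply(seq_len(Fo), function(ifo)
            split_accuracy(prep, train[inner_folds != ifo],
                           train[inner_folds == ifo], g), numeric(1))
          if (all(is.na(accs))) NA_real_ else mean(accs, na.rm = TRUE)
        }, numeric(1))
        if (all(is.na(inner_mean)))
          stop("no grid threshold yields a valid supporting set")
        # best inner threshold first (ties -> lower threshold); fall back
        # down the ranking if a threshold collapses on the full outer fold
        ranking <- grid[order(-inner_mean, grid, na.last = TRUE)]
        ranking <- ranking[!is.na(inner_mean[match(ranking, grid)])]
        model <- NULL
        for (thr in ranking) {
          model <- tryCatch(fit_prepared(prep, train, thr),
                            error = function(e) NULL)
          if (!is.null(model)) break
        }
        if (is.null(model))
          stop("no grid threshold yields a valid supporting set on the ",
               "training fold")
      } else {
        thr <- threshold
        model <- if (allow_na)
          tryCatch(fit_prepared(prep, train, thr), error = function(e) NULL)
        else fit_prepared(prep, train, thr)
      }
      chosen[r, fo] <- thr
      if (!is.null(model))
        fold_acc[r, fo] <- mean(predict_prepared(model, prep, test) ==
                                  prep$labels[test]) * 100
      if (per_threshold_table) {
        for (g in seq_along(grid)) {
          thr_acc[g, r, fo] <- split_accuracy(prep, train, test, grid[g])
          thr_size[g, r, fo] <- tryCatch(
            length(support_from_rho(prep$rho, prep$labels, train,
                                    principle_from_tdps(prep$tdps, prep$labels,
                                                        train)$principle,
                                    grid[g])$support),
            error = function(e) NA_real_)
        }
      }
    }
  }
  tab <- if (per_threshold_table) {
    data.frame(rho_thr = grid,
               accuracy = apply(thr_acc, 1L, mean, na.rm = TRUE),
               sd = apply(thr_acc, 1L, stats::sd, na.rm = TRUE),
               support_size = apply(thr_size, 1L, mean, na.rm = TRUE))
  } else NULL
  structure(list(fold_acc = fold_acc,
                 mean = mean(fold_acc, na.rm = allow_na),
                 sd = stats::sd(as.numeric(fold_acc), na.rm = allow_na),
                 chosen_thresholds = chosen, threshold_table = tab,
                 mode = if (is.null(threshold)) "nested" else "constant",
                 threshold = threshold, config = config),
            class = "fbcsp_cv")
}

#' @export
print.fbcsp_cv <- function(x, ...) {
  cat("Repeated stratified cross-validation (", nrow(x$fold_acc), " x ",
      ncol(x$fold_acc), ")\n", sep = "")
  cat("  threshold mode :", x$mode,
      if (x$mode == "constant") paste0("(rho_thr = ", x$threshold, ")") else "",
      "\n")
  cat(sprintf("  accuracy       : %.2f %% (sd %.2f)\n", x$mean, x$sd))
  if (x$mode == "nested") {
    tt <- table(x$chosen_thresholds)
    cat("  chosen rho_thr :",
        paste(sprintf("%s (x%d)", names(tt), as.integer(tt)), collapse = ", "),
        "\n")
  }
  if (!is.null(x$threshold_table)) {
    cat("  per-threshold outer accuracy (constant mode):\n")
    tab <- x$threshold_table
    tab$accuracy <- round(tab$accuracy, 2)
    tab$sd <- round(tab$sd, 2)
    tab$support_size <- round(tab$support_size, 1)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.fbcsp_cv <- function(object, ...) {
  print(object)
  cat("\nPer-fold accuracies (%):\n")
  print(round(object$fold_acc, 2))
  invisible(object)
}

#' @export
plot.fbcsp_cv <- function(x, ...) {
  if (is.null(x$threshold_table)) {
    graphics::boxplot(as.numeric(x$fold_acc), ylab = "accuracy (%)",
                      main = "cross-validated accuracy", ...)
  } else {
    tab <- x$threshold_table
    graphics::plot(tab$rho_thr, tab$accuracy, type = "b", pch = 19,
                   xlab = expression(rho[thr]), ylab = "accuracy (%)",
                   main = "accuracy vs correlation threshold", ...)
    graphics::abline(h = x$mean, lty = 2)
  }
  invisible(x)
}

#' Label-permutation null test of the cross-validated accuracy
#'
#' Repeats the full cross-validation under seeded random permutations of
#' the class labels.  If the pipeline leaks no information, the permuted
#' accuracies scatter around chance level (50% for balanced classes); a
#' mean far from chance indicates leakage or a broken protocol.  The
#' permutation runs use a fixed threshold (constant mode) since the
#' chance-level property does not depend on the threshold mode.
#'
#' @param x a labelled [epoch_set()].
#' @param config an [fbcsp_config()].
#' @param n_perm number of label permutations.
#' @param threshold fixed `rho_thr` used for every permutation run.
#' @return a list with `perm_means` (length-`n_perm` vector of mean CV
#'   accuracies, percent) and `mean` (their average).
#' @export
permutation_test <- function(x, config = fbcsp_config(), n_perm = 20L,
                             threshold = 0.7) {
  stopifnot(inherits(x, "epoch_set"))
  if (is.null(x$labels)) stop("epochs must be labelled")
  prep <- prepare_session(x, config)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  perm_means <- vapply(seq_len(n_perm), function(p) {
    prep$labels <- sample(x$labels)
    cv_run(prep, config, threshold = threshold,
           per_threshold_table = FALSE, allow_na = TRUE)$mean
  }, numeric(1))
  list(perm_means = perm_means, mean = mean(perm_means))
}
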