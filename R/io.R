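#' Read and write the plain-text epoch container
#'
#' A simple self-describing text format for pre-cut epochs, used by the
#' command-line tools and tests.  Layout: comment-style header lines
#' (`# key: value` — `fs`, `trials`, `channels`, `samples`,
#' `channel_names` (comma-separated), `labels` (space-separated or
#' `none`)), followed by `trials * channels` data lines of `samples`
#' whitespace-separated numbers, trial-major (trial 1 channel 1..K, then
#' trial 2, ...).
#'
#' @param es an [epoch_set()].
#' @param path file path.
#' @return `read_epochs()` returns an [epoch_set()]; `write_epochs()`
#'   returns `path` invisibly.
#' @export
write_epochs <- function(es, path) {
  stopifnot(inherits(es, "epoch_set"))
  dm <- dim(es$data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fbcsp epoch container v1",
               paste0("# fs: ", format(es$fs, digits = 15)),
               paste0("# trials: ", dm[1L]),
               paste0("# channels: ", dm[2L]),
               paste0("# samples: ", dm[3L]),
               paste0("# channel_names: ", paste(es$channel_names, collapse = ",")),
               paste0("# labels: ",
                      if (is.null(es$labels)) "none"
                      else paste(es$labels, collapse = " "))), con)
  for (i in seq_len(dm[1L]))
    for (k in seq_len(dm[2L]))
      writeLines(paste(format(es$data[i, k, ], digits = 17), collapse = " "), con)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("epoch container is missing header field '", key, "'")
    trimws(sub(paste0("^# ", key, ":"), "", ln[1L]))
  }
  fs <- as.numeric(get_field("fs"))
  I <- as.integer(get_field("trials"))
  K <- as.integer(get_field("channels"))
  N <- as.integer(get_field("samples"))
  chn <- strsplit(get_field("channel_names"), ",")[[1L]]
  lab_str <- get_field("labels")
  labels <- if (identical(lab_str, "none")) NULL
            else as.integer(strsplit(lab_str, "\\s+")[[1L]])
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != I * K)
    stop("expected ", I * K, " data lines, found ", length(body))
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  if (any(lengths(vals) != N)) stop("data line with wrong sample count")
  data <- array(NA_real_, c(I, K, N))
  row <- 0L
  for (i in seq_len(I))
    for (k in seq_len(K)) {
      row <- row + 1L
      data[i, k, ] <- vals[[row]]
    }
  epoch_set(data, labels = labels, fs = fs, channel_names = chn)
}

# ---- EDF / EDF+ ----------------------------------------------------------

pad_str <- function(s, n) {
  s <- substr(s, 1L, n)
  paste0(s, strrep(" ", n - nchar(s)))
}

#' Write a continuous recording as EDF(+)
#'
#' Minimal European-Data-Format writer: one data record per second,
#' 16-bit samples with per-channel physical scaling, and (optionally) an
#' `EDF Annotations` signal carrying cue markers as EDF+ time-stamped
#' annotation lists.  The recording is zero-padded to a whole number of
#' seconds.
#'
#' @param signals numeric matrix `channels x time` (microvolts).
#' @param fs sampling rate, Hz (integer).
#' @param path output file path.
#' @param channel_names optional channel labels.
#' @param annotations optional `data.frame(onset, text)` with onsets in
#'   seconds — typically trial cues.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, path, channel_names = NULL,
                      annotations = NULL) {
  stopifnot(is.matrix(signals), fs == round(fs))
  K <- nrow(signals)
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(K))
  n_rec <- ceiling(ncol(signals) / fs)
  if (ncol(signals) < n_rec * fs)
    signals <- cbind(signals,
                     matrix(0, K, n_rec * fs - ncol(signals)))
  has_annot <- !is.null(annotations) && nrow(annotations) > 0
  ns <- K + as.integer(has_annot)
  annot_samples <- 60L   # 120 bytes of annotation text per record

  phys_min <- apply(signals, 1L, min)
  phys_max <- apply(signals, 1L, max)
  same <- phys_max - phys_min < 1e-9
  phys_max[same] <- phys_min[same] + 1
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, n) writeChar(pad_str(s, n), con, nchars = n, eos = NULL)
  wr("0", 8)                                  # version
  wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (1L + ns)), 8)       # header bytes
  wr(if (has_annot) "EDF+C" else "", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)                                  # record duration, seconds
  wr(as.character(ns), 4)
  labs <- c(channel_names, if (has_annot) "EDF Annotations")
  for (l in labs) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)           # transducer
  wr_each <- function(vals, n) for (v in vals) wr(v, n)
  wr_each(c(rep("uV", K), if (has_annot) ""), 8)
  wr_each(c(sprintf("%.7g", phys_min), if (has_annot) "-1"), 8)
  wr_each(c(sprintf("%.7g", phys_max), if (has_annot) "1"), 8)
  wr_each(c(rep(as.character(dig_min), K), if (has_annot) "-32768"), 8)
  wr_each(c(rep(as.character(dig_max), K), if (has_annot) "32767"), 8)
  for (i in seq_len(ns)) wr("", 80)           # prefiltering
  wr_each(c(rep(as.character(fs), K), if (has_annot) as.character(annot_samples)), 8)
  for (i in seq_len(ns)) wr("", 32)           # reserved

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (k in seq_len(K)) {
      dig <- round((signals[k, cols] - phys_min[k]) / scale[k] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2L, endian = "little")
    }
    if (has_annot) {
      tals <- paste0("+", r - 1L, "\x14\x14")  # record time stamp
      in_rec <- which(annotations$onset >= r - 1L & annotations$onset < r)
      for (j in in_rec)
        tals <- c(tals, paste0("+", format(annotations$onset[j], digits = 10),
                               "\x14", annotations$text[j], "\x14"))
      # TALs are separated and terminated by NUL bytes
      raw_tal <- unlist(lapply(tals, function(t) c(charToRaw(t), as.raw(0L))))
      budget <- 2L * annot_samples
      if (length(raw_tal) > budget)
        stop("too many annotations in record ", r, " for the EDF+ byte budget")
      writeBin(c(raw_tal, raw(budget - length(raw_tal))), con)
    }
  }
  invisible(path)
}

#' Read a continuous EDF(+) recording
#'
#' Minimal reader for the classic EDF layout written by [write_edf()] and
#' common acquisition software: equal sampling rate across ordinary
#' signals, 16-bit samples, optional `EDF Annotations` signal parsed into
#' onset/text pairs (usable directly as cue times for
#' [extract_epochs()]).
#'
#' @param path EDF file path.
#' @return a list with `signals` (`channels x time` matrix, physical
#'   units), `fs`, `channel_names`, `annotations`
#'   (`data.frame(onset, text)`).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  vapply(seq_len(ns), function(i) rd(8), character(1))   # units
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  is_annot <- labels == "EDF Annotations"
  ord_idx <- which(!is_annot)
  K <- length(ord_idx)
  if (length(unique(nsamp[ord_idx])) > 1L)
    stop("signals with differing sampling rates are not supported")
  fs <- nsamp[ord_idx[1L]] / rec_dur
  signals <- matrix(NA_real_, K, n_rec * nsamp[ord_idx[1L]])
  ann <- list()
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (is_annot[s]) {
        raw_tal <- readBin(con, "raw", n = 2L * nsamp[s])
        ann <- c(ann, split_raw_tals(raw_tal))
      } else {
        dig <- readBin(con, "integer", n = nsamp[s], size = 2L,
                       endian = "little")
        k <- match(s, ord_idx)
        cols <- ((r - 1L) * nsamp[s] + 1L):(r * nsamp[s])
        scale <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
        signals[k, cols] <- (dig - dig_min[s]) * scale + phys_min[s]
      }
    }
  }
  annotations <- parse_tals(ann)
  list(signals = signals, fs = fs, channel_names = labels[ord_idx],
       annotations = annotations)
}

# split the NUL-separated byte stream of an annotation signal into
# individual TAL strings
split_raw_tals <- function(raw_tal) {
  is_sep <- raw_tal == as.raw(0L)
  grp <- cumsum(c(TRUE, is_sep[-length(is_sep)]))
  pieces <- split(raw_tal[!is_sep], grp[!is_sep])
  unname(vapply(pieces, rawToChar, character(1)))
}

# turn TAL strings into onset/text rows, dropping bare record time stamps
parse_tals <- function(tals) {
  onset <- numeric(0); text <- character(0)
  for (tal in tals) {
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) next              # time-stamp-only TAL
    on <- suppressWarnings(as.numeric(sub("\x15.*", "", parts[1L])))
    for (tx in parts[-1L]) {
      if (!nzchar(tx) || is.na(on)) next
      onset <- c(onset, on); text <- c(text, tx)
    }
  }
  data.frame(onset = onset, text = text)
}

# ---- fitted-model container ----------------------------------------------

#' Save and load a fitted model
#'
#' The fitted model is serialized to a single self-contained JSON file:
#' channel selection, per-band spatial filter pairs, selected bands and
#' their mutual-information scores, feature scaling, the linear classifier
#' hyperplane, and the configuration snapshot.  `read_model()` restores an
#' object on which [predict.fbcsp()] works directly.
#'
#' @param model a fitted [fbcsp_fit()] model.
#' @param path file path (`.json`).
#' @return `read_model()` returns the `fbcsp` object; `write_model()`
#'   returns `path` invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "fbcsp"))
  x <- unclass(model)
  x$train_decision <- NULL
  x$selection <- unclass(x$selection)
  x$filters <- lapply(x$filters, unclass)
  x$config <- serialize_config(x$config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  x$selection <- structure(list(
    fisher = as.numeric(unlist(x$selection$fisher)),
    principle = as.integer(x$selection$principle),
    mean_corr = matrix(as.numeric(unlist(x$selection$mean_corr)),
                       ncol = 2L, byrow = TRUE,
                       dimnames = list(NULL, c("class1", "class2"))),
    threshold = x$selection$threshold,
    support = as.integer(unlist(x$selection$support))),
    class = "channel_selection")
  x$filters <- lapply(x$filters, function(f) structure(
    list(p_max = as.numeric(unlist(f$p_max)),
         p_min = as.numeric(unlist(f$p_min)),
         j_max = f$j_max, j_min = f$j_min,
         band = if (is.null(f$band) || is.na(f$band)) NA_integer_
                else as.integer(f$band)),
    class = "spatial_filter_pair"))
  x$bands <- as.integer(unlist(x$bands))
  x$mi_scores <- as.numeric(unlist(x$mi_scores))
  x$feat_center <- as.numeric(unlist(x$feat_center))
  x$feat_scale <- as.numeric(unlist(x$feat_scale))
  x$svm$w <- as.numeric(unlist(x$svm$w))
  x$channel_names <- as.character(unlist(x$channel_names))
  x$config <- deserialize_config(x$config)
  structure(x, class = "fbcsp")
}

serialize_config <- function(cfg) {
  list(window = cfg$window,
       broadband = unclass(cfg$broadband),
       filterbank = lapply(cfg$filterbank, unclass),
       rho_grid = cfg$rho_grid, cv_folds = cfg$cv_folds,
       cv_repeats = cfg$cv_repeats, cost = cfg$cost, seed = cfg$seed)
}

deserialize_config <- function(x) {
  fbcsp_config(window = unlist(x$window),
               broadband = band_spec(x$broadband$low_hz, x$broadband$high_hz,
                                     x$broadband$order),
               filterbank = filter_bank(lapply(
                 if (is.data.frame(x$filterbank))
                   split(x$filterbank, seq_len(nrow(x$filterbank)))
                 else x$filterbank,
                 function(b) band_spec(b$low_hz, b$high_hz, b$order))),
               rho_grid = unlist(x$rho_grid), cv_folds = x$cv_folds,
               cv_repeats = x$cv_repeats, cost = x$cost, seed = x$seed)
}

#' Read a pipeline configuration from a YAML file
#'
#' Schema (all keys optional; missing keys take the [fbcsp_config()]
#' defaults): `window_t0`, `window_t1` (seconds), `broadband`
#' (`[low, high]` Hz), `filter_order`, `filterbank` (`default` or a list
#' of `[low, high]` pairs), `rho_grid`, `cv_folds`, `cv_repeats`, `cost`,
#' `seed`.
#'
#' @param path YAML file path.
#' @return an [fbcsp_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  ord <- if (!is.null(y$filter_order)) y$filter_order else 4L
  d <- fbcsp_config()
  fb <- if (is.null(y$filterbank) || identical(y$filterbank, "default"))
    default_filterbank()
  else filter_bank(lapply(y$filterbank, function(b)
    band_spec(b[[1L]], b[[2L]], order = ord)))
  fbcsp_config(
    window = c(if (!is.null(y$window_t0)) y$window_t0 else d$window[1L],
               if (!is.null(y$window_t1)) y$window_t1 else d$window[2L]),
    broadband = if (!is.null(y$broadband))
      band_spec(y$broadband[[1L]], y$broadband[[2L]], order = ord)
    else d$broadband,
    filterbank = fb,
    rho_grid = if (!is.null(y$rho_grid)) unlist(y$rho_grid) else d$rho_grid,
    cv_folds = if (!is.null(y$cv_folds)) y$cv_folds else d$cv_folds,
    cv_repeats = if (!is.null(y$cv_repeats)) y$cv_repeats else d$cv_repeats,
    cost = if (!is.null(y$cost)) y$cost else d$cost,
    seed = if (!is.null(y$seed)) y$seed else d$seed)
}
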