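#' Feature-file writer configuration
#'
#' Controls how labeled feature vectors are serialized. Two dialects are
#' supported: a numbered sparse/dense dialect following the SVM^light line
#' grammar (`<label> <index>:<value> ...`, 1-based strictly ascending
#' indices, zero-valued features optionally omitted) and an unnumbered dense
#' dialect (`<label> <value> <value> ...`).
#'
#' @param numbered Emit `index:value` pairs (`TRUE`, SVM^light) or bare
#'   values (`FALSE`, dense).
#' @param sparse In numbered mode, omit features whose value is exactly 0
#'   (the final feature is always written so the vector length is
#'   recoverable).
#' @param precision Decimal places printed for feature values (default 6:
#'   lossless enough for \[0, 1\]-scaled features while keeping files
#'   diffable).
#' @return A `writer_config` list.
#' @export
writer_config <- function(numbered = TRUE, sparse = FALSE, precision = 6L) {
  if (precision < 0) abort_domain("precision must be >= 0")
  if (sparse && !numbered) {
    abort_domain("sparse output requires numbered mode (indices identify features)")
  }
  structure(
    list(
      numbered = isTRUE(numbered), sparse = isTRUE(sparse),
      precision = as.integer(precision), index_base = 1L, delimiter = " "
    ),
    class = "writer_config"
  )
}

fmt_value <- function(v, precision) sprintf(paste0("%.", precision, "f"), v)

# Labels print as integers when integral, else at feature precision.
fmt_label <- function(label, precision) {
  if (label == round(label)) sprintf("%d", as.integer(label))
  else fmt_value(label, precision)
}

#' Format one labeled example as a feature-file line
#'
#' @param label A finite numeric target (class or regression value).
#' @param features Non-empty numeric vector of feature values.
#' @param cfg A [writer_config()].
#' @param comment Optional comment, appended as `" # <comment>"` in numbered
#'   mode (the SVM^light comment convention).
#' @return A single text line (no trailing newline).
#' @export
#' @examples
#' format_example(1, c(0.5, 0, 1), writer_config(sparse = TRUE))
format_example <- function(label, features, cfg = writer_config(), comment = NULL) {
  if (length(features) == 0) abort_domain("features must be non-empty")
  if (!is.finite(label)) abort_domain("label must be finite")
  bad <- which(!is.finite(features))
  if (length(bad) > 0) {
    abort_domain(paste0("non-finite feature value at index ", bad[[1]]))
  }
  if (cfg$numbered) {
    # sparse mode always emits the final feature, zero or not, so the
    # vector's dimension survives the round trip
    keep <- if (cfg$sparse) {
      features != 0 | seq_along(features) == length(features)
    } else {
      rep(TRUE, length(features))
    }
    toks <- paste0(which(keep), ":", fmt_value(features[keep], cfg$precision))
    line <- paste(c(fmt_label(label, cfg$precision), toks), collapse = cfg$delimiter)
    if (!is.null(comment)) line <- paste0(line, " # ", comment)
  } else {
    line <- paste(
      c(fmt_label(label, cfg$precision), fmt_value(features, cfg$precision)),
      collapse = cfg$delimiter
    )
  }
  line
}

#' Write labeled feature vectors to a text file
#'
#' Serializes a feature table — one row per training/classification example
#' — to the dialect selected by `cfg`, one line per example in order,
#' newline-terminated. Existing files are overwritten.
#'
#' @param examples A data frame with a numeric `label` column and a
#'   `features` list-column of numeric vectors (as returned by
#'   [parse_feature_file()] or [build_feature_table()]); an optional
#'   `comment` character column is carried into numbered-mode lines.
#' @param path Output file path.
#' @param cfg A [writer_config()].
#' @return The number of lines written, invisibly.
#' @export
write_features <- function(examples, path, cfg = writer_config()) {
  if (!is.data.frame(examples) || nrow(examples) == 0) {
    abort_domain("examples must be a non-empty data frame")
  }
  if (!all(c("label", "features") %in% names(examples))) {
    abort_domain("examples needs 'label' and 'features' columns")
  }
  comments <- if ("comment" %in% names(examples)) examples$comment else rep(list(NULL), nrow(examples))
  lines <- vapply(seq_len(nrow(examples)), function(i) {
    cm <- comments[[i]]
    if (is.null(cm) || is.na(cm)) cm <- NULL
    format_example(examples$label[[i]], examples$features[[i]], cfg, comment = cm)
  }, character(1))
  con <- file(path, open = "wb") # fixed LF endings for byte-identical round trips
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(length(lines))
}

#' Read a feature file back into a feature table
#'
#' Parses both dialects written by [write_features()]. Numbered lines are
#' recognized by `index:value` tokens; on sparse lines, indices absent up to
#' the maximum index seen on that line fill with 0.
#'
#' @param path Path to a feature file.
#' @return A tibble with columns `label` (numeric), `features` (list-column
#'   of numeric vectors) and `comment` (character, `NA` when absent).
#' @export
parse_feature_file <- function(path) {
  lines <- read_file_lines(path, "feature")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort_format("empty feature file")
  labels <- numeric(length(lines))
  feats <- vector("list", length(lines))
  comments <- rep(NA_character_, length(lines))
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("#", line, fixed = TRUE)) {
      comments[[i]] <- trimws(sub("^[^#]*#", "", line))
      line <- sub("#.*$", "", line)
    }
    toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(toks) < 2) {
      abort_format(paste0("line ", i, ": expected a label and at least one feature"))
    }
    labels[[i]] <- parse_num(toks[[1]], i, "label")
    body <- toks[-1]
    if (any(grepl(":", body, fixed = TRUE))) {
      if (!all(grepl("^[0-9]+:", body))) {
        abort_format(paste0("line ", i, ": mixed numbered and bare feature tokens"))
      }
      idx <- as.integer(sub(":.*$", "", body))
      val <- vapply(sub("^[0-9]+:", "", body), parse_num, numeric(1),
        line = i, what = "feature value", USE.NAMES = FALSE
      )
      if (any(idx < 1) || any(diff(idx) <= 0)) {
        abort_format(paste0("line ", i, ": feature indices must be ascending and >= 1"))
      }
      v <- numeric(max(idx))
      v[idx] <- val
      feats[[i]] <- v
    } else {
      feats[[i]] <- vapply(body, parse_num, numeric(1),
        line = i, what = "feature value", USE.NAMES = FALSE
      )
    }
  }
  tibble(label = labels, features = feats, comment = comments)
}

parse_num <- function(tok, line, what) {
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v)) abort_format(paste0("line ", line, ": unparsable ", what, " '", tok, "'"))
  v
}
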