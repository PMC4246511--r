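#' Read SSpro / ACCpro flat prediction output
#'
#' Parses the two-line flat layout: a header block (lines starting with `#`
#' or containing a program banner), the query sequence line, then the
#' prediction string line of equal length. Whether the prediction is 3-state
#' secondary structure (symbols from \{H, E, C\}) or 2-state solvent
#' accessibility is inferred from the observed symbol alphabet; ACCpro-style
#' `\{e, -\}` strings are mapped onto \{e, b\}. An alphabet consistent with
#' both (or neither) interpretation requires an explicit `kind`.
#'
#' @param path Path to the prediction file.
#' @param kind `"SS3"`, `"SA2"`, or `NULL` to infer from the symbols.
#' @return An `ss_prediction` object: a list with `residues` (query
#'   sequence), `kind`, `symbols` (the per-residue annotation string) and
#'   `probabilities` (`NULL`; only PSIPRED supplies class probabilities).
#' @export
read_sspro <- function(path, kind = NULL) {
  lines <- read_file_lines(path, "SSpro")
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[!grepl("^#", trimws(lines))]
  # a banner line mentions the program; anything with whitespace or digits
  # cannot be a sequence/prediction string in this layout
  body <- body[!grepl("[[:space:][:digit:]]", trimws(body))]
  if (length(body) < 2) {
    abort_format("SSpro output must contain a sequence line and a prediction line")
  }
  residues <- normalize_sequence(body[[1]], record = "SSpro query")
  pred <- trimws(body[[2]])
  if (nchar(pred) != nchar(residues)) {
    abort_format(paste0(
      "SSpro prediction length ", nchar(pred),
      " does not match sequence length ", nchar(residues)
    ))
  }
  pred <- chartr("-", "b", pred) # ACCpro writes '-' for buried
  inferred <- infer_annotation_kind(pred)
  if (is.null(kind)) {
    if (is.na(inferred)) {
      abort_domain(
        "prediction alphabet is consistent with both SS3 and SA2; pass kind="
      )
    }
    kind <- inferred
  }
  check_annotation(pred, kind)
  new_ss_prediction(residues, kind, pred, probabilities = NULL, source = "sspro")
}

#' Read PSIPRED vertical (.ss2) prediction output
#'
#' Parses the machine-readable PSIPRED dialect: `#` comment line(s), a blank
#' line, then one row per residue of the form
#' `idx aa ss p_coil p_helix p_strand`. The probability matrix is returned
#' in (coil, helix, strand) column order. A row whose probabilities do not
#' sum to 1 within 0.02 triggers a warning but is kept (source files print 3
#' decimals).
#'
#' @param path Path to the `.ss2` file.
#' @return An `ss_prediction` object with `kind = "SS3"` and a length x 3
#'   `probabilities` matrix (columns `coil`, `helix`, `strand`).
#' @export
read_psipred <- function(path) {
  lines <- read_file_lines(path, "PSIPRED")
  rows <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(rows) == 0) abort_format("PSIPRED .ss2 file contains no data rows")
  residues <- character(0)
  ss <- character(0)
  probs <- matrix(numeric(0), ncol = 3)
  for (i in seq_along(rows)) {
    toks <- strsplit(trimws(rows[[i]]), "[[:space:]]+")[[1]]
    if (length(toks) != 6) {
      abort_format(paste0("PSIPRED row ", i, ": expected 6 fields, got ", length(toks)))
    }
    p <- suppressWarnings(as.numeric(toks[4:6]))
    if (anyNA(p) || !toks[[3]] %in% SS3) {
      abort_format(paste0("PSIPRED row ", i, ": malformed fields"))
    }
    if (abs(sum(p) - 1) > 0.02) {
      warn(paste0(
        "PSIPRED row ", i, ": probabilities sum to ", sprintf("%.3f", sum(p)),
        "; row kept"
      ))
    }
    residues <- c(residues, toks[[2]])
    ss <- c(ss, toks[[3]])
    probs <- rbind(probs, p)
  }
  colnames(probs) <- c("coil", "helix", "strand")
  rownames(probs) <- NULL
  residues <- normalize_sequence(paste(residues, collapse = ""), "PSIPRED query")
  new_ss_prediction(residues, "SS3", paste(ss, collapse = ""),
    probabilities = probs, source = "psipred"
  )
}

new_ss_prediction <- function(residues, kind, symbols, probabilities, source) {
  structure(
    list(
      residues = residues, kind = kind, symbols = symbols,
      probabilities = probabilities, source = source
    ),
    class = "ss_prediction"
  )
}

#' @export
print.ss_prediction <- function(x, ...) {
  cat("<ss_prediction> ", x$kind, ", ", nchar(x$symbols), " residues (",
    x$source, ")\n",
    sep = ""
  )
  invisible(x)
}
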