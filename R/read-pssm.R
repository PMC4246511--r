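#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the plain-text PSSM that PSI-BLAST emits with
#' `-out_ascii_pssm`/`-Q`: header lines, a column-label line carrying 40
#' residue letters, then one row per query position with the position index,
#' the query residue, 20 integer log-odds scores, 20 weighted observed
#' percentages, the per-position information (bits) and the relative weight.
#' Footer statistics (lambda/K) after the data block are ignored.
#'
#' Both 20-column blocks are kept in the file's native column order
#' (`A R N D C Q E G H I L K M F P S T W Y V`), recorded in the matrix
#' column names; characterizers remap to the package's canonical
#' alphabetical order at their boundary.
#'
#' @param path Path to the ASCII PSSM file.
#' @return A `pssm_profile` object: a list with `residues` (character vector
#'   of query residues), `log_odds` and `percentages` (length x 20 integer
#'   matrices), and `information` (numeric vector, bits).
#' @export
read_pssm <- function(path) {
  lines <- read_file_lines(path, "PSSM")
  is_label <- vapply(lines, function(l) {
    toks <- strsplit(trimws(l), "[[:space:]]+")[[1]]
    length(toks) == 40 && all(nchar(toks) == 1) && all(toks %in% AA20)
  }, logical(1), USE.NAMES = FALSE)
  if (!any(is_label)) {
    abort_format("not a PSI-BLAST ASCII PSSM: no 40-letter column label line")
  }
  start <- which(is_label)[[1]] + 1
  residues <- character(0)
  log_odds <- list()
  percentages <- list()
  information <- numeric(0)
  expected_idx <- 1L
  for (i in seq.int(start, length.out = max(length(lines) - start + 1, 0))) {
    line <- lines[[i]]
    toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(toks) == 0 || !nzchar(toks[[1]])) break
    if (!grepl("^[0-9]+$", toks[[1]])) break # footer statistics block
    if (length(toks) < 44) {
      abort_format(paste0(
        "PSSM line ", i, ": expected 42 data fields after index and residue, got ",
        length(toks) - 2
      ))
    }
    idx <- as.integer(toks[[1]])
    if (idx != expected_idx) {
      abort_format(paste0(
        "PSSM line ", i, ": non-contiguous position index ", idx,
        " (expected ", expected_idx, ")"
      ))
    }
    expected_idx <- expected_idx + 1L
    residues <- c(residues, toks[[2]])
    log_odds[[idx]] <- as.numeric(toks[3:22])
    percentages[[idx]] <- as.numeric(toks[23:42])
    information <- c(information, as.numeric(toks[[43]]))
  }
  if (length(residues) == 0) abort_format("PSSM contains no data rows")
  lo <- do.call(rbind, log_odds)
  pc <- do.call(rbind, percentages)
  colnames(lo) <- colnames(pc) <- PSIBLAST_ORDER
  if (anyNA(lo) || anyNA(pc) || anyNA(information)) {
    abort_format("PSSM contains non-numeric score fields")
  }
  if (any(information < 0)) {
    abort_format("PSSM information column contains negative values")
  }
  new_pssm_profile(residues, lo, pc, information)
}

new_pssm_profile <- function(residues, log_odds, percentages, information) {
  structure(
    list(
      residues = residues,
      log_odds = log_odds,
      percentages = percentages,
      information = information
    ),
    class = "pssm_profile"
  )
}

#' @export
length.pssm_profile <- function(x) length(x$residues)

#' @export
print.pssm_profile <- function(x, ...) {
  cat("<pssm_profile> ", length(x), " positions, query ",
    paste(x$residues, collapse = ""), "\n",
    sep = ""
  )
  invisible(x)
}
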