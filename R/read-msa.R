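#' Read a query-anchored multiple sequence alignment
#'
#' The anchored dialect is one aligned sequence per line, all lines the same
#' length, `-` for gaps, with the (gapless) query on the first line. Because
#' the query carries no gaps, alignment columns map one-to-one onto query
#' residues.
#'
#' @param path Path to the alignment file.
#' @param id Identifier assigned to the query record (default the file name).
#' @return An `anchored_msa` object: a list with `query` (a list holding
#'   `id` and `sequence`) and `rows` (character vector of aligned strings,
#'   row 1 the query itself).
#' @export
read_anchored_msa <- function(path, id = NULL) {
  lines <- read_file_lines(path, "MSA")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort_format("empty MSA file")
  widths <- nchar(lines)
  if (any(widths != widths[[1]])) {
    bad <- which(widths != widths[[1]])[[1]]
    abort_format(paste0(
      "MSA line ", bad, " has length ", widths[[bad]],
      " but the query has length ", widths[[1]]
    ))
  }
  if (grepl("-", lines[[1]], fixed = TRUE)) {
    abort_format("anchored MSA query (first line) must not contain gaps")
  }
  rows <- toupper(lines)
  for (k in seq_along(rows)) {
    bad <- setdiff(unique(seq_chars(rows[[k]])), c(AA20, "X", "-"))
    if (length(bad) > 0) {
      abort_alphabet(bad[[1]], paste0("MSA row ", k))
    }
  }
  query_id <- id %||% basename(if (file.exists(path)) path else "query")
  new_anchored_msa(query_id, rows)
}

new_anchored_msa <- function(id, rows) {
  structure(
    list(query = list(id = id, sequence = rows[[1]]), rows = rows),
    class = "anchored_msa"
  )
}

#' @export
print.anchored_msa <- function(x, ...) {
  cat("<anchored_msa> ", length(x$rows), " rows x ",
    nchar(x$query$sequence), " columns, query '", x$query$id, "'\n",
    sep = ""
  )
  invisible(x)
}
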