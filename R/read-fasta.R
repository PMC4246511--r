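#' Read protein sequences from FASTA
#'
#' Parses FASTA-formatted text into one record per header. Multi-line
#' sequences are concatenated, whitespace is stripped, lower-case residues
#' are upper-cased, and the non-standard codes B, Z, U, O, J are mapped to
#' `X`. The record id is the header text after `>` up to the first
#' whitespace.
#'
#' @param path_or_text Path to a FASTA file, or a character vector of raw
#'   FASTA text (recognized by the presence of a `>` header or newline).
#' @return A tibble with one row per record and columns `id` and `sequence`.
#' @export
#' @examples
#' read_fasta(">p1 some description\nAC\nDE\n>p2\nGG")
read_fasta <- function(path_or_text) {
  lines <- slurp_lines(path_or_text)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort_format("empty FASTA input")
  if (!startsWith(trimws(lines[[1]]), ">")) {
    abort_format("FASTA input must start with a '>' header")
  }
  headers <- grepl("^>", trimws(lines))
  group <- cumsum(headers)
  ids <- character(0)
  seqs <- character(0)
  for (g in unique(group)) {
    block <- lines[group == g]
    header <- sub("^>", "", trimws(block[[1]]))
    id <- strsplit(header, "[[:space:]]+")[[1]][[1]]
    if (is.na(id) || !nzchar(id)) id <- paste0("record", g)
    body <- paste(block[-1], collapse = "")
    if (!nzchar(gsub("[[:space:]]", "", body))) {
      abort_format(paste0("record '", id, "' has an empty sequence"))
    }
    ids <- c(ids, id)
    seqs <- c(seqs, normalize_sequence(body, record = id))
  }
  tibble(id = ids, sequence = seqs)
}

# Accept a file path or raw text: anything containing a newline or '>' that
# is not an existing file is treated as text.
slurp_lines <- function(path_or_text) {
  if (length(path_or_text) == 1 && !nzchar(trimws(path_or_text))) {
    return(character(0))
  }
  if (length(path_or_text) == 1 && !grepl("[\n>]", path_or_text) &&
      !file.exists(path_or_text)) {
    abort_format(paste0("file not found: ", path_or_text))
  }
  if (length(path_or_text) == 1 && file.exists(path_or_text)) {
    return(readLines(path_or_text, warn = FALSE))
  }
  unlist(strsplit(path_or_text, "\n", fixed = TRUE), use.names = FALSE)
}

read_file_lines <- function(path, what) {
  if (!file.exists(path)) {
    abort_format(paste0(what, " file not found: ", path))
  }
  readLines(path, warn = FALSE)
}
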