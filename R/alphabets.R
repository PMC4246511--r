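# Canonical alphabets and index helpers. The amino-acid feature order is
# alphabetical one-letter order everywhere in this package; PSSM files keep
# their native PSI-BLAST column order inside `pssm_profile` objects and are
# remapped to canonical order at the characterizer boundary.

#' Canonical symbol orders
#'
#' `aa_alphabet()` returns the 20 standard residues in the package's fixed
#' (alphabetical) feature order; `ss3_alphabet()` the three secondary
#' structure classes in (H, E, C) order; `sa2_alphabet()` the two solvent
#' accessibility classes in (b = buried, e = exposed) order.
#'
#' @return A character vector of single-letter symbols.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() AA20

#' @rdname aa_alphabet
#' @export
ss3_alphabet <- function() SS3

#' @rdname aa_alphabet
#' @export
sa2_alphabet <- function() SA2

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
SS3 <- c("H", "E", "C")
SA2 <- c("b", "e")

# Column order of PSI-BLAST ASCII PSSM files (both 20-column blocks).
PSIBLAST_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# DSSP 8-state alphabet; " " is loop.
DSSP8 <- c("H", "G", "I", "E", "B", "T", "S", " ")

space_alphabet <- function(space) {
  switch(space,
    AA20 = AA20,
    SS3 = SS3,
    SA2 = SA2,
    abort(paste0("unknown encoding space '", space, "'"),
      class = "protchar_error_domain")
  )
}

abort_alphabet <- function(symbol, context) {
  abort(
    paste0("illegal symbol '", symbol, "' in ", context),
    class = "protchar_error_alphabet"
  )
}

abort_format <- function(msg) abort(msg, class = "protchar_error_format")
abort_domain <- function(msg) abort(msg, class = "protchar_error_domain")

# Normalize a raw amino-acid string: upper-case, strip whitespace, map the
# ambiguity / non-standard codes B, Z, U, O (and J) to 'X'. Errors on any
# character outside the 20-letter alphabet plus X.
normalize_sequence <- function(x, record = "sequence") {
  x <- toupper(gsub("[[:space:]]", "", x))
  x <- chartr("BZUOJ", "XXXXX", x)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), c(AA20, "X"))
  if (length(bad) > 0) {
    abort_alphabet(bad[[1]], paste0("record '", record, "'"))
  }
  x
}

seq_chars <- function(x) strsplit(x, "")[[1]]

# Infer SS3 vs SA2 from the observed symbols of an annotation string;
# ambiguous alphabets (e.g. all-'E') need an explicit kind.
infer_annotation_kind <- function(symbols) {
  u <- unique(seq_chars(symbols))
  in_ss3 <- all(u %in% SS3)
  in_sa2 <- all(u %in% SA2)
  if (in_ss3 && !in_sa2) return("SS3")
  if (in_sa2 && !in_ss3) return("SA2")
  if (in_ss3 && in_sa2) return(NA_character_)
  abort_alphabet(setdiff(u, c(SS3, SA2))[[1]], "annotation string")
}

check_annotation <- function(symbols, kind) {
  alpha <- space_alphabet(kind)
  bad <- setdiff(unique(seq_chars(symbols)), alpha)
  if (length(bad) > 0) abort_alphabet(bad[[1]], paste0(kind, " annotation"))
  invisible(symbols)
}
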