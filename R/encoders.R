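#' Orthogonal (one-hot) encoding of residue and annotation symbols
#'
#' Encodes a single symbol as a 0/1 indicator vector with no artificial
#' ordering imposed on the categories: residues over the 20-letter canonical
#' order (`hot_encode_aa`), 3-state secondary structure over (H, E, C)
#' (`hot_encode_ss`) and 2-state solvent accessibility over (b, e)
#' (`hot_encode_sa`). Helix therefore encodes as `1 0 0` and coil as
#' `0 0 1`. The unknown residue `X` encodes as the all-zero length-20
#' vector, preserving the 20-column feature space.
#'
#' @param aa,ss,sa A single symbol from the relevant alphabet.
#' @return A named numeric 0/1 vector of length 20, 3 or 2.
#' @export
#' @examples
#' hot_encode_ss("H")
#' hot_encode_aa("X")
hot_encode_aa <- function(aa) {
  if (!is.character(aa) || length(aa) != 1 || nchar(aa) != 1) {
    abort_domain("hot_encode_aa expects a single residue symbol")
  }
  aa <- toupper(aa)
  v <- stats::setNames(numeric(20), AA20)
  if (aa == "X") return(v)
  if (!aa %in% AA20) abort_alphabet(aa, "AA20 encoding")
  v[[aa]] <- 1
  v
}

#' @rdname hot_encode_aa
#' @export
hot_encode_ss <- function(ss) {
  hot_one(ss, SS3, "SS3 encoding")
}

#' @rdname hot_encode_aa
#' @export
hot_encode_sa <- function(sa) {
  hot_one(sa, SA2, "SA2 encoding")
}

hot_one <- function(symbol, alphabet, context) {
  if (!is.character(symbol) || length(symbol) != 1 || nchar(symbol) != 1) {
    abort_domain(paste0(context, " expects a single symbol"))
  }
  if (!symbol %in% alphabet) abort_alphabet(symbol, context)
  v <- stats::setNames(numeric(length(alphabet)), alphabet)
  v[[symbol]] <- 1
  v
}

#' One-hot encode a whole string
#'
#' Applies the single-symbol encoder for `space` to every position of `s`,
#' preserving order.
#'
#' @param s A sequence or annotation string.
#' @param space `"AA20"`, `"SS3"` or `"SA2"`.
#' @return A numeric matrix with one row per symbol and the space's
#'   alphabet as column names; zero rows for the empty string.
#' @export
#' @examples
#' encode_string("HC", "SS3")
encode_string <- function(s, space = c("AA20", "SS3", "SA2")) {
  space <- match.arg(space)
  alpha <- space_alphabet(space)
  chars <- seq_chars(s)
  m <- matrix(0, nrow = length(chars), ncol = length(alpha),
    dimnames = list(NULL, alpha))
  encoder <- switch(space,
    AA20 = hot_encode_aa, SS3 = hot_encode_ss, SA2 = hot_encode_sa)
  for (i in seq_along(chars)) {
    m[i, ] <- tryCatch(encoder(chars[[i]]), protchar_error_alphabet = function(e) {
      abort(paste0(conditionMessage(e), " (position ", i, ")"),
        class = "protchar_error_alphabet")
    })
  }
  m
}
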