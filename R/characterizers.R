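#' Symbol composition of a sequence or annotation string
#'
#' `aa_composition()` returns the fraction of each of the 20 residues in a
#' protein sequence (unknown `X` residues are excluded from both numerator
#' and denominator); `ss_composition()` and `sa_composition()` do the same
#' for 3-state secondary structure and 2-state solvent accessibility
#' strings. Fractions are reported in the canonical order of each space and
#' sum to 1.
#'
#' @param seq,ss,sa A non-empty string over the relevant alphabet.
#' @return A `composition` tibble with columns `symbol` and `fraction` and a
#'   `space` attribute.
#' @export
#' @examples
#' aa_composition("ACDC")
#' ss_composition("HHEC")
aa_composition <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) {
    abort_domain("aa_composition expects a non-empty sequence string")
  }
  seq <- normalize_sequence(seq, record = "composition input")
  chars <- seq_chars(seq)
  chars <- chars[chars != "X"]
  if (length(chars) == 0) {
    abort_domain("sequence contains only unknown ('X') residues")
  }
  composition_of(chars, AA20, "AA20")
}

#' @rdname aa_composition
#' @export
ss_composition <- function(ss) {
  if (!is.character(ss) || length(ss) != 1 || !nzchar(ss)) {
    abort_domain("ss_composition expects a non-empty SS3 string")
  }
  check_annotation(ss, "SS3")
  composition_of(seq_chars(ss), SS3, "SS3")
}

#' @rdname aa_composition
#' @export
sa_composition <- function(sa) {
  if (!is.character(sa) || length(sa) != 1 || !nzchar(sa)) {
    abort_domain("sa_composition expects a non-empty SA2 string")
  }
  check_annotation(sa, "SA2")
  composition_of(seq_chars(sa), SA2, "SA2")
}

composition_of <- function(chars, alphabet, space) {
  counts <- table(factor(chars, levels = alphabet))
  out <- tibble(
    symbol = alphabet,
    fraction = as.numeric(counts) / length(chars)
  )
  attr(out, "space") <- space
  class(out) <- c("composition", class(out))
  out
}

#' Shannon entropy of a probability vector
#'
#' Computes \eqn{-\sum_i p_i \log_2 p_i} in bits, with the convention
#' \eqn{0 \cdot \log 0 = 0}. The input must be a probability distribution:
#' non-negative entries summing to 1 (within 1e-6).
#'
#' @param p Numeric vector of probabilities.
#' @return Entropy in bits (a single non-negative number).
#' @export
#' @examples
#' calculate_entropy(rep(0.25, 4)) # 2 bits
calculate_entropy <- function(p) {
  if (!is.numeric(p) || length(p) == 0) {
    abort_domain("calculate_entropy expects a numeric probability vector")
  }
  if (any(p < 0)) abort_domain("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) {
    abort_domain(paste0("probabilities sum to ", sum(p), ", not 1"))
  }
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

#' Pearson correlation of two feature vectors
#'
#' Sample Pearson correlation coefficient. A constant vector has no defined
#' correlation, so zero variance in either input is an error rather than a
#' silent `NaN`.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A single value in \[-1, 1\].
#' @export
calculate_r <- function(x, y) {
  if (length(x) != length(y)) {
    abort_domain("calculate_r: vectors differ in length")
  }
  if (length(x) < 2) abort_domain("calculate_r needs length >= 2")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort(
      "correlation undefined: an input vector has zero variance",
      class = "protchar_error_undefined_correlation"
    )
  }
  cor(x, y)
}

#' Cosine similarity of two feature vectors
#'
#' \eqn{x \cdot y / (\lVert x\rVert \, \lVert y\rVert)}.
#'
#' @param x,y Numeric vectors of equal length >= 1 with non-zero norm.
#' @return A single value in \[-1, 1\].
#' @export
calculate_cosine <- function(x, y) {
  if (length(x) != length(y)) {
    abort_domain("calculate_cosine: vectors differ in length")
  }
  if (length(x) < 1) abort_domain("calculate_cosine needs length >= 1")
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) abort_domain("cosine undefined for a zero-norm vector")
  sum(x * y) / (nx * ny)
}

# Per-symbol numeric value in [0,1] for the power mean, by scale name.
ordered_mean_values <- function(s, scale) {
  if (scale %in% c("hydrophobicity", paste0("atchley", 1:5))) {
    chars <- seq_chars(normalize_sequence(s, record = "ordered mean input"))
    if (scale == "hydrophobicity") {
      h <- hydrophobicity_vector()
      v <- minmax(h, min(h), max(h))
    } else {
      dim <- as.integer(substr(scale, 8, 8))
      m <- atchley_matrix()[, dim]
      v <- minmax(m, min(m), max(m))
    }
    vals <- unname(v[chars])
    vals[chars == "X"] <- mean(v)
    return(vals)
  }
  if (scale == "ss3") {
    check_annotation(s, "SS3")
    return(unname(c(H = 0, E = 0.5, C = 1)[seq_chars(s)]))
  }
  if (scale == "sa2") {
    check_annotation(s, "SA2")
    return(unname(c(b = 0, e = 1)[seq_chars(s)]))
  }
  abort_domain(paste0("unknown ordered-mean scale '", scale, "'"))
}

#' Generalized (power) mean of a scaled string
#'
#' Maps each symbol of `s` to a numeric value in \[0, 1\] via `scale`, then
#' returns the power mean of order `n`,
#' \eqn{M_n = ((1/L)\sum_i v_i^n)^{1/n}}. Order 1 is the arithmetic mean and
#' \eqn{M_n} is non-decreasing in `n` (power-mean inequality). For amino
#' acid strings the scale is the min-max scaled hydrophobicity scale or one
#' Atchley dimension (`"atchley1"` ... `"atchley5"`, with `X` mapping to the
#' scale mean); for annotation strings the fixed class indices are rescaled
#' to \[0, 1\] (`"ss3"`: H = 0, E = 0.5, C = 1; `"sa2"`: b = 0, e = 1).
#'
#' @param s A non-empty sequence or annotation string.
#' @param n Positive integer order of the mean.
#' @param scale `"hydrophobicity"` (default), `"atchley1"` ... `"atchley5"`,
#'   `"ss3"`, or `"sa2"`.
#' @return A single value in \[0, 1\].
#' @export
#' @examples
#' scaled_ordered_mean("ACDEFG", 1)
#' scaled_ordered_mean("HHEC", 2, scale = "ss3")
scaled_ordered_mean <- function(s, n, scale = "hydrophobicity") {
  if (!is.character(s) || length(s) != 1 || !nzchar(s)) {
    abort_domain("scaled_ordered_mean expects a non-empty string")
  }
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort_domain("scaled_ordered_mean: n must be a positive integer")
  }
  v <- ordered_mean_values(s, scale)
  mean(v^n)^(1 / n)
}
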