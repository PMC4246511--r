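#' Per-column residue profiles of an anchored alignment
#'
#' For each query position of an anchored MSA, computes the relative
#' frequency of each residue type over the column's non-gap rows, the gap
#' fraction, and the information content in bits,
#' \eqn{I = \log_2 20 - H(f)} where \eqn{H} is the Shannon entropy of the
#' column frequencies. Fully conserved columns carry \eqn{\log_2 20 \approx
#' 4.32} bits; columns at the uniform background carry 0. Unknown (`X`)
#' residues count toward the non-gap total and are spread uniformly over the
#' 20 frequencies.
#'
#' @param msa An `anchored_msa` from [read_anchored_msa()].
#' @return A `column_profiles` tibble with one row per query position:
#'   `position` (1-based), `residue` (query residue), one column per residue
#'   type in canonical order, `gap_fraction` and `information`.
#' @export
column_profiles <- function(msa) {
  if (!inherits(msa, "anchored_msa")) {
    abort_domain("column_profiles expects an anchored_msa")
  }
  chars <- do.call(rbind, lapply(msa$rows, seq_chars))
  n_pos <- ncol(chars)
  query <- seq_chars(msa$query$sequence)
  freq <- matrix(0, n_pos, 20, dimnames = list(NULL, AA20))
  gap_fraction <- numeric(n_pos)
  information <- numeric(n_pos)
  for (j in seq_len(n_pos)) {
    col <- chars[, j]
    gaps <- col == "-"
    gap_fraction[[j]] <- mean(gaps)
    col <- col[!gaps]
    if (length(col) == 0) {
      abort_domain(paste0("column ", j, " has no residues; anchored queries are gapless"))
    }
    counts <- table(factor(col[col != "X"], levels = AA20))
    f <- as.numeric(counts)
    f <- f + sum(col == "X") / 20 # spread unknowns uniformly
    f <- f / length(col)
    freq[j, ] <- f
    information[[j]] <- log2(20) - calculate_entropy(f)
  }
  profile_tibble(seq_len(n_pos), query, freq, gap_fraction, information)
}

#' Per-position profiles from a PSSM
#'
#' Converts the weighted observed percentages of a PSI-BLAST PSSM into
#' per-position residue frequencies (rows renormalized to sum to 1 and
#' remapped to canonical alphabetical residue order); the per-position
#' information is taken directly from the file's information column. An
#' all-zero percentage row (PSI-BLAST prints these at positions with no
#' aligned evidence) falls back to the uniform distribution with a warning.
#'
#' @param pssm A `pssm_profile` from [read_pssm()].
#' @return A `column_profiles` tibble (see [column_profiles()]);
#'   `gap_fraction` is 0 throughout.
#' @export
pssm_column_profiles <- function(pssm) {
  if (!inherits(pssm, "pssm_profile")) {
    abort_domain("pssm_column_profiles expects a pssm_profile")
  }
  n_pos <- length(pssm)
  pc <- pssm$percentages[, AA20, drop = FALSE] # remap to canonical order
  freq <- matrix(0, n_pos, 20, dimnames = list(NULL, AA20))
  for (j in seq_len(n_pos)) {
    row <- pc[j, ]
    if (sum(row) == 0) {
      warn(paste0("PSSM position ", j, ": all-zero percentages; using uniform frequencies"))
      freq[j, ] <- rep(1 / 20, 20)
    } else {
      freq[j, ] <- row / sum(row)
    }
  }
  profile_tibble(
    seq_len(n_pos), pssm$residues, freq,
    gap_fraction = rep(0, n_pos), information = pssm$information
  )
}

profile_tibble <- function(position, residue, freq, gap_fraction, information) {
  out <- dplyr::bind_cols(
    tibble(position = position, residue = residue),
    as_tibble(freq),
    tibble(gap_fraction = gap_fraction, information = information)
  )
  class(out) <- c("column_profiles", class(out))
  out
}

# length x 20 frequency matrix from a column_profiles tibble
profile_freq_matrix <- function(profiles) {
  m <- as.matrix(profiles[, AA20])
  rownames(m) <- NULL
  m
}
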