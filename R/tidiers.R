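#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PSSM into a long score table
#'
#' @param x A `pssm_profile`.
#' @param ... Unused.
#' @return A tibble with one row per (position, residue-column) pair:
#'   `position`, `residue` (query residue), `column` (scored residue type),
#'   `log_odds`, `percentage`.
#' @export
tidy.pssm_profile <- function(x, ...) {
  n <- length(x)
  tibble(
    position = rep(seq_len(n), each = 20),
    residue = rep(x$residues, each = 20),
    column = rep(colnames(x$log_odds), times = n),
    log_odds = as.vector(t(x$log_odds)),
    percentage = as.vector(t(x$percentages))
  )
}

#' @rdname tidy.pssm_profile
#' @return `glance()`: a one-row tibble with `length`, `mean_information`,
#'   `max_information`.
#' @export
glance.pssm_profile <- function(x, ...) {
  tibble(
    length = length(x),
    mean_information = mean(x$information),
    max_information = max(x$information)
  )
}

#' Tidy an anchored alignment into per-row records
#'
#' @param x An `anchored_msa`.
#' @param ... Unused.
#' @return A tibble with `row`, `aligned` (the aligned string), `gaps`
#'   (gap count) and `identity` (fraction of non-gap positions matching the
#'   query).
#' @export
tidy.anchored_msa <- function(x, ...) {
  q <- seq_chars(x$query$sequence)
  purrr::map_dfr(seq_along(x$rows), function(k) {
    chars <- seq_chars(x$rows[[k]])
    non_gap <- chars != "-"
    tibble(
      row = k,
      aligned = x$rows[[k]],
      gaps = sum(!non_gap),
      identity = if (any(non_gap)) mean(chars[non_gap] == q[non_gap]) else 0
    )
  })
}

#' @rdname tidy.anchored_msa
#' @return `glance()`: a one-row tibble with `rows`, `columns`,
#'   `mean_identity`, `gap_fraction`.
#' @export
glance.anchored_msa <- function(x, ...) {
  d <- tidy(x)
  tibble(
    rows = length(x$rows),
    columns = nchar(x$query$sequence),
    mean_identity = mean(d$identity),
    gap_fraction = sum(d$gaps) / (length(x$rows) * nchar(x$query$sequence))
  )
}

#' Tidy a secondary structure / accessibility prediction
#'
#' @param x An `ss_prediction`.
#' @param ... Unused.
#' @return A tibble with `position`, `aa`, `state` and, for PSIPRED input,
#'   the class probability columns `coil`, `helix`, `strand`.
#' @export
tidy.ss_prediction <- function(x, ...) {
  out <- tibble(
    position = seq_len(nchar(x$symbols)),
    aa = seq_chars(x$residues),
    state = seq_chars(x$symbols)
  )
  if (!is.null(x$probabilities)) {
    out <- dplyr::bind_cols(out, as_tibble(x$probabilities))
  }
  out
}
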