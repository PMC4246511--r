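#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a composition as a bar chart
#'
#' @param object A `composition` from [aa_composition()] and friends.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.composition <- function(object, ...) {
  space <- attr(object, "space")
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$symbol, levels = space_alphabet(space)),
    y = .data$fraction
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = paste0(space, " symbol"), y = "fraction",
      title = paste0(space, " composition")
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-position conservation of a profile
#'
#' Information content (bits) along the sequence; the dashed line marks the
#' `log2(20)` maximum of a fully conserved column.
#'
#' @param object A `column_profiles` tibble from [column_profiles()] or
#'   [pssm_column_profiles()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.column_profiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$information)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = log2(20), linetype = "dashed", color = "firebrick") +
    ggplot2::labs(
      x = "position", y = "information (bits)",
      title = "Per-position information content"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a PSSM as a log-odds heatmap
#'
#' @param object A `pssm_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pssm_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$position,
    y = factor(.data$column, levels = rev(AA20)),
    fill = .data$log_odds
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "position", y = "residue type", fill = "log-odds") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
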