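# Plot helpers for prediction tables.

#' Bar chart of per-family prediction counts
#'
#' @param predictions Prediction tibble from [classify_proteins()] /
#'   [classify_batch()].
#' @param top Show at most this many families, largest first (default 25).
#' @return A ggplot object: distinct sequences per family, filled by
#'   regulator category.
#' @export
plot_family_counts <- function(predictions, top = 25) {
  df <- dplyr::summarise(
    dplyr::group_by(predictions, .data$family, .data$category),
    n_sequences = dplyr::n_distinct(.data$sequence_id), .groups = "drop"
  )
  df <- utils::head(dplyr::arrange(df, dplyr::desc(.data$n_sequences)), top)
  df$family <- stats::reorder(df$family, df$n_sequences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$n_sequences,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "sequences assigned",
                  fill = "category",
                  title = "Predicted family membership") +
    ggplot2::theme_minimal()
}
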