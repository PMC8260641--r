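#' Plot the attention-category distribution by study class
#'
#' A stacked-bar view of the category-by-class crosstab, mirroring the
#' usual presentation of registry screening results: one bar per study
#' class, filled by sex/gender attention category.
#'
#' @param df Analysis frame from [analysis_frame()].
#' @return A ggplot object.
#' @export
plot_category_by_type <- function(df) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_category_by_type() requires the ggplot2 package",
      call. = FALSE
    )
  }
  dat <- dplyr::count(df,
    label = factor(.data$label, levels = .label_levels),
    category = factor(.data$category, levels = rev(.category_levels))
  )
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$label, y = .data$n, fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Blues", direction = -1) +
    ggplot2::labs(
      x = NULL, y = "Registrations",
      fill = "S/G attention"
    ) +
    ggplot2::theme_minimal()
}
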