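#' Plot an index summary
#'
#' @param object an [summarize_survey()] result.
#' @param type `"species"` (use value and citation frequency per species),
#'   `"icf"` (informant consensus factor per ailment) or `"fidelity"`
#'   (species-by-ailment fidelity-level heatmap).
#' @param top_n number of species shown in the species panel.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ethno_summary
#' @export
autoplot.ethno_summary <- function(object, type = c("species", "icf",
                                                    "fidelity"),
                                   top_n = 15, ...) {
  type <- match.arg(type)
  if (type == "species") {
    d <- object$species |>
      arrange(desc(.data$uv)) |>
      head(top_n) |>
      mutate(species = stats::reorder(.data$species, .data$uv))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$uv, y = .data$species)) +
      ggplot2::geom_col(fill = "grey30") +
      ggplot2::labs(x = "use value (UR / N)", y = NULL,
                    title = "Most important species by use value") +
      ggplot2::theme_minimal()
  } else if (type == "icf") {
    d <- mutate(object$categories,
                category = stats::reorder(.data$category, .data$icf))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$icf, y = .data$category)) +
      ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$category),
                            colour = "grey60") +
      ggplot2::geom_point(size = 2) +
      ggplot2::xlim(0, 1) +
      ggplot2::labs(x = "informant consensus factor", y = NULL,
                    title = "Informant consensus by ailment category") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$cells,
                    ggplot2::aes(x = .data$category, y = .data$species,
                                 fill = .data$fl)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient(low = "grey90", high = "grey10",
                                   name = "FL (%)") +
      ggplot2::labs(x = NULL, y = NULL,
                    title = "Fidelity level by species and ailment") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  }
}

#' Bar chart of novel / divergent / corroborated counts
#'
#' @param classifications a [classify_uses()] result.
#' @return a ggplot object.
#' @export
plot_use_classification <- function(classifications) {
  d <- summarize_classifications(classifications)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$percent, "%")),
                       vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "species-uses",
                  title = "Local uses vs published literature") +
    ggplot2::theme_minimal()
}
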