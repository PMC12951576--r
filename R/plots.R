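# ggplot2 views of the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot ranked search results
#'
#' Shape versus ESP similarity for every scored library entry, colored by
#' total score, with the query self-match (if present) marked.
#'
#' @param object A `ringhop_results` tibble.
#' @param top_n Label the `top_n` highest-ranked molecules (default 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ringhop_results <- function(object, top_n = 5, ...) {
  df <- tibble::as_tibble(object)
  lab <- df[df$rank <= top_n, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shape, y = .data$esp)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$total), size = 2) +
    ggplot2::geom_point(
      data = df[df$is_query, , drop = FALSE],
      shape = 1, size = 4, stroke = 1
    ) +
    ggplot2::geom_text(
      data = lab, ggplot2::aes(label = .data$smiles),
      vjust = -0.8, size = 2.8, check_overlap = TRUE
    ) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 2)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "shape Tanimoto", y = "ESP similarity", colour = "total",
      title = paste0("bioisostere search: ", attr(object, "query"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment table
#'
#' Enrichment factor per cutoff on a log scale; the dashed line marks chance
#' performance (EF = 1).
#'
#' @param object An `enrichment_table` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$cutoff <- factor(df$cutoff, levels = df$cutoff)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$ef)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "ranked-list cutoff", y = "enrichment factor") +
    ggplot2::theme_minimal()
}

#' Plot the weight-optimization objective
#'
#' Pearson correlation of the weighted score with pIC50 as a function of the
#' shape weight, with the fitted optimum and the equal-weight point marked.
#'
#' @param object A `weight_fit` from [optimize_weights()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weight_fit <- function(object, ...) {
  w <- seq(0, 1, by = 0.01)
  r <- vapply(w, weight_objective, numeric(1), records = object$records)
  df <- tibble::tibble(w = w, r = r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$w, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$w_shape, colour = "firebrick") +
    ggplot2::geom_point(
      data = tibble::tibble(w = 0.5, r = object$r_equal), shape = 1, size = 3
    ) +
    ggplot2::labs(
      x = "shape weight (ESP weight = 1 - shape weight)",
      y = "Pearson r vs pIC50"
    ) +
    ggplot2::theme_minimal()
}
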