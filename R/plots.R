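#' Plate heat map of a per-well value
#'
#' Draws the standard 96-well plate view (rows A--H, columns 1--12) with
#' wells colored by the chosen value.
#'
#' @param scores A tibble with a `well_id` column and the value column.
#' @param value_col Column to color by (default `"score_after_qc"`).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_plate_heatmap <- function(scores, value_col = "score_after_qc",
                               title = NULL) {
  stopifnot("well_id" %in% names(scores), value_col %in% names(scores))
  df <- scores %>%
    mutate(row = factor(substr(.data$well_id, 1, 1), levels = rev(LETTERS[1:8])),
           col = factor(as.integer(substr(.data$well_id, 2, 3)), levels = 1:12))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data[[value_col]])) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_viridis_c(name = value_col) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' @describeIn run_screen Plate heat map of post-QC normalized scores.
#' @param object A `cilia_screen`.
#' @method autoplot cilia_screen
#' @export
autoplot.cilia_screen <- function(object, ...) {
  plot_plate_heatmap(object$scores, "score_after_qc",
                     title = paste0("Normalized disassembly score (",
                                    object$params$mode, ")"))
}

#' Ranked compound effect plot for a screen
#'
#' Shows each compound's directional effect size in rank order, with
#' called hits highlighted.
#'
#' @param screen A `cilia_screen` object.
#' @return A ggplot object.
#' @export
plot_screen_ranks <- function(screen) {
  stopifnot(inherits(screen, "cilia_screen"))
  ggplot2::ggplot(screen$hits,
                  ggplot2::aes(x = .data$rank, y = .data$effect_size,
                               color = .data$hit)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50", `TRUE` = "red3")) +
    ggplot2::labs(x = "Rank", y = "Effect size (screen direction)",
                  color = "Hit") +
    ggplot2::theme_minimal()
}
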