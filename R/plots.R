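#' Five-bin interaction-score heatmap
#'
#' Mutant x ligand tile plot of clipped interaction scores colored by the
#' five bins of [bin_for_heatmap()] (purple, blue, teal, green, yellow);
#' missing combinations are left white.
#'
#' @param scores Tibble with columns `mutant`, `ligand`, `score` (raw
#'   scores; clipped internally for display).
#' @return A ggplot object.
#' @export
plot_score_heatmap <- function(scores) {
  stopifnot(all(c("mutant", "ligand", "score") %in% names(scores)))
  scores$bin <- bin_for_heatmap(clip_score(scores$score))
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$ligand, y = .data$mutant,
                                       fill = .data$bin)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(values = heatmap_palette(),
                               name = "score", drop = FALSE,
                               na.value = "white") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Per-condition bar-with-points plot
#'
#' Group means as bars with SEM error bars and the individual per-cell or
#' per-well values overlaid as jittered points, the layout used for
#' quantification panels.
#'
#' @param df Data frame of observations.
#' @param value,group Column names (strings).
#' @return A ggplot object.
#' @export
plot_group_points <- function(df, value, group) {
  summ <- summarize_groups(df, value, group)
  ggplot2::ggplot() +
    ggplot2::geom_col(data = summ,
                      ggplot2::aes(x = .data$group, y = .data$mean),
                      fill = "grey80", color = "grey30", width = 0.7) +
    ggplot2::geom_errorbar(
      data = summ,
      ggplot2::aes(x = .data$group, ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.2, na.rm = TRUE) +
    ggplot2::geom_jitter(
      data = df,
      ggplot2::aes(x = .data[[group]], y = .data[[value]]),
      width = 0.15, size = 1, alpha = 0.6) +
    ggplot2::theme_classic() +
    ggplot2::labs(x = NULL, y = value)
}
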