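#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a model-recovery confusion matrix
#'
#' @param object A [run_recovery()] result.
#' @param ... Unused.
#' @return A ggplot: true model by best-fitting model, tile fill = row
#'   proportion.
#' @export
autoplot.recovery_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$best_model, y = .data$true_model,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "best-fitting model", y = "generating model",
                  fill = "row prop.",
                  title = sprintf("Model recovery accuracy %.3f",
                                  object$overall_accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot the top-ranked utility-maximizing conditions
#'
#' @param object An [cohens_d_map()] result.
#' @param n_top Number of top-ranked condition classes to show.
#' @param ... Unused.
#' @return A ggplot: summed pairwise effect size for the top condition
#'   classes, ambiguous (excluded) classes greyed.
#' @export
autoplot.effect_size_table <- function(object, n_top = 15, ...) {
  ranking <- rank_conditions(object, exclude_ambiguous = TRUE)
  ranking <- head(dplyr::arrange(ranking, dplyr::desc(.data$summed_d)), n_top)
  ranking$label <- sprintf("[%g, %g, %g]", ranking$c1, ranking$c2, ranking$c3)
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = stats::reorder(.data$label, .data$summed_d),
                               y = .data$summed_d,
                               fill = is.na(.data$rank))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#2c7fb8",
                                          `TRUE` = "grey70"),
                               labels = c(`FALSE` = "eligible",
                                          `TRUE` = "ambiguous"),
                               name = NULL) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "condition (sorted strengths)",
                  y = "summed |Cohen's d| over model pairs") +
    ggplot2::theme_minimal()
}

#' Plot simulated confidence against task difficulty
#'
#' @param object A z-scored [simulate_grid()] result.
#' @param ... Unused.
#' @return A ggplot: per-point mean z-scored confidence against the gap
#'   between the largest and second-largest strength, one line per model.
#' @export
autoplot.grid_simulation <- function(object, ...) {
  if (is.null(object$pooled)) {
    abort("Z-score the simulation first (see `zscore_confidence()`).")
  }
  s <- object$summary
  m <- as.matrix(s[, c("c1", "c2", "c3")])
  gap <- apply(m, 1L, function(r) {
    sr <- sort(r, decreasing = TRUE)
    sr[1] - sr[2]
  })
  df <- tibble::tibble(model = s$model, gap = gap,
                       conf_mean_z = s$conf_mean_z)
  df <- df |>
    dplyr::group_by(.data$model, .data$gap) |>
    dplyr::summarise(conf_mean_z = mean(.data$conf_mean_z),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gap, y = .data$conf_mean_z,
                                   color = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "strength gap (largest - second largest)",
                  y = "mean z-scored confidence", color = "model") +
    ggplot2::theme_minimal()
}
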