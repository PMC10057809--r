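# ggplot2 visualisations of the main result types.

#' Plot a smoothed trajectory
#'
#' One line per feature along the progression grid, faceted by block
#' (AS events vs RBPs).
#'
#' @param object A `trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory <- function(object, ...) {
  tab <- dplyr::bind_rows(
    tidyr::pivot_longer(
      tibble::as_tibble(t(object$X)) |> tibble::add_column(s = object$grid),
      -"s", names_to = "feature", values_to = "expression") |>
      tibble::add_column(block = "AS events"),
    tidyr::pivot_longer(
      tibble::as_tibble(t(object$U)) |> tibble::add_column(s = object$grid),
      -"s", names_to = "feature", values_to = "expression") |>
      tibble::add_column(block = "RBPs"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$s, y = .data$expression,
                                    colour = .data$feature)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~block, scales = "free_y") +
    ggplot2::labs(x = "pseudotime s", y = "smoothed expression")
}

#' Plot a pseudotime ordering
#'
#' Specimens by rank against score, coloured by state: epithelial specimens
#' should occupy the head of the trajectory and mesenchymal the tail.
#'
#' @param object A `pseudotime_ordering`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pseudotime_ordering <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  tab$state <- factor(tab$state, c(1L, 2L), c("epithelial", "mesenchymal"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$rank, y = .data$score,
                                    colour = .data$state)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pseudotime rank", y = "pseudotime score")
}

#' Plot an evaluation report across noise levels
#'
#' Mean +/- sd of each metric per realised-CV bin; the robustness view of
#' the benchmark.
#'
#' @param object An `evaluation_report` from [robustness_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  metrics <- intersect(c("rho", "rmse", "auc", "accuracy", "ppv", "matthews"),
                       colnames(object))
  tab <- tidyr::pivot_longer(tibble::as_tibble(object),
                             dplyr::all_of(metrics),
                             names_to = "metric", values_to = "value")
  grp <- if ("level" %in% colnames(tab)) "level" else "mu"
  agg <- dplyr::summarise(
    dplyr::group_by(tab, .data[[grp]], .data$metric),
    cv = mean(.data$cv), m = mean(.data$value, na.rm = TRUE),
    s = sd(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$cv, y = .data$m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$s,
                                      ymax = .data$m + .data$s), alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "realised coefficient of variation", y = "metric")
}

#' Plot a regulatory network as an arc-free edge table heat map
#'
#' Signed coefficient posterior means as source-by-target tiles.
#'
#' @param object A `regulatory_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regulatory_network <- function(object, ...) {
  if (nrow(object$edges) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = paste0("empty network (", object$state_tag, ")")))
  }
  ggplot2::ggplot(object$edges,
                  ggplot2::aes(x = .data$target, y = .data$source,
                               fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "target", y = "regulator",
                  title = paste0(object$state_tag, " state"),
                  fill = "coefficient") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
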