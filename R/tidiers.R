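# broom-style tidiers for the package's fitted objects.

#' @export
tidy.posterior_fit <- function(x, ...) {
  tibble::add_column(x$summary, target_id = x$target_id, .before = 1L)
}

#' @export
glance.posterior_fit <- function(x, ...) {
  tibble::tibble(target_id = x$target_id, target_type = x$target_type,
                 method = x$method, ci_level = x$ci_level,
                 n_draws = if (is.null(x$draws)) NA_integer_ else nrow(x$draws),
                 converged = x$converged, max_psrf = x$max_psrf)
}

#' @export
tidy.regulatory_network <- function(x, ...) {
  tibble::add_column(x$edges, state_tag = x$state_tag, .before = 1L)
}

#' @export
glance.regulatory_network <- function(x, ...) {
  tibble::tibble(state_tag = x$state_tag, n_nodes = nrow(x$nodes),
                 n_edges = nrow(x$edges),
                 n_activating = sum(x$edges$sign == "+"),
                 n_repressing = sum(x$edges$sign == "-"))
}

#' @export
tidy.pseudotime_ordering <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
tidy.emt_analysis <- function(x, ...) {
  dplyr::bind_rows(lapply(x$networks, tidy))
}

#' @export
glance.emt_analysis <- function(x, ...) {
  tibble::tibble(n_specimens = nrow(x$ordering),
                 n_selected_as = length(x$selected_as),
                 n_selected_rbp = length(x$selected_rbp),
                 boundary = x$boundary,
                 n_edges_epithelial = nrow(x$networks$epithelial$edges),
                 n_edges_mesenchymal = nrow(x$networks$mesenchymal$edges))
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network: %s state, %d nodes, %d edges>\n",
              x$state_tag, nrow(x$nodes), nrow(x$edges)))
  print(x$edges, n = 10)
  invisible(x)
}

#' @export
print.dyn_system <- function(x, ...) {
  cat(sprintf("<dyn_system: %d AS events, %d RBPs, %d nonzero interactions>\n",
              length(x$d), length(x$d_prime),
              sum(x$A != 0) + sum(x$B != 0) + sum(x$C != 0)))
  invisible(x)
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("<posterior_fit (%s) for %s [%s], %s%% CI>\n", x$method,
              x$target_id, x$target_type, format(100 * x$ci_level)))
  print(x$summary)
  invisible(x)
}
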