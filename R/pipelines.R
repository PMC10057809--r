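# End-to-end pipeline recipes tying the modules together: the full
# progression analysis, and the targeted single-gene analysis.

#' Full progression analysis of an AS / RBP expression pair
#'
#' Runs the complete workflow: clean both matrices, infer pseudotime from
#' the RBP profile, order and smooth both matrices, select the
#' top-scoring AS events and RBPs by trend analysis, fit separate
#' epithelial- and mesenchymal-state dynamical systems on the selected
#' features, call edges, and rank hubs.
#'
#' @param as_expr,rbp_expr Feature-by-specimen matrices (missing values
#'   allowed; they are imputed).
#' @param annot Annotation tibble (`specimen_id`, `state` in \{1, 2\}).
#' @param config A [run_config()].
#' @return An `emt_analysis` object: list with `ordering`, `trend_as`,
#'   `trend_rbp`, `selected_as`, `selected_rbp`, `trajectory`, `fits`
#'   (epithelial / mesenchymal), `networks`, `rankings`, `config`.
#' @export
run_emt_analysis <- function(as_expr, rbp_expr, annot, config = run_config()) {
  shared <- intersect(intersect(colnames(as_expr), colnames(rbp_expr)),
                      annot$specimen_id)
  if (length(shared) < 10L) stop("data error: matrices share fewer than 10 annotated specimens")
  as_expr <- preprocess_matrix(as_expr[, shared, drop = FALSE], k = config$knn_k)
  rbp_expr <- preprocess_matrix(rbp_expr[, shared, drop = FALSE], k = config$knn_k)

  ordering <- infer_pseudotime(rbp_expr, annot, n_neighbors = config$n_neighbors,
                               seed = substream(config$seed, 7L))
  om <- order_matrices(as_expr, rbp_expr, ordering)
  grid_size <- config$grid_size %||% length(om$scores)
  traj <- smooth_trajectory(om$as_expr, om$rbp_expr, om$scores,
                            bandwidth = config$bandwidth, grid_size = grid_size)

  trend_as <- trend_table(traj$X, traj$grid)
  trend_rbp <- trend_table(traj$U, traj$grid)
  sel_as <- select_top(trend_as, min(config$top_as, nrow(trend_as)))
  sel_rbp <- select_top(trend_rbp, min(config$top_rbp, nrow(trend_rbp)))
  traj_sel <- new_trajectory(grid = traj$grid,
                             X = traj$X[sel_as, , drop = FALSE],
                             U = traj$U[sel_rbp, , drop = FALSE],
                             as_ids = sel_as, rbp_ids = sel_rbp)

  states <- fit_state_systems(traj_sel, ordering, method = "lasso",
                              mcmc = config$mcmc, seed = config$seed,
                              ci_level = config$ci_level)
  networks <- list(epithelial = states$epithelial$network,
                   mesenchymal = states$mesenchymal$network)
  rankings <- list(
    clique_centrality = lapply(networks, clique_centrality_ranking),
    out_degree = lapply(networks, out_degree_ranking))
  structure(list(ordering = ordering, trend_as = trend_as, trend_rbp = trend_rbp,
                 selected_as = sel_as, selected_rbp = sel_rbp,
                 trajectory = traj_sel,
                 fits = list(epithelial = states$epithelial$fits,
                             mesenchymal = states$mesenchymal$fits),
                 networks = networks, rankings = rankings,
                 boundary = states$boundary, config = config),
            class = "emt_analysis")
}

#' Targeted analysis of one gene's splicing events
#'
#' For a small set of AS events of a single gene and a named set of
#' candidate regulator RBPs: pseudotime is inferred from the full RBP
#' matrix, events whose expression does not differ between the two states
#' (two-sided Wilcoxon rank-sum p >= alpha) are dropped, and the two-state
#' dynamical systems are fitted on the surviving events plus the
#' candidate RBPs.
#'
#' @param as_events Event-by-specimen matrix restricted to the gene's
#'   events (>= 2 events).
#' @param rbp_expr Full RBP matrix used for pseudotime.
#' @param regulators Character vector of RBP feature IDs to model (>= 1).
#' @param annot Annotation tibble.
#' @param alpha Significance level of the group-difference filter.
#' @param config A [run_config()].
#' @return A `targeted_analysis` object: `filter` (p-value table),
#'   `kept_events`, `ordering`, `fits`, `networks`, `config`.
#' @export
run_targeted_analysis <- function(as_events, rbp_expr, regulators, annot,
                                  alpha = 0.05, config = run_config()) {
  stopifnot(nrow(as_events) >= 2L, length(regulators) >= 1L)
  miss <- setdiff(regulators, rownames(rbp_expr))
  if (length(miss) > 0L) stop("regulators absent from the RBP matrix: ",
                              paste(miss, collapse = ", "))
  shared <- intersect(intersect(colnames(as_events), colnames(rbp_expr)),
                      annot$specimen_id)
  as_events <- preprocess_matrix(as_events[, shared, drop = FALSE], k = config$knn_k)
  rbp_expr <- preprocess_matrix(rbp_expr[, shared, drop = FALSE], k = config$knn_k)
  regulators <- intersect(regulators, rownames(rbp_expr))

  filt <- group_difference_filter(as_events, annot, alpha = alpha)
  kept <- filt$feature_id[filt$retained]
  if (length(kept) == 0L) {
    stop("data error: every event was filtered out; p-values: ",
         paste(sprintf("%s=%.3g", filt$feature_id, filt$p_value), collapse = ", "))
  }

  ordering <- infer_pseudotime(rbp_expr, annot, n_neighbors = config$n_neighbors,
                               seed = substream(config$seed, 7L))
  om <- order_matrices(as_events[kept, , drop = FALSE],
                       rbp_expr[regulators, , drop = FALSE], ordering)
  grid_size <- config$grid_size %||% length(om$scores)
  traj <- smooth_trajectory(om$as_expr, om$rbp_expr, om$scores,
                            bandwidth = config$bandwidth, grid_size = grid_size)
  states <- fit_state_systems(traj, ordering, method = "lasso",
                              mcmc = config$mcmc, seed = config$seed,
                              ci_level = config$ci_level)
  structure(list(filter = filt, kept_events = kept, ordering = ordering,
                 fits = list(epithelial = states$epithelial$fits,
                             mesenchymal = states$mesenchymal$fits),
                 networks = list(epithelial = states$epithelial$network,
                                 mesenchymal = states$mesenchymal$network),
                 boundary = states$boundary, config = config),
            class = "targeted_analysis")
}
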