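# Hub ranking of inferred networks (maximal clique centrality, out-degree)
# and the group-difference feature filter.

#' Rank nodes by maximal clique centrality
#'
#' The directed network is symmetrised (an undirected edge exists if either
#' direction is present); a node's clique centrality is the sum over the
#' maximal cliques containing it of `(|clique| - 1)!`. A node belonging to
#' no clique of size >= 2 receives its degree (0 for isolated nodes). This
#' is the "MCC" hub metric of network analysis; it is unrelated to the
#' Matthews correlation coefficient used by the benchmark metrics.
#'
#' @param net A nonempty `regulatory_network`.
#' @return Tibble `node`, `score`, `rank` (descending score, lexicographic
#'   tie-break).
#' @export
clique_centrality_ranking <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  nodes <- net$nodes$id
  if (length(nodes) == 0L) stop("network has no nodes")
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = nodes))
  g <- igraph::simplify(g)
  cl <- igraph::max_cliques(g, min = 2L)
  score <- setNames(numeric(length(nodes)), nodes)
  in_clique <- setNames(logical(length(nodes)), nodes)
  for (cc in cl) {
    members <- names(cc)
    score[members] <- score[members] + factorial(length(members) - 1L)
    in_clique[members] <- TRUE
  }
  deg <- igraph::degree(g)[nodes]
  score[!in_clique] <- deg[!in_clique]
  out <- tibble::tibble(node = nodes, score = unname(score))
  out$rank <- rank_by_score(out$score, out$node)
  dplyr::arrange(out, .data$rank)
}

#' Rank nodes by out-degree
#'
#' @param net A `regulatory_network`.
#' @return Tibble `node`, `out_degree`, `rank` (descending, lexicographic
#'   tie-break).
#' @export
out_degree_ranking <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  nodes <- net$nodes$id
  deg <- vapply(nodes, function(v) sum(net$edges$source == v), numeric(1))
  out <- tibble::tibble(node = nodes, out_degree = unname(deg))
  out$rank <- rank_by_score(out$out_degree, out$node)
  dplyr::arrange(out, .data$rank)
}

#' Filter features by a two-state group difference
#'
#' Per feature, a two-sided Wilcoxon rank-sum test comparing state-1 versus
#' state-2 specimens: exact enumeration when both groups have at most 10
#' specimens and no ties, the normal approximation with tie correction
#' otherwise. Features with `p < alpha` are retained; `alpha >= 1` keeps
#' every feature (a p-value can equal 1 exactly).
#'
#' @param expr Feature-by-specimen matrix (raw or reconstructed expression).
#' @param annot Annotation tibble with `specimen_id` and `state`; both
#'   states need >= 2 specimens among the matrix columns.
#' @param alpha Significance level. Default 0.05.
#' @return Tibble `feature_id`, `p_value`, `retained`, ordered as the input
#'   rows.
#' @export
group_difference_filter <- function(expr, annot, alpha = 0.05) {
  validate_annotation(annot)
  state <- annot$state[match(colnames(expr), annot$specimen_id)]
  if (anyNA(state)) stop("all matrix specimens must be annotated")
  g1 <- state == 1L; g2 <- state == 2L
  if (sum(g1) < 2L || sum(g2) < 2L) stop("each state needs at least 2 specimens")
  use_exact <- sum(g1) <= 10L && sum(g2) <= 10L
  p <- vapply(seq_len(nrow(expr)), function(i) {
    x <- expr[i, g1]; y <- expr[i, g2]
    suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = use_exact)$p.value)
  }, numeric(1))
  tibble::tibble(feature_id = rownames(expr), p_value = p,
                 retained = if (alpha >= 1) rep(TRUE, length(p)) else p < alpha)
}
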