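# Monotone-trend scoring of smoothed features along pseudotime and top-K
# selection of progression-associated AS events and RBPs.

#' Trend score of one smoothed series
#'
#' Fits the series to a straight line `L * s + C` by ordinary least
#' squares, detrends (`H(s) = X(s) - (L s + C)`), takes the sample standard
#' deviation `V = sd(H)`, and scores `R = |L / V|`: large when the series
#' changes systematically along progression relative to its fluctuation.
#' A perfectly linear, non-constant series has `V = 0` and scores `Inf`
#' (ranks first); a constant series scores 0.
#'
#' @param series Numeric values on the grid (>= 3 points, finite).
#' @param grid Progression states of the same length.
#' @return A one-row tibble: `L`, `C`, `V`, `R`.
#' @export
trend_score <- function(series, grid) {
  if (length(series) < 3L) stop("need at least 3 grid points")
  stopifnot(length(series) == length(grid), all(is.finite(series)))
  fit <- lm(series ~ grid)
  L <- unname(coef(fit)[2L]); C <- unname(coef(fit)[1L])
  H <- unname(stats::residuals(fit))
  V <- sd(H)
  # degeneracy at floating-point resolution: an exactly linear series leaves
  # only rounding noise in the residuals
  tol <- 1e-10 * max(abs(series), 1)
  if (V <= tol) {
    R <- if (abs(L) <= tol) 0 else Inf
    V <- 0
  } else {
    R <- abs(L / V)
  }
  tibble::tibble(L = L, C = C, V = V, R = R)
}

#' Trend table for a whole trajectory block
#'
#' Applies [trend_score()] to every feature of a smoothed trajectory block
#' and ranks features by descending score (ties broken by feature ID).
#'
#' @param block Feature-by-grid matrix of smoothed expression.
#' @param grid Progression grid.
#' @return Tibble: `feature_id`, `L`, `C`, `V`, `R`, `rank`.
#' @export
trend_table <- function(block, grid) {
  res <- purrr::map_dfr(seq_len(nrow(block)), function(i) trend_score(block[i, ], grid))
  res <- tibble::add_column(res, feature_id = rownames(block), .before = 1L)
  res$rank <- rank_by_score(res$R, res$feature_id)
  dplyr::arrange(res, .data$rank)
}

rank_by_score <- function(R, ids) {
  ord <- order(-R, ids)
  match(seq_along(R), ord)
}

#' Select the top-k features by trend score
#'
#' @param results A trend table (from [trend_table()]).
#' @param k How many features to keep (<= number of rows).
#' @return Character vector of k feature IDs, descending score, ties broken
#'   lexicographically.
#' @export
select_top <- function(results, k) {
  if (k > nrow(results)) stop("k exceeds the number of scored features")
  results$feature_id[order(results$rank)][seq_len(k)]
}
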