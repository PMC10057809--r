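# Pseudotime inference from cross-sectional RBP expression plus binary state
# labels; shared ordering of both matrices; kernel smoothing onto a uniform
# progression grid.

#' Infer a pseudotime ordering of specimens
#'
#' Orders cross-sectional specimens along a one-dimensional progression
#' using the whole RBP expression profile and the binary epithelial (1) /
#' mesenchymal (2) state labels:
#'
#' 1. features are standardised to zero mean / unit variance;
#' 2. a symmetric k-nearest-neighbour graph over specimens is built
#'    (Euclidean distance) with Gaussian edge weights; disconnected
#'    components are joined by their minimal bridging edges;
#' 3. the leading nontrivial eigenvector of the graph's random-walk
#'    transition structure (the first diffusion component) gives a raw score;
#' 4. the score is oriented so epithelial specimens sit at the low end
#'    (mean score of state 1 <= mean score of state 2) and min-max rescaled
#'    to \[0, 1\].
#'
#' @param rbp_expr Complete RBP feature-by-specimen matrix (post-imputation).
#' @param annot Annotation tibble with `specimen_id` and `state`; specimens
#'   absent from the annotation are dropped with a warning.
#' @param n_neighbors Neighbours for the kNN graph. Default 15.
#' @param seed Integer seed (consumed only to perturb exactly tied
#'   degenerate scores).
#' @return A `pseudotime_ordering`: tibble with columns `specimen_id`,
#'   `score` (in \[0, 1\]), `state`, and `rank`, plus attribute `order`
#'   (the permutation sorting scores ascending, barcode-lexicographic on
#'   ties).
#' @export
infer_pseudotime <- function(rbp_expr, annot, n_neighbors = 15L, seed = 1L) {
  stopifnot(is.matrix(rbp_expr))
  if (anyNA(rbp_expr)) stop("expression must be complete (impute first)")
  validate_annotation(annot)
  ids <- colnames(rbp_expr)
  missing_annot <- setdiff(ids, annot$specimen_id)
  if (length(missing_annot) > 0L) {
    warning(length(missing_annot), " specimens missing from the annotation were dropped")
    rbp_expr <- rbp_expr[, setdiff(ids, missing_annot), drop = FALSE]
    ids <- colnames(rbp_expr)
  }
  state <- annot$state[match(ids, annot$specimen_id)]
  n <- length(ids)
  if (length(unique(state)) < 2L) stop("both states must be present for pseudotime inference")
  if (min(table(state)) < 2L) stop("need at least 2 specimens per state")
  if (n < n_neighbors + 1L) stop("fewer specimens than n_neighbors + 1")

  # standardise features; constant features carry no signal and are dropped
  sds <- apply(rbp_expr, 1L, sd)
  z <- (rbp_expr[sds > 0, , drop = FALSE] - rowMeans(rbp_expr[sds > 0, , drop = FALSE])) /
    sds[sds > 0]
  if (nrow(z) == 0L) stop("all features are constant")

  dmat <- as.matrix(stats::dist(t(z)))
  raw <- diffusion_score(dmat, n_neighbors)
  if (max(raw) - min(raw) <= 0) {  # fully degenerate geometry: break ties
    raw <- raw + with_seed(seed, runif(n, -1e-9, 1e-9))
  }
  # rank-uniformise: the diffusion coordinate orders specimens but is an
  # arbitrarily warped monotone function of progression; the empirical rank
  # transform places the ordered specimens evenly on [0, 1], matching the
  # uniform-sampling view of cross-sectional designs and keeping downstream
  # derivative estimates free of score-density distortion.
  score <- numeric(n)
  score[order(raw, ids)] <- (seq_len(n) - 1) / (n - 1)
  # orient on the final scale: epithelial head, mesenchymal tail
  if (mean(score[state == 1L]) > mean(score[state == 2L])) score <- 1 - score
  ord <- order(score, ids)
  out <- tibble::tibble(specimen_id = ids, score = score, state = state)
  out$rank <- match(seq_len(n), ord)
  attr(out, "order") <- ord
  class(out) <- c("pseudotime_ordering", class(out))
  out
}

# First nontrivial diffusion component of a symmetric kNN graph given a
# distance matrix. Deterministic; eigen sign fixed later by state labels.
diffusion_score <- function(dmat, k) {
  n <- nrow(dmat)
  k <- min(k, n - 1L)
  W <- matrix(0, n, n)
  sigma <- 0
  nn_d <- numeric(0)
  for (i in seq_len(n)) {
    nb <- order(dmat[i, ])[2:(k + 1L)]
    nn_d <- c(nn_d, dmat[i, nb])
    W[i, nb] <- dmat[i, nb]
  }
  # symmetrize: edge if either direction present
  D <- pmax(W, t(W))
  sigma <- stats::median(nn_d)
  if (sigma <= 0) sigma <- 1
  W <- ifelse(D > 0, exp(-(D / sigma)^2), 0)

  # bridge disconnected components with minimal inter-component edges
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  while (length(unique(comp)) > 1L) {
    best <- c(Inf, 0L, 0L)
    for (ci in unique(comp)) {
      a <- which(comp == ci); b <- which(comp != ci)
      sub <- dmat[a, b, drop = FALSE]
      m <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
      if (sub[m[1L], m[2L]] < best[1L]) best <- c(sub[m[1L], m[2L]], a[m[1L]], b[m[2L]])
    }
    i <- best[2L]; j <- best[3L]
    W[i, j] <- W[j, i] <- exp(-(best[1L] / sigma)^2)
    comp[comp == comp[j]] <- comp[i]
  }

  deg <- rowSums(W)
  dis <- 1 / sqrt(deg)
  Msym <- W * (dis %o% dis)
  ev <- eigen(Msym, symmetric = TRUE)
  # leading eigenvector is the stationary (trivial) direction; take the next
  ev$vectors[, 2L] * dis
}

#' Re-index both expression matrices by a pseudotime ordering
#'
#' @param as_expr,rbp_expr Matrices sharing the ordering's barcodes.
#' @param ordering A `pseudotime_ordering`.
#' @return List with `as_expr`, `rbp_expr` (columns in ascending pseudotime,
#'   barcodes retained) and `scores` (sorted pseudotime values).
#' @export
order_matrices <- function(as_expr, rbp_expr, ordering) {
  stopifnot(inherits(ordering, "pseudotime_ordering"))
  for (m in list(as_expr, rbp_expr)) {
    off <- c(setdiff(colnames(m), ordering$specimen_id),
             setdiff(ordering$specimen_id, colnames(m)))
    if (length(off) > 0L) {
      stop("barcode mismatch between matrix and ordering: ",
           paste(head(off, 5L), collapse = ", "))
    }
  }
  ord_ids <- ordering$specimen_id[attr(ordering, "order")]
  list(as_expr = as_expr[, ord_ids, drop = FALSE],
       rbp_expr = rbp_expr[, ord_ids, drop = FALSE],
       scores = ordering$score[attr(ordering, "order")])
}

#' Smooth ordered expression onto a uniform progression grid
#'
#' Per feature, Nadaraya-Watson kernel regression with a Gaussian kernel of
#' standard deviation `bandwidth`, evaluated on a uniform grid of
#' `grid_size` points spanning \[0, 1\]. Outputs are clipped at 0, matching
#' the nonnegative expression scale.
#'
#' The default bandwidth is one mean specimen spacing,
#' `(max(scores) - min(scores)) / (n - 1)`: near-interpolation, so that at
#' low noise the smoothed curves track the data closely and derivative-based
#' coefficient estimation downstream is not distorted by smoothing bias.
#' Raise it for noisy data. The trajectory records the bandwidth and
#' smoothing support so that fitting functions can exclude the
#' boundary-biased region (see [fit_system()]).
#'
#' @param ordered_as,ordered_rbp Matrices with columns in ascending
#'   pseudotime.
#' @param scores Ascending pseudotime values matching the columns.
#' @param bandwidth Positive kernel bandwidth on the \[0, 1\] scale, or
#'   `NULL` for the spacing-based default.
#' @param grid_size Number of grid points; default = number of specimens.
#' @return A `trajectory` (`grid`, `X`, `U`, feature ids, `bandwidth`,
#'   `support`).
#' @export
smooth_trajectory <- function(ordered_as, ordered_rbp, scores,
                              bandwidth = NULL, grid_size = length(scores)) {
  stopifnot(ncol(ordered_as) == length(scores), ncol(ordered_rbp) == length(scores))
  if (is.unsorted(scores)) stop("scores must be ascending with their matrices")
  if (is.null(bandwidth)) {
    bandwidth <- (max(scores) - min(scores)) / max(length(scores) - 1L, 1L)
    if (bandwidth <= 0) bandwidth <- 0.01
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")
  grid <- seq(0, 1, length.out = grid_size)
  smooth_block <- function(mat) {
    K <- exp(-0.5 * (outer(grid, scores, "-") / bandwidth)^2)
    K <- K / rowSums(K)
    out <- mat %*% t(K)
    out[out < 0] <- 0
    colnames(out) <- NULL
    out
  }
  new_trajectory(grid = grid,
                 X = smooth_block(ordered_as),
                 U = smooth_block(ordered_rbp),
                 as_ids = rownames(ordered_as), rbp_ids = rownames(ordered_rbp),
                 bandwidth = bandwidth, support = range(grid))
}
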