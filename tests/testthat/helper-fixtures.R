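# Shared fixtures and independent oracles used across the suite.

# A tiny deterministic two-species-per-block system with known coefficients.
tiny_system <- function() {
  A <- matrix(c(0, 0.5, -0.4, 0), 2, 2, byrow = TRUE)
  B <- matrix(c(0.6, 0, 0, -0.5), 2, 2, byrow = TRUE)
  C <- matrix(c(0, -0.6, 0.5, 0), 2, 2, byrow = TRUE)
  dyn_system(A, B, C, d = c(1.2, 1.5), d_prime = c(1.1, 1.4))
}

# Decoupled system: pure exponential decay, closed form known.
decay_system <- function(d = c(1, 2), d_prime = c(0.5, 1.5)) {
  n <- length(d); m <- length(d_prime)
  dyn_system(matrix(0, n, n), matrix(0, n, m), matrix(0, m, m), d, d_prime)
}

# Explicit-Euler integrator: the independent fine-step oracle for the RK4
# trajectory simulator.
euler_trajectory <- function(system, x0, u0, grid, substeps = 1000L) {
  n_as <- length(x0); n_rbp <- length(u0)
  X <- matrix(NA_real_, n_as, length(grid))
  U <- matrix(NA_real_, n_rbp, length(grid))
  x <- x0; u <- u0
  X[, 1L] <- x; U[, 1L] <- u
  for (i in seq_len(length(grid) - 1L)) {
    h <- (grid[i + 1L] - grid[i]) / substeps
    for (k in seq_len(substeps)) {
      dx <- x * (system$A %*% x + system$B %*% u - system$d)
      du <- u * (system$C %*% u - system$d_prime)
      x <- x + h * as.numeric(dx)
      u <- u + h * as.numeric(du)
    }
    X[, i + 1L] <- x; U[, i + 1L] <- u
  }
  list(X = X, U = U)
}

# Brute-force maximal-clique enumeration over all vertex subsets (n <= 12).
brute_maximal_cliques <- function(adj) {
  n <- nrow(adj)
  verts <- seq_len(n)
  cliques <- list()
  for (size in 2:n) {
    for (cmb in utils::combn(verts, size, simplify = FALSE)) {
      sub <- adj[cmb, cmb, drop = FALSE]
      if (all(sub[upper.tri(sub)] == 1)) cliques[[length(cliques) + 1L]] <- cmb
    }
  }
  keep <- vapply(cliques, function(cl) {
    !any(vapply(cliques, function(other)
      length(other) > length(cl) && all(cl %in% other), logical(1)))
  }, logical(1))
  cliques[keep]
}

# Hand-built regulatory network fixture.
make_network <- function(edges_df, node_ids = NULL, state_tag = "all") {
  if (is.null(node_ids)) node_ids <- unique(c(edges_df$source, edges_df$target))
  nodes <- tibble::tibble(id = node_ids, type = NA_character_)
  splicedyn:::new_regulatory_network(nodes, tibble::as_tibble(edges_df), state_tag)
}

empty_edges <- function() {
  tibble::tibble(source = character(), target = character(), sign = character(),
                 mean = numeric(), ci_low = numeric(), ci_high = numeric())
}

# Hand-built posterior_fit fixture from a coefficient summary table.
make_fit <- function(target_id, target_type, summary, method = "lasso") {
  structure(list(method = method, target_id = target_id,
                 target_type = target_type, summary = summary, draws = NULL,
                 seed = 0L, ci_level = 0.95, converged = TRUE,
                 max_psrf = NA_real_),
            class = "posterior_fit")
}

# Random expression matrix with barcodes.
random_matrix <- function(nr, nc, seed = 1, prefix = "F") {
  withr::with_seed(seed, {
    m <- matrix(runif(nr * nc, 0.5, 2), nr, nc)
    dimnames(m) <- list(paste0(prefix, seq_len(nr)), sprintf("S%03d", seq_len(nc)))
    m
  })
}

simple_annot <- function(ids, states) {
  tibble::tibble(specimen_id = ids, state = as.integer(states),
                 stage = NA_character_, tnm = NA_character_)
}
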