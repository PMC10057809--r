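# Synthetic benchmark generator: ground-truth sparse mass-action systems,
# trajectory simulation, shuffled cross-sectional snapshots, multiplicative
# exponential noise. This module defines the study conditions for every
# simulation-based check in the package.

#' Ground-truth mass-action dynamical system
#'
#' The coupled system describing expression of N alternative-splicing (AS)
#' events \eqn{X_i} and M RNA-binding proteins (RBPs) \eqn{U_l} along a
#' progression coordinate \eqn{s}:
#' \deqn{dX_i/ds = \sum_{j \ne i} a_{ij} X_i X_j + \sum_l b_{il} X_i U_l - d_i X_i}
#' \deqn{dU_l/ds = \sum_{k \ne l} c_{lk} U_l U_k - d'_l U_l}
#' RBPs regulate each other and AS events; AS events never regulate RBPs.
#' `A` (N x N, zero diagonal) holds \eqn{a_{ij}} (AS j to AS i), `B` (N x M)
#' holds \eqn{b_{il}}, `C` (M x M, zero diagonal) holds \eqn{c_{lk}}; `d`
#' and `d_prime` are positive self-degradation rates.
#'
#' @param A,B,C Coefficient matrices as above.
#' @param d,d_prime Positive degradation-rate vectors (lengths N, M).
#' @param as_ids,rbp_ids Feature identifiers; defaults `AS1..ASN`, `RBP1..RBPM`.
#' @return An object of class `dyn_system`.
#' @export
dyn_system <- function(A, B, C, d, d_prime,
                       as_ids = paste0("AS", seq_len(nrow(B))),
                       rbp_ids = paste0("RBP", seq_len(ncol(B)))) {
  N <- length(d); M <- length(d_prime)
  stopifnot(is.matrix(A), is.matrix(B), is.matrix(C),
            dim(A) == c(N, N), dim(B) == c(N, M), dim(C) == c(M, M),
            length(as_ids) == N, length(rbp_ids) == M)
  if (any(diag(A) != 0) || any(diag(C) != 0)) {
    stop("diag(A) and diag(C) must be zero: self-effects are the degradation terms")
  }
  if (any(d <= 0) || any(d_prime <= 0)) stop("degradation rates must be positive")
  structure(list(A = A, B = B, C = C, d = d, d_prime = d_prime,
                 as_ids = as.character(as_ids), rbp_ids = as.character(rbp_ids)),
            class = "dyn_system")
}

#' Sample a random sparse ground-truth system
#'
#' Each off-diagonal entry of `A` and `C` and each entry of `B` is nonzero
#' independently with probability `edge_density`; nonzero magnitudes are
#' uniform in `[coeff_scale/2, coeff_scale]` with a fair random sign.
#' Degradation rates are uniform in `[1, 2]`, a degradation-dominated regime
#' that keeps trajectories bounded on the unit progression interval.
#'
#' @param n_as,n_rbp Numbers of AS events (N) and RBPs (M).
#' @param edge_density Probability in (0, 1] that a candidate coefficient is
#'   nonzero. Default 0.2 (sparsely connected truth).
#' @param coeff_scale Upper bound of nonzero coefficient magnitudes.
#' @param seed Integer seed; output is reproducible for a fixed seed.
#' @return A `dyn_system`.
#' @export
sample_system <- function(n_as, n_rbp, edge_density = 0.2, coeff_scale = 0.8,
                          seed = 1L) {
  stopifnot(n_as >= 1, n_rbp >= 1, coeff_scale > 0)
  if (edge_density <= 0 || edge_density > 1) stop("edge_density must lie in (0, 1]")
  with_seed(seed, {
    draw <- function(nr, nc, zero_diag) {
      m <- matrix(0, nr, nc)
      mask <- matrix(runif(nr * nc) < edge_density, nr, nc)
      if (zero_diag) diag(mask) <- FALSE
      k <- sum(mask)
      if (k > 0L) {
        m[mask] <- runif(k, coeff_scale / 2, coeff_scale) *
          sample(c(-1, 1), k, replace = TRUE)
      }
      m
    }
    A <- draw(n_as, n_as, zero_diag = TRUE)
    B <- draw(n_as, n_rbp, zero_diag = FALSE)
    C <- draw(n_rbp, n_rbp, zero_diag = TRUE)
    d <- runif(n_as, 1, 2)
    d_prime <- runif(n_rbp, 1, 2)
    dyn_system(A, B, C, d, d_prime)
  })
}

#' Simulate the mass-action trajectories on a progression grid
#'
#' Integrates the coupled system with a fixed-step classical Runge-Kutta
#' (4th order) scheme, sub-stepping `substeps` times between consecutive
#' grid points. The RBP block is autonomous and feeds the AS block; both are
#' integrated jointly. Integration is guarded: any state exceeding
#' `overflow_guard` aborts with advice to lower `coeff_scale`, and states are
#' floored at 0 so all-positive initial conditions stay nonnegative.
#'
#' @param system A `dyn_system`.
#' @param x0,u0 Positive initial conditions (lengths N, M).
#' @param grid Strictly increasing progression states in \[0, 1\].
#' @param substeps Integration sub-steps per grid interval. Default 10.
#' @param overflow_guard Blow-up threshold. Default 1e6.
#' @return A `trajectory` object: list with `grid`, `X` (N x |grid|),
#'   `U` (M x |grid|), `as_ids`, `rbp_ids`.
#' @export
simulate_trajectory <- function(system, x0, u0, grid, substeps = 10L,
                                overflow_guard = 1e6) {
  stopifnot(inherits(system, "dyn_system"),
            length(x0) == length(system$d), length(u0) == length(system$d_prime),
            all(x0 > 0), all(u0 > 0))
  if (length(grid) < 2L || any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  N <- length(x0); M <- length(u0)
  deriv <- function(t, y, parms) {
    x <- y[seq_len(N)]; u <- y[N + seq_len(M)]
    dx <- x * (system$A %*% x + system$B %*% u - system$d)
    du <- u * (system$C %*% u - system$d_prime)
    list(c(dx, du))
  }
  # sub-stepped fixed-step RK4 via deSolve; keep only requested grid points
  fine <- unique(sort(c(grid, unlist(
    lapply(seq_len(length(grid) - 1L), function(i)
      seq(grid[i], grid[i + 1L], length.out = substeps + 1L))))))
  sol <- deSolve::rk4(y = c(x0, u0), times = fine, func = deriv, parms = NULL)
  if (anyNA(sol) || max(abs(sol[, -1L]), na.rm = TRUE) > overflow_guard) {
    stop("trajectory blow-up beyond the overflow guard; use a smaller coeff_scale")
  }
  keep <- match(grid, sol[, 1L])
  states <- t(sol[keep, -1L, drop = FALSE])
  states[states < 0] <- 0
  new_trajectory(grid = grid,
                 X = states[seq_len(N), , drop = FALSE],
                 U = states[N + seq_len(M), , drop = FALSE],
                 as_ids = system$as_ids, rbp_ids = system$rbp_ids)
}

new_trajectory <- function(grid, X, U, as_ids, rbp_ids, bandwidth = NULL,
                           support = NULL) {
  rownames(X) <- as_ids; rownames(U) <- rbp_ids
  structure(list(grid = grid, X = X, U = U, as_ids = as_ids, rbp_ids = rbp_ids,
                 bandwidth = bandwidth, support = support),
            class = "trajectory")
}

#' Turn a simulated trajectory into shuffled cross-sectional matrices
#'
#' Emulates cross-sectional sampling: each grid point becomes one specimen,
#' sample IDs are randomised by a single shared permutation of both matrices,
#' and the binary epithelial/mesenchymal state label is retained (true
#' progression `< boundary` is state 1, else state 2). The returned truth
#' records the true scores and the permutation that restores the original
#' order.
#'
#' @param traj A `trajectory`.
#' @param boundary State boundary on the true progression scale, in (0, 1).
#' @param seed Integer seed for the permutation.
#' @return A list with `as_matrix`, `rbp_matrix` (feature x specimen
#'   matrices with barcodes `S001...`), `annotation` (tibble), and `truth`
#'   (class `synthetic_truth`: `true_scores`, `true_order`, `states` in the
#'   shuffled specimen order, plus the generating `grid`).
#' @export
make_cross_sectional <- function(traj, boundary = 0.5, seed = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  if (boundary <= 0 || boundary >= 1) stop("boundary must lie in (0, 1)")
  n <- length(traj$grid)
  states <- ifelse(traj$grid < boundary, 1L, 2L)
  if (length(unique(states)) < 2L) stop("boundary leaves one state class empty")
  perm <- with_seed(seed, sample.int(n))
  ids <- sprintf("S%03d", seq_len(n))
  as_mat <- traj$X[, perm, drop = FALSE]
  rbp_mat <- traj$U[, perm, drop = FALSE]
  colnames(as_mat) <- ids
  colnames(rbp_mat) <- ids
  annot <- tibble::tibble(specimen_id = ids, state = states[perm],
                          stage = NA_character_, tnm = NA_character_)
  truth <- structure(list(true_scores = traj$grid[perm],
                          true_order = order(traj$grid[perm]),
                          states = states[perm],
                          specimen_ids = ids, grid = traj$grid),
                     class = "synthetic_truth")
  list(as_matrix = as_mat, rbp_matrix = rbp_mat, annotation = annot,
       truth = truth)
}

#' Perturb a matrix with multiplicative exponential noise
#'
#' Each entry `v` becomes `v * (1 + eta * eps)` with
#' `eps ~ Exponential(mean = mu)` and `eta` an independent fair random sign,
#' so the noise factor is mean-preserving with standard deviation
#' `mu * sqrt(2)`. Negative results are clipped to 0. With
#' `one_sided = TRUE` the factor is `1 + eps` (pure inflation). `mu = 0`
#' returns the input unchanged.
#'
#' @param mat Numeric matrix without missing entries.
#' @param mu Mean of the exponential noise, >= 0.
#' @param seed Integer seed.
#' @param one_sided Use the one-sided factor `1 + eps` instead of the
#'   sign-symmetrised default.
#' @return A matrix of the same shape and dimnames.
#' @export
add_noise <- function(mat, mu, seed = 1L, one_sided = FALSE) {
  stopifnot(is.matrix(mat))
  if (anyNA(mat)) stop("matrix must be complete before noise injection")
  if (mu < 0) stop("mu must be >= 0")
  if (mu == 0) return(mat)
  n <- length(mat)
  with_seed(seed, {
    eps <- rexp(n, rate = 1 / mu)
    eta <- if (one_sided) rep(1, n) else sample(c(-1, 1), n, replace = TRUE)
    out <- mat * (1 + eta * eps)
    out[out < 0] <- 0
    out
  })
}

#' Default initial conditions for synthetic systems
#'
#' Uniform in \[0.5, 1.5\] per species, which keeps every species well away
#' from zero so the divide-through linearisation used downstream stays
#' well-posed.
#'
#' @param n Number of species.
#' @param seed Integer seed.
#' @return Positive numeric vector of length `n`.
#' @export
sample_initial_conditions <- function(n, seed = 1L) {
  with_seed(seed, runif(n, 0.5, 1.5))
}
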