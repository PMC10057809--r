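# Per-equation regression problems from smoothed trajectories, Bayesian
# coefficient estimation (Lasso Gibbs sampler plus conjugate, semiconjugate
# and diffuse baselines), credible-interval edge calling, and the two-state
# system fits.

#' Numerical derivatives along a uniform grid
#'
#' Central differences at interior points and second-order one-sided
#' differences at the endpoints; exact for linear series.
#'
#' @param traj A `trajectory` on a uniform grid with >= 3 points.
#' @return A list with `dX` and `dU`, matching the trajectory blocks.
#' @export
estimate_derivatives <- function(traj) {
  grid <- traj$grid
  h <- diff(grid)
  if (length(grid) < 3L) stop("need at least 3 grid points")
  if (max(abs(h - h[1L])) > 1e-8 * h[1L]) stop("grid must be uniform; resample first")
  list(dX = finite_diff(traj$X, h[1L]), dU = finite_diff(traj$U, h[1L]))
}

finite_diff <- function(mat, h) {
  n <- ncol(mat)
  d <- matrix(0, nrow(mat), n, dimnames = dimnames(mat))
  d[, 2:(n - 1L)] <- (mat[, 3:n, drop = FALSE] - mat[, 1:(n - 2L), drop = FALSE]) / (2 * h)
  d[, 1L] <- (-3 * mat[, 1L] + 4 * mat[, 2L] - mat[, 3L]) / (2 * h)
  d[, n] <- (3 * mat[, n] - 4 * mat[, n - 1L] + mat[, n - 2L]) / (2 * h)
  d
}

#' Build the per-equation regression problem
#'
#' The mass-action equations all carry the factor of the target species, so
#' dividing through linearises each equation into an ordinary regression:
#' for AS target i the response is `(dX_i/ds) / X_i` and the predictors are
#' the peer AS series `X_j` (j != i, coefficients `a_ij`), the RBP series
#' `U_l` (coefficients `b_il`), and a constant `-1` column whose coefficient
#' is the degradation rate `d_i`. For an RBP target l the response is
#' `(dU_l/ds) / U_l` and the predictors are the peer RBP series only (no AS
#' terms exist in the RBP equation) plus the `-1` degradation column.
#'
#' @param traj A `trajectory`.
#' @param derivs Output of [estimate_derivatives()].
#' @param target Feature ID of the equation's left-hand side.
#' @param positivity_floor If `TRUE`, floor the target series at 1e-6 with a
#'   warning instead of erroring on nonpositive values.
#' @return A `regression_problem`: list with `target_id`, `target_type`,
#'   `response`, `design` (grid x predictors), `predictor_ids`, `roles`
#'   (coefficient class per column: `"as_as"`, `"rbp_as"`, `"rbp_rbp"`,
#'   `"degradation"`).
#' @export
build_design <- function(traj, derivs, target, positivity_floor = FALSE) {
  is_as <- target %in% traj$as_ids
  if (!is_as && !(target %in% traj$rbp_ids)) stop("unknown target feature: ", target)
  tgt <- if (is_as) traj$X[target, ] else traj$U[target, ]
  if (any(tgt <= 0)) {
    if (!positivity_floor) {
      stop("target series has nonpositive values on the grid; ",
           "use positivity_floor = TRUE to floor at 1e-6")
    }
    warning("flooring nonpositive target values at 1e-6")
    tgt <- pmax(tgt, 1e-6)
  }
  dtgt <- if (is_as) derivs$dX[target, ] else derivs$dU[target, ]
  if (is_as) {
    peers <- setdiff(traj$as_ids, target)
    design <- cbind(t(traj$X[peers, , drop = FALSE]),
                    t(traj$U), rep(-1, length(tgt)))
    ids <- c(peers, traj$rbp_ids, "degradation")
    roles <- c(rep("as_as", length(peers)), rep("rbp_as", length(traj$rbp_ids)),
               "degradation")
  } else {
    peers <- setdiff(traj$rbp_ids, target)
    design <- cbind(t(traj$U[peers, , drop = FALSE]), rep(-1, length(tgt)))
    ids <- c(peers, "degradation")
    roles <- c(rep("rbp_rbp", length(peers)), "degradation")
  }
  colnames(design) <- ids
  structure(list(target_id = target, target_type = if (is_as) "AS" else "RBP",
                 response = dtgt / tgt, design = design,
                 predictor_ids = ids, roles = roles),
            class = "regression_problem")
}

#' Bayesian Lasso fit of one regression problem
#'
#' Gibbs sampler for the Bayesian Lasso: independent Laplace priors on the
#' coefficients represented as scale mixtures of normals with
#' per-coefficient latent scales, an inverse-gamma update for the noise
#' variance, and a gamma hyperprior on the squared shrinkage parameter.
#' Returns retained posterior draws and equal-tailed credible intervals.
#' A split-chain potential-scale-reduction factor above 1.2 on any
#' coefficient is recorded as a convergence warning in the fit (never an
#' error).
#'
#' @param problem A `regression_problem` (>= 10 rows).
#' @param mcmc List with `iterations`, `burn_in`, `thinning`.
#' @param seed Integer seed; fits are deterministic given the seed.
#' @param ci_level Credible level for the interval summaries.
#' @return A `posterior_fit`: `method`, `summary` tibble (`predictor_id`,
#'   `role`, `mean`, `sd`, `ci_low`, `ci_high`), `draws` matrix, `seed`,
#'   `converged`, `max_psrf`.
#' @export
bayesian_lasso_fit <- function(problem, mcmc = list(iterations = 5000L, burn_in = 1000L, thinning = 2L),
                               seed = 1L, ci_level = 0.95) {
  stopifnot(inherits(problem, "regression_problem"))
  X <- problem$design; y <- problem$response
  if (nrow(X) < 10L) stop("need at least 10 grid rows to fit")
  draws <- with_seed(seed, blasso_gibbs_cpp(y, X, as.integer(mcmc$iterations),
                                            as.integer(mcmc$burn_in),
                                            as.integer(mcmc$thinning)))
  beta <- draws$beta
  colnames(beta) <- problem$predictor_ids
  new_posterior_fit("lasso", problem, beta, seed, ci_level)
}

#' Baseline Bayesian fits (conjugate, semiconjugate, diffuse)
#'
#' Gaussian-prior baselines against which the Lasso's sparsity is compared:
#' * `conjugate` - normal-inverse-gamma prior scaled by the noise variance;
#'   closed-form posterior, marginal Student-t credible intervals.
#' * `semiconjugate` - independent normal prior on coefficients and
#'   inverse-gamma on the variance; Gibbs sampling.
#' * `diffuse` - improper flat prior; the posterior mean equals the
#'   ordinary-least-squares solution with Student-t intervals.
#'
#' @inheritParams bayesian_lasso_fit
#' @param prior One of `"conjugate"`, `"semiconjugate"`, `"diffuse"`.
#' @param prior_precision Prior precision of the coefficients for the
#'   conjugate and semiconjugate priors (as a multiple of the identity).
#'   The default 4 (prior standard deviation 1/2) is weakly informative on
#'   the O(1) coefficient scale of the linearised mass-action equations
#'   while proper enough to resolve directions the near-collinear designs
#'   leave unidentified; as it tends to 0 the conjugate posterior
#'   approaches the diffuse one.
#' @return A `posterior_fit`.
#' @export
bayesian_baseline_fit <- function(problem, prior = c("conjugate", "semiconjugate", "diffuse"),
                                  mcmc = list(iterations = 5000L, burn_in = 1000L, thinning = 2L),
                                  seed = 1L, ci_level = 0.95, prior_precision = 4) {
  prior <- match.arg(prior)
  stopifnot(inherits(problem, "regression_problem"))
  X <- problem$design; y <- problem$response
  n <- nrow(X); p <- ncol(X)
  if (n < 10L) stop("need at least 10 grid rows to fit")
  alpha <- (1 - ci_level) / 2
  a0 <- 0.001; b0 <- 0.001
  if (prior == "semiconjugate") {
    draws <- with_seed(seed, semiconj_gibbs_cpp(y, X, prior_precision,
                                                as.integer(mcmc$iterations),
                                                as.integer(mcmc$burn_in),
                                                as.integer(mcmc$thinning)))
    beta <- draws$beta
    colnames(beta) <- problem$predictor_ids
    return(new_posterior_fit("semiconjugate", problem, beta, seed, ci_level))
  }
  XtX <- crossprod(X)
  if (prior == "conjugate") {
    A <- XtX + diag(prior_precision, p)
    Ainv <- pinv_sym(A)
    m <- Ainv %*% crossprod(X, y)
    a_n <- a0 + n / 2
    b_n <- b0 + 0.5 * (sum(y^2) - sum(m * (A %*% m)))
    scale2 <- (b_n / a_n) * diag(Ainv)
    df <- 2 * a_n
  } else { # diffuse
    Ainv <- pinv_sym(XtX)
    m <- Ainv %*% crossprod(X, y)
    rss <- sum((y - X %*% m)^2)
    df <- n - p
    scale2 <- (rss / df) * diag(Ainv)
    a_n <- df / 2; b_n <- rss / 2
  }
  se <- sqrt(pmax(scale2, 0))
  tq <- qt(1 - alpha, df)
  summary <- tibble::tibble(
    predictor_id = problem$predictor_ids, role = problem$roles,
    mean = as.numeric(m), sd = se * sqrt(df / max(df - 2, 1e-9)),
    ci_low = as.numeric(m) - tq * se, ci_high = as.numeric(m) + tq * se)
  structure(list(method = prior, target_id = problem$target_id,
                 target_type = problem$target_type, summary = summary,
                 draws = NULL, seed = seed, ci_level = ci_level,
                 converged = TRUE, max_psrf = NA_real_),
            class = "posterior_fit")
}

new_posterior_fit <- function(method, problem, beta, seed, ci_level) {
  alpha <- (1 - ci_level) / 2
  psrf <- apply(beta, 2L, split_chain_psrf)
  max_psrf <- max(psrf)
  if (max_psrf > 1.2) {
    warning("possible non-convergence: split-chain PSRF = ", round(max_psrf, 3),
            " for target ", problem$target_id)
  }
  summary <- tibble::tibble(
    predictor_id = problem$predictor_ids, role = problem$roles,
    mean = colMeans(beta), sd = apply(beta, 2L, sd),
    ci_low = apply(beta, 2L, quantile, probs = alpha, names = FALSE),
    ci_high = apply(beta, 2L, quantile, probs = 1 - alpha, names = FALSE))
  structure(list(method = method, target_id = problem$target_id,
                 target_type = problem$target_type, summary = summary,
                 draws = beta, seed = seed, ci_level = ci_level,
                 converged = max_psrf <= 1.2, max_psrf = max_psrf),
            class = "posterior_fit")
}

# Moore-Penrose pseudoinverse of a symmetric PSD matrix; tolerates the
# numerically singular designs produced by near-collinear trajectories.
pinv_sym <- function(A, tol = 1e-12) {
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > tol * max(e$values)
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

# Gelman-Rubin potential scale reduction on the two halves of one chain.
split_chain_psrf <- function(x) {
  n <- floor(length(x) / 2)
  a <- x[seq_len(n)]; b <- x[n + seq_len(n)]
  W <- (var(a) + var(b)) / 2
  if (W <= 0) return(1)
  B <- n * var(c(mean(a), mean(b)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Call signed directed edges from credible intervals
#'
#' A directed edge source -> target exists iff the credible interval of the
#' corresponding regulatory coefficient excludes zero (an endpoint exactly
#' at zero does not qualify); its sign is the sign of the posterior mean.
#' Degradation coefficients never become edges, and the model structure
#' guarantees no AS -> RBP edge can exist.
#'
#' @param fits List of `posterior_fit`, one per target equation.
#' @param level Credible level the fits were summarised at (refit to change).
#' @param state_tag Label attached to the network (`"all"`, `"epithelial"`,
#'   `"mesenchymal"`).
#' @return A `regulatory_network`: `nodes` tibble (`id`, `type`), `edges`
#'   tibble (`source`, `target`, `sign`, `mean`, `ci_low`, `ci_high`),
#'   `state_tag`.
#' @export
call_edges <- function(fits, level = 0.95, state_tag = "all") {
  stopifnot(length(fits) > 0L, all(vapply(fits, inherits, TRUE, "posterior_fit")))
  edges <- purrr::map_dfr(fits, function(f) {
    s <- f$summary
    if (!is.null(f$draws) && abs(level - f$ci_level) > 1e-12) {
      alpha <- (1 - level) / 2
      s$ci_low <- apply(f$draws, 2L, quantile, probs = alpha, names = FALSE)
      s$ci_high <- apply(f$draws, 2L, quantile, probs = 1 - alpha, names = FALSE)
    }
    s <- s[s$role != "degradation" & (s$ci_low > 0 | s$ci_high < 0), , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    tibble::tibble(source = s$predictor_id, target = f$target_id,
                   sign = ifelse(s$mean > 0, "+", "-"),
                   mean = s$mean, ci_low = s$ci_low, ci_high = s$ci_high)
  })
  if (nrow(edges) == 0L) {
    edges <- tibble::tibble(source = character(), target = character(),
                            sign = character(), mean = numeric(),
                            ci_low = numeric(), ci_high = numeric())
  }
  nodes <- purrr::map_dfr(fits, function(f)
    tibble::tibble(id = f$target_id, type = f$target_type))
  nodes <- dplyr::distinct(nodes)
  extra <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
  if (length(extra) > 0L) {
    nodes <- dplyr::bind_rows(nodes, tibble::tibble(id = extra, type = NA_character_))
  }
  new_regulatory_network(nodes, dplyr::arrange(edges, .data$source, .data$target),
                         state_tag)
}

new_regulatory_network <- function(nodes, edges, state_tag) {
  structure(list(nodes = nodes, edges = tibble::as_tibble(edges),
                 state_tag = state_tag),
            class = "regulatory_network")
}

#' Network sparsity
#'
#' `1 - |interactions| / (N^2 + N M + M^2)` for a network over N AS events
#' and M RBPs: the fraction of candidate regulatory coefficients (including
#' the diagonal positions of the printed formula's denominator) that carry
#' no interaction.
#'
#' @param net A `regulatory_network`.
#' @param N,M Numbers of AS events and RBPs.
#' @return A single number in \[0, 1\].
#' @export
network_sparsity <- function(net, N, M) {
  n_edges <- nrow(net$edges)
  denom <- N^2 + N * M + M^2
  if (n_edges > denom) stop("edge count exceeds the candidate-coefficient count")
  1 - n_edges / denom
}

#' Fit one dynamical system on a whole smoothed trajectory
#'
#' Runs derivatives -> per-equation design -> coefficient fit -> edge
#' calling for every AS and RBP target of a trajectory.
#'
#' For trajectories produced by kernel smoothing, grid points within
#' `boundary_exclude` bandwidths of the smoothing support's edges are
#' dropped before derivative estimation: the one-sided kernel there biases
#' the fitted curve's derivative, which would otherwise leak into every
#' coefficient. Raw (simulated) trajectories are used in full.
#'
#' @param traj A `trajectory`.
#' @param method `"lasso"` or a baseline prior name.
#' @param mcmc,seed,ci_level As in [bayesian_lasso_fit()].
#' @param positivity_floor Passed to [build_design()].
#' @param state_tag Tag for the returned network.
#' @param boundary_exclude Width of the excluded boundary region in
#'   bandwidths (smoothed trajectories only). At least 10 grid points are
#'   always retained.
#' @return List with `fits` (per-target `posterior_fit`s, named) and
#'   `network` (a `regulatory_network`).
#' @export
fit_system <- function(traj, method = "lasso",
                       mcmc = list(iterations = 5000L, burn_in = 1000L, thinning = 2L),
                       seed = 1L, ci_level = 0.95, positivity_floor = TRUE,
                       state_tag = "all", boundary_exclude = 4) {
  if (!is.null(traj$bandwidth) && boundary_exclude > 0) {
    margin <- boundary_exclude * traj$bandwidth
    keep <- traj$grid >= traj$support[1L] + margin &
      traj$grid <= traj$support[2L] - margin
    if (sum(keep) >= 10L) {
      traj <- new_trajectory(traj$grid[keep], traj$X[, keep, drop = FALSE],
                             traj$U[, keep, drop = FALSE],
                             traj$as_ids, traj$rbp_ids)
    }
  }
  derivs <- estimate_derivatives(traj)
  targets <- c(traj$as_ids, traj$rbp_ids)
  fits <- lapply(seq_along(targets), function(i) {
    pb <- build_design(traj, derivs, targets[i], positivity_floor = positivity_floor)
    sub <- substream(seed, i)
    if (method == "lasso") {
      bayesian_lasso_fit(pb, mcmc = mcmc, seed = sub, ci_level = ci_level)
    } else {
      bayesian_baseline_fit(pb, prior = method, mcmc = mcmc, seed = sub,
                            ci_level = ci_level)
    }
  })
  names(fits) <- targets
  list(fits = fits, network = call_edges(fits, level = ci_level, state_tag = state_tag))
}

#' Fit separate epithelial- and mesenchymal-state systems
#'
#' Splits the smoothed trajectory at the pseudotime boundary between the
#' states (midpoint between the largest epithelial and smallest mesenchymal
#' score when the states separate; otherwise the threshold minimising label
#' misclassification along pseudotime) and runs the full inference
#' independently on each segment.
#'
#' @param traj A `trajectory` shared by both states.
#' @param ordering A `pseudotime_ordering` carrying scores and states.
#' @inheritParams fit_system
#' @return List with `epithelial` and `mesenchymal` elements (each as
#'   returned by [fit_system()]) and `boundary` (the split point).
#' @export
fit_state_systems <- function(traj, ordering,
                              method = "lasso",
                              mcmc = list(iterations = 5000L, burn_in = 1000L, thinning = 2L),
                              seed = 1L, ci_level = 0.95, positivity_floor = TRUE) {
  stopifnot(inherits(ordering, "pseudotime_ordering"))
  if (length(unique(ordering$state)) < 2L) stop("both states must be present along the ordering")
  boundary <- state_boundary(ordering$score, ordering$state)
  pick <- function(mask) {
    if (sum(mask) < 10L) stop("a state segment has fewer than 10 grid points; use a larger grid")
    new_trajectory(grid = traj$grid[mask],
                   X = traj$X[, mask, drop = FALSE],
                   U = traj$U[, mask, drop = FALSE],
                   as_ids = traj$as_ids, rbp_ids = traj$rbp_ids,
                   bandwidth = traj$bandwidth, support = traj$support)
  }
  epi <- fit_system(pick(traj$grid < boundary), method = method, mcmc = mcmc,
                    seed = substream(seed, 101L), ci_level = ci_level,
                    positivity_floor = positivity_floor, state_tag = "epithelial")
  mes <- fit_system(pick(traj$grid >= boundary), method = method, mcmc = mcmc,
                    seed = substream(seed, 202L), ci_level = ci_level,
                    positivity_floor = positivity_floor, state_tag = "mesenchymal")
  list(epithelial = epi, mesenchymal = mes, boundary = boundary)
}

# Split point between epithelial (1) and mesenchymal (2) along pseudotime.
state_boundary <- function(scores, states) {
  hi_epi <- max(scores[states == 1L])
  lo_mes <- min(scores[states == 2L])
  if (hi_epi < lo_mes) return((hi_epi + lo_mes) / 2)
  cand <- sort(unique(scores))
  mis <- vapply(cand, function(b)
    sum(states == 1L & scores >= b) + sum(states == 2L & scores < b), numeric(1))
  cand[which.min(mis)]
}
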