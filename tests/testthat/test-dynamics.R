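# Derivatives, design construction, Bayesian fits, edge calling, sparsity,
# two-state fits.

test_that("finite differences are exact on linears and match analytic s^2", {
  grid <- seq(0, 1, length.out = 21)
  traj <- splicedyn:::new_trajectory(grid,
                                     rbind(3 * grid, rep(2, 21)),
                                     rbind(grid^2),
                                     c("AS1", "AS2"), "RBP1")
  d <- estimate_derivatives(traj)
  expect_equal(unname(d$dX[1, ]), rep(3, 21))
  expect_equal(unname(d$dX[2, ]), rep(0, 21))
  # second-order formulas are exact on quadratics, endpoints included
  expect_equal(unname(d$dU[1, ]), 2 * grid, tolerance = 1e-10)
  # endpoint error on a cubic shrinks ~4x when the step halves (O(h^2))
  err_for <- function(n) {
    g <- seq(0, 1, length.out = n)
    tr <- splicedyn:::new_trajectory(g, rbind(g^3), rbind(g), "AS1", "RBP1")
    abs(estimate_derivatives(tr)$dX[1, 1] - 0)
  }
  expect_gt(err_for(11) / err_for(21), 3)
  bad <- splicedyn:::new_trajectory(c(0, 0.1, 0.5), rbind(1:3), rbind(1:3),
                                    "AS1", "RBP1")
  expect_error(estimate_derivatives(bad), "uniform")
})

test_that("designs have the structure forced by the model equations", {
  sys <- sample_system(5, 3, seed = 1)
  traj <- simulate_trajectory(sys, sample_initial_conditions(5, 2),
                              sample_initial_conditions(3, 3),
                              seq(0, 1, length.out = 50))
  dv <- estimate_derivatives(traj)
  pb_as <- build_design(traj, dv, "AS1")
  expect_identical(ncol(pb_as$design), 8L)  # 4 peers + 3 RBPs + degradation
  expect_identical(pb_as$roles,
                   c(rep("as_as", 4), rep("rbp_as", 3), "degradation"))
  pb_rbp <- build_design(traj, dv, "RBP2")
  expect_identical(ncol(pb_rbp$design), 3L)  # 2 peers + degradation
  expect_false(any(pb_rbp$predictor_ids %in% traj$as_ids))
  expect_true(all(pb_as$design[, "degradation"] == -1))
  expect_error(build_design(traj, dv, "NOPE"), "unknown target")
})

test_that("least squares on the built design recovers a small generator", {
  # well-conditioned instance: 2 AS events, 2 RBPs, noiseless dynamics
  sys <- sample_system(2, 2, edge_density = 0.2, seed = 1)
  traj <- simulate_trajectory(sys, sample_initial_conditions(2, 5),
                              sample_initial_conditions(2, 6),
                              seq(0, 1, length.out = 100))
  dv <- estimate_derivatives(traj)
  for (tg in c(traj$as_ids, traj$rbp_ids)) {
    pb <- build_design(traj, dv, tg)
    b <- qr.coef(qr(pb$design), pb$response)
    truth <- if (tg %in% traj$as_ids) {
      i <- match(tg, traj$as_ids)
      c(sys$A[i, -i], sys$B[i, ], sys$d[i])
    } else {
      l <- match(tg, traj$rbp_ids)
      c(sys$C[l, -l], sys$d_prime[l])
    }
    expect_lt(sqrt(sum((b - truth)^2)) / sqrt(sum(truth^2)), 0.05)
  }
})

test_that("the lasso posterior is calibrated on simple regressions", {
  # null signal: every CI straddles zero
  n <- 40
  X <- withr::with_seed(1, matrix(rnorm(n * 3), n, 3))
  pb <- structure(list(target_id = "AS1", target_type = "AS",
                       response = rep(0, n), design = X,
                       predictor_ids = c("a", "b", "c"),
                       roles = rep("as_as", 3)),
                  class = "regression_problem")
  f <- bayesian_lasso_fit(pb, seed = 2)
  expect_true(all(f$summary$ci_low <= 0 & f$summary$ci_high >= 0))

  # single strong predictor: posterior close to OLS, shrinkage small
  x <- withr::with_seed(3, runif(50, 0.5, 2))
  y <- 2 * x + withr::with_seed(4, rnorm(50, sd = 0.1))
  pb1 <- structure(list(target_id = "AS1", target_type = "AS",
                        response = y, design = cbind(x = x),
                        predictor_ids = "x", roles = "as_as"),
                   class = "regression_problem")
  f1 <- bayesian_lasso_fit(pb1, seed = 5)
  ols <- sum(x * y) / sum(x^2)
  expect_lt(abs(f1$summary$mean - 2), 3 * f1$summary$sd)
  expect_lt(abs(f1$summary$mean - ols) / abs(ols), 0.10)
  # deterministic given the seed
  f2 <- bayesian_lasso_fit(pb1, seed = 5)
  expect_identical(f1$summary, f2$summary)
})

test_that("truly-zero coefficients straddle zero more often than active ones", {
  n <- 100; p <- 8
  hits_zero <- hits_active <- 0
  for (s in 1:20) {
    X <- withr::with_seed(s, matrix(rnorm(n * p), n, p))
    beta <- c(2, -1.5, rep(0, p - 2))
    y <- X %*% beta + withr::with_seed(s + 500, rnorm(n, sd = 0.3))
    pb <- structure(list(target_id = "AS1", target_type = "AS",
                         response = as.numeric(y), design = X,
                         predictor_ids = paste0("v", 1:p),
                         roles = rep("as_as", p)),
                    class = "regression_problem")
    f <- bayesian_lasso_fit(pb, mcmc = list(iterations = 1500L, burn_in = 500L,
                                            thinning = 2L), seed = s)
    straddle <- f$summary$ci_low <= 0 & f$summary$ci_high >= 0
    hits_zero <- hits_zero + sum(straddle[3:p])
    hits_active <- hits_active + sum(straddle[1:2])
  }
  expect_gt(hits_zero / (20 * (p - 2)), hits_active / (20 * 2))
})

test_that("the diffuse posterior mean equals ordinary least squares", {
  n <- 60
  X <- withr::with_seed(7, cbind(runif(n), runif(n), rnorm(n)))
  y <- X %*% c(1, -2, 0.5) + withr::with_seed(8, rnorm(n, sd = 0.2))
  pb <- structure(list(target_id = "RBP1", target_type = "RBP",
                       response = as.numeric(y), design = X,
                       predictor_ids = c("a", "b", "c"), roles = rep("rbp_rbp", 3)),
                  class = "regression_problem")
  fd <- bayesian_baseline_fit(pb, "diffuse")
  ols <- qr.coef(qr(X), y)
  expect_lt(max(abs(fd$summary$mean - ols)), 1e-8)
  # conjugate with vanishing prior precision approaches the diffuse solution
  fc <- bayesian_baseline_fit(pb, "conjugate", prior_precision = 1e-10)
  expect_lt(max(abs(fc$summary$mean - fd$summary$mean)), 1e-6)
  # semiconjugate chain agrees with the same posterior up to MC error
  fs <- bayesian_baseline_fit(pb, "semiconjugate", prior_precision = 1e-6, seed = 9)
  expect_lt(max(abs(fs$summary$mean - ols)), 0.05)
})

test_that("edge calling follows the credible-interval rule exactly", {
  s <- tibble::tibble(
    predictor_id = c("AS2", "RBP1", "RBP2", "degradation"),
    role = c("as_as", "rbp_as", "rbp_as", "degradation"),
    mean = c(0.05, 0.3, -0.4, 1),
    sd = c(0.1, 0.1, 0.1, 0.1),
    ci_low = c(-0.2, 0.1, -0.6, 0.8),
    ci_high = c(0.3, 0.5, -0.2, 1.2))
  net <- call_edges(list(make_fit("AS1", "AS", s)))
  expect_identical(nrow(net$edges), 2L)             # (-0.2, 0.3) straddles: no edge
  expect_identical(net$edges$sign, c("+", "-"))
  expect_false("degradation" %in% net$edges$source)  # never an edge

  # an endpoint exactly at zero does not count as exclusion
  s0 <- s; s0$ci_low <- c(0, 0.1, -0.6, 0.8)
  net0 <- call_edges(list(make_fit("AS1", "AS", s0)))
  expect_false("AS2" %in% net0$edges$source)
})

test_that("edge calling is monotone in the credible level", {
  sys <- tiny_system()
  traj <- simulate_trajectory(sys, c(1, 1.2), c(0.9, 1.1),
                              seq(0, 1, length.out = 60))
  fit <- suppressWarnings(fit_system(traj, seed = 3,
                                     mcmc = list(iterations = 2000L,
                                                 burn_in = 500L, thinning = 2L)))
  key <- function(net) paste(net$edges$source, net$edges$target)
  e99 <- key(call_edges(fit$fits, level = 0.99))
  e95 <- key(call_edges(fit$fits, level = 0.95))
  e90 <- key(call_edges(fit$fits, level = 0.90))
  expect_true(all(e99 %in% e95))
  expect_true(all(e95 %in% e90))
})

test_that("networks never contain AS -> RBP edges or self-loops", {
  for (s in 1:3) {
    sys <- sample_system(3, 2, edge_density = 0.8, seed = s)
    traj <- simulate_trajectory(sys, sample_initial_conditions(3, s + 30),
                                sample_initial_conditions(2, s + 60),
                                seq(0, 1, length.out = 40))
    fit <- suppressWarnings(
      fit_system(traj, seed = s, mcmc = list(iterations = 1200L,
                                             burn_in = 400L, thinning = 2L)))
    edges <- fit$network$edges
    expect_false(any(edges$source %in% traj$as_ids &
                       edges$target %in% traj$rbp_ids))
    expect_false(any(edges$source == edges$target))
  }
})

test_that("sparsity implements the printed formula", {
  empty <- make_network(empty_edges(), node_ids = c("AS1", "RBP1"))
  expect_identical(network_sparsity(empty, 5, 3), 1)
  edges <- tibble::tibble(source = paste0("AS", 1:10), target = "AS1",
                          sign = "+", mean = 1, ci_low = 0.5, ci_high = 1.5)
  expect_equal(network_sparsity(make_network(edges), 5, 3), 1 - 10 / 49)
  dense <- tibble::tibble(source = paste0("N", 1:49), target = "AS1",
                          sign = "+", mean = 1, ci_low = 0.5, ci_high = 1.5)
  expect_identical(network_sparsity(make_network(dense), 5, 3), 0)
  expect_error(network_sparsity(make_network(dense), 2, 2), "exceeds")
})

test_that("two-state fits split at the label boundary and stay self-consistent", {
  # same generator on both halves: the two edge sets should broadly agree
  sys <- tiny_system()
  grid <- seq(0, 1, length.out = 160)
  traj <- simulate_trajectory(sys, c(1, 1.3), c(1.1, 0.8), grid)
  ordering <- tibble::tibble(specimen_id = sprintf("S%03d", 1:160),
                             score = grid,
                             state = ifelse(grid < 0.5, 1L, 2L),
                             rank = 1:160)
  attr(ordering, "order") <- 1:160
  class(ordering) <- c("pseudotime_ordering", class(ordering))
  st <- suppressWarnings(
    fit_state_systems(traj, ordering, seed = 4,
                      mcmc = list(iterations = 4000L, burn_in = 1000L,
                                  thinning = 2L)))
  expect_equal(st$boundary, 0.5, tolerance = 0.01)
  expect_identical(st$epithelial$network$state_tag, "epithelial")
  key <- function(net) paste(net$edges$source, net$edges$target, net$edges$sign)
  a <- key(st$epithelial$network); b <- key(st$mesenchymal$network)
  if (length(union(a, b)) > 0) {
    expect_gt(length(intersect(a, b)) / length(union(a, b)), 0.5)
  }
  expect_error(
    fit_state_systems(traj,
                      within(ordering, state <- rep(1L, 160)), seed = 1),
    "both states")
})

test_that("interleaved labels fall back to the misclassification-minimising split", {
  scores <- seq(0, 1, length.out = 20)
  states <- c(rep(1L, 9), 2L, 1L, rep(2L, 9))  # one straggler on each side
  b <- splicedyn:::state_boundary(scores, states)
  mis <- sum(states == 1L & scores >= b) + sum(states == 2L & scores < b)
  expect_lte(mis, 2L)
})
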