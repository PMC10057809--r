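# Benchmark metrics and the experiment drivers.

fake_truth <- function(scores, ids = sprintf("S%03d", seq_along(scores))) {
  structure(list(true_scores = scores, true_order = order(scores),
                 states = rep(c(1L, 2L), length.out = length(scores)),
                 specimen_ids = ids, grid = sort(scores)),
            class = "synthetic_truth")
}

fake_ordering <- function(scores, ids = sprintf("S%03d", seq_along(scores))) {
  out <- tibble::tibble(specimen_id = ids, score = scores,
                        state = rep(c(1L, 2L), length.out = length(scores)),
                        rank = rank(scores))
  attr(out, "order") <- order(scores, ids)
  class(out) <- c("pseudotime_ordering", class(out))
  out
}

test_that("pseudotime metrics recover identity, reversal, and the rank formula", {
  s <- seq(0, 1, length.out = 20)
  expect_equal(pseudotime_metrics(fake_ordering(s), fake_truth(s)),
               tibble::tibble(rho = 1, rho_oriented = 1, rmse = 0))
  rev <- pseudotime_metrics(fake_ordering(1 - s), fake_truth(s))
  expect_equal(rev$rho, -1)
  expect_equal(rev$rho_oriented, 1)
  expect_equal(rev$rmse, 0)
  # hand evaluation of 1 - 6 sum(d^2) / (n(n^2-1))
  got <- pseudotime_metrics(fake_ordering(c(1, 3, 2, 4)), fake_truth(c(1, 2, 3, 4)))
  expect_equal(got$rho, 1 - 6 * 2 / (4 * 15))
  expect_equal(got$rho, 0.8)
  expect_error(pseudotime_metrics(fake_ordering(s), fake_truth(s[-1])), "match")
})

test_that("rank-based AUC matches perfect, random, and cross-checked scores", {
  expect_identical(roc_auc(c(5, 4, 1, 0), c(1, 1, 0, 0)), 1)
  expect_identical(roc_auc(c(0, 1, 5, 6), c(1, 1, 0, 0)), 0)
  withr::with_seed(11, {
    scores <- rnorm(200)
    labels <- rbinom(200, 1, 0.3)
    a <- roc_auc(scores, labels)
    expect_lt(abs(a - 0.5), 0.1)
    # independent cross-check against pROC's trapezoidal AUC
    skip_if_not_installed("pROC")
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                   direction = "<"))))
  })
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "AUC undefined")
})

test_that("edge-recovery metrics evaluate the standard confusion formulas", {
  # 4 AS x 1 RBP: 12 a-candidates + 4 b-candidates = 16 positions.
  # Truth: 5 positives. Fits call 4 edges: 3 true, 1 false.
  A <- matrix(0, 4, 4); B <- matrix(0, 4, 1)
  A[1, 2] <- A[2, 3] <- A[3, 4] <- A[4, 1] <- 0.5   # 4 positives in A
  B[1, 1] <- 0.5                                    # 1 positive in B
  C <- matrix(0, 1, 1)
  sys <- dyn_system(A, B, C, d = rep(1, 4), d_prime = 1)
  called_keys <- list(c("AS2", "AS1"), c("AS3", "AS2"), c("AS4", "AS3"),
                      c("AS3", "AS1"))  # 3 TP + 1 FP  -> FN = 2, TN = 10
  fits <- lapply(1:4, function(i) {
    peers <- setdiff(paste0("AS", 1:4), paste0("AS", i))
    ids <- c(peers, "RBP1", "degradation")
    truth_nonzero <- c(A[i, match(peers, paste0("AS", 1:4))], B[i, 1], 1)
    called <- vapply(ids, function(p)
      any(vapply(called_keys, function(k)
        k[1] == p && k[2] == paste0("AS", i), logical(1))), logical(1))
    score_sd <- ifelse(truth_nonzero != 0, 0.1, 1)  # separable scores
    s <- tibble::tibble(predictor_id = ids,
                        role = c(rep("as_as", 3), "rbp_as", "degradation"),
                        mean = ifelse(truth_nonzero != 0, 0.5, 0.01),
                        sd = score_sd,
                        ci_low = ifelse(called, 0.2, -0.5),
                        ci_high = ifelse(called, 0.8, 0.5))
    make_fit(paste0("AS", i), "AS", s)
  })
  fits[[5]] <- make_fit("RBP1", "RBP",
                        tibble::tibble(predictor_id = "degradation",
                                       role = "degradation", mean = 1, sd = 0.1,
                                       ci_low = 0.8, ci_high = 1.2))
  names(fits) <- c(paste0("AS", 1:4), "RBP1")
  called <- call_edges(fits)
  m <- edge_recovery_metrics(sys, fits, called)
  expect_identical(m$auc, 1)  # scores separate positives perfectly
  expect_equal(m$ppv, 3 / 4)
  expect_equal(m$accuracy, 13 / 16)
  # (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))
  expect_equal(m$matthews, (3 * 10 - 1 * 2) / sqrt(4 * 5 * 11 * 12))
})

test_that("benchmark replicates are deterministic and respect metric bounds", {
  r1 <- suppressWarnings(run_benchmark(4:5,
    config = run_config(mcmc = list(iterations = 1200L, burn_in = 400L,
                                    thinning = 2L))))
  r2 <- suppressWarnings(run_benchmark(4:5,
    config = run_config(mcmc = list(iterations = 1200L, burn_in = 400L,
                                    thinning = 2L))))
  expect_identical(r1, r2)
  expect_true(all(r1$auc >= 0 & r1$auc <= 1))
  expect_true(all(abs(r1$rho) <= 1))
  expect_true(all(r1$matthews >= -1 & r1$matthews <= 1))
  expect_true(all(r1$accuracy >= 0 & r1$accuracy <= 1))
  # the fast path stops after the ordering metrics
  fast <- run_benchmark(4:5, infer_network = FALSE)
  expect_false("auc" %in% colnames(fast))
})

test_that("the robustness sweep degrades ordering gracefully with noise", {
  sw <- suppressWarnings(robustness_sweep(
    cv_targets = c(0, 0.15, 0.30), replicates = 3, base_seed = 2,
    infer_network = FALSE))
  expect_identical(nrow(sw), 9L)
  agg <- tapply(sw$rho, sw$level, mean)
  expect_lte(agg[["3"]], agg[["1"]] + 0.01)
  expect_identical(unique(sw$cv[sw$level == 1]), 0)
  expect_gt(mean(sw$cv[sw$level == 3]), 0.25)
  expect_error(robustness_sweep(mu_grid = c(-0.1, 0)), ">= 0")
})

test_that("warping pseudotime perturbs coefficients continuously", {
  pc <- suppressWarnings(perturbation_convergence(
    deltas = c(0.1, 0.05, 0.01, 0), seed = 2, n_specimens = 60,
    config = run_config(mcmc = list(iterations = 1500L, burn_in = 500L,
                                    thinning = 2L))))
  expect_identical(pc$delta, c(0.1, 0.05, 0.01, 0))
  expect_identical(pc$coef_distance[4], 0)
  expect_true(all(diff(pc$coef_distance) <= 0))
  # the warp's L2 norm matches the analytic value delta / sqrt(2)
  expect_equal(pc$warp_l2[1:3], pc$delta[1:3] / sqrt(2), tolerance = 0.05)
})
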