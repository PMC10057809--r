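# Pseudotime inference, matrix ordering, trajectory smoothing.

test_that("a monotone profile is ordered exactly (sorting oracle)", {
  n <- 30
  vals <- withr::with_seed(1, sort(runif(n, 0, 10)))
  m <- matrix(vals, 1, n, dimnames = list("RBP1", sprintf("S%03d", 1:n)))
  annot <- simple_annot(colnames(m), c(rep(1L, 15), rep(2L, 15)))
  ord <- infer_pseudotime(m, annot, n_neighbors = 5)
  # oracle: sorting the single feature
  expect_identical(attr(ord, "order"), order(vals))
  expect_equal(cor(ord$score, vals, method = "spearman"), 1)
  expect_true(all(ord$score >= 0 & ord$score <= 1))
})

test_that("scores are equivariant under permuting the input columns", {
  m <- random_matrix(8, 40, seed = 2, prefix = "RBP")
  annot <- simple_annot(colnames(m), rep(c(1L, 2L), each = 20))
  ord1 <- infer_pseudotime(m, annot, n_neighbors = 6)
  perm <- withr::with_seed(3, sample.int(40))
  ord2 <- infer_pseudotime(m[, perm], annot, n_neighbors = 6)
  merged <- merge(as.data.frame(ord1[, c("specimen_id", "score")]),
                  as.data.frame(ord2[, c("specimen_id", "score")]),
                  by = "specimen_id")
  expect_equal(merged$score.x, merged$score.y, tolerance = 1e-8)
})

test_that("epithelial specimens sit at the low end of the score (orientation)", {
  for (s in 1:5) {
    m <- random_matrix(6, 30, seed = s, prefix = "RBP")
    states <- withr::with_seed(s + 100, sample(c(rep(1L, 15), rep(2L, 15))))
    ord <- infer_pseudotime(m, simple_annot(colnames(m), states), n_neighbors = 5)
    expect_lte(mean(ord$score[ord$state == 1L]), mean(ord$score[ord$state == 2L]))
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  m <- random_matrix(3, 20, seed = 4, prefix = "RBP")
  expect_error(infer_pseudotime(m, simple_annot(colnames(m), rep(1L, 20))),
               "both states")
  expect_error(infer_pseudotime(m, simple_annot(colnames(m), rep(c(1L, 2L), 10)),
                                n_neighbors = 25),
               "n_neighbors")
  m[1, 1] <- NA
  expect_error(infer_pseudotime(m, simple_annot(colnames(m), rep(c(1L, 2L), 10))),
               "complete")
})

test_that("ordering matrices is invertible and matches the barcodes", {
  as_m <- random_matrix(4, 20, seed = 5, prefix = "AS")
  rbp_m <- random_matrix(3, 20, seed = 6, prefix = "RBP")
  annot <- simple_annot(colnames(as_m), rep(c(1L, 2L), 10))
  ord <- infer_pseudotime(rbp_m, annot, n_neighbors = 5)
  om <- order_matrices(as_m, rbp_m, ord)
  expect_identical(colnames(om$as_expr), ord$specimen_id[attr(ord, "order")])
  expect_false(is.unsorted(om$scores))
  # applying the inverse permutation restores the originals
  inv <- match(colnames(as_m), colnames(om$as_expr))
  expect_identical(om$as_expr[, inv], as_m)
  expect_identical(om$rbp_expr[, inv], rbp_m)
  bad <- as_m; colnames(bad)[1] <- "ZZZ"
  expect_error(order_matrices(bad, rbp_m, ord), "barcode mismatch.*ZZZ")
})

test_that("on shuffled synthetic truth the ordered columns restore the trajectory", {
  sys <- tiny_system()
  traj <- simulate_trajectory(sys, c(1, 1.2), c(0.9, 1.1),
                              seq(0, 1, length.out = 60))
  cs <- make_cross_sectional(traj, seed = 11)
  ord <- infer_pseudotime(cs$rbp_matrix, cs$annotation, n_neighbors = 10)
  om <- order_matrices(cs$as_matrix, cs$rbp_matrix, ord)
  agreement <- cor(om$scores, cs$truth$true_scores[match(colnames(om$as_expr),
                                                         cs$truth$specimen_ids)],
                   method = "spearman")
  expect_gt(abs(agreement), 0.99)
})

test_that("kernel smoothing reproduces constants, interpolates, and tracks lines", {
  n <- 60
  scores <- seq(0, 1, length.out = n)
  const <- matrix(3.5, 1, n, dimnames = list("AS1", NULL))
  lin <- matrix(2 * scores, 1, n, dimnames = list("RBP1", NULL))
  sm <- smooth_trajectory(const, lin, scores, bandwidth = 0.08, grid_size = n)
  expect_equal(unname(sm$X[1, ]), rep(3.5, n))

  # bandwidth -> 0 with grid at the score locations: interpolation limit
  wig <- matrix(sin(6 * scores) + 2, 1, n, dimnames = list("AS1", NULL))
  sm0 <- smooth_trajectory(wig, lin, scores, bandwidth = 1e-4, grid_size = n)
  expect_equal(unname(sm0$X[1, ]), unname(wig[1, ]), tolerance = 1e-8)

  # linear feature: interior grid points within 1% of 2s
  dense <- seq(0, 1, length.out = 201)
  lin2 <- matrix(2 * dense, 1, 201, dimnames = list("RBP1", NULL))
  sml <- smooth_trajectory(matrix(1, 1, 201, dimnames = list("AS1", NULL)),
                           lin2, dense, bandwidth = 0.05, grid_size = 201)
  interior <- dense > 0.15 & dense < 0.85
  expect_lt(max(abs(sml$U[1, interior] - 2 * dense[interior]) /
                  (2 * dense[interior])), 0.01)
  expect_error(smooth_trajectory(const, lin, scores, bandwidth = -1), "bandwidth")
})
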