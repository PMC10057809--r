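# Data-cleaning and state-calling rules applied to raw expression matrices
# before pseudotime inference: marker-based EMT scoring, +/-1 SD state
# calling, missing-row filtering, kNN imputation, zero-variance filtering.

#' EMT score per specimen from marker expression
#'
#' The epithelial-mesenchymal transition score of a specimen is the
#' expression difference between Vimentin (mesenchymal marker) and
#' E-cadherin/CDH1 (epithelial marker): `VIM - CDH1`, so that high scores
#' mark mesenchymal specimens. Set `orientation = "cdh1_minus_vim"` to flip.
#'
#' @param expr Feature-by-specimen matrix containing both marker rows, with
#'   no missing values in those rows.
#' @param cdh1_id,vim_id Row identifiers of the two markers.
#' @param orientation `"vim_minus_cdh1"` (default) or `"cdh1_minus_vim"`.
#' @return Named numeric vector, one score per specimen.
#' @export
emt_score <- function(expr, cdh1_id = "CDH1", vim_id = "VIM",
                      orientation = c("vim_minus_cdh1", "cdh1_minus_vim")) {
  orientation <- match.arg(orientation)
  for (id in c(cdh1_id, vim_id)) {
    if (!id %in% rownames(expr)) stop("marker feature not found in matrix: ", id)
  }
  if (anyNA(expr[cdh1_id, ]) || anyNA(expr[vim_id, ])) {
    stop("marker rows must not contain missing values")
  }
  s <- expr[vim_id, ] - expr[cdh1_id, ]
  if (orientation == "cdh1_minus_vim") s <- -s
  s
}

#' Call epithelial / mesenchymal states from EMT scores
#'
#' Specimens more than one sample standard deviation above the mean score
#' are called mesenchymal, more than one below are called epithelial, and
#' the rest are unassigned (dropped before pseudotime inference).
#'
#' @param scores Numeric vector of EMT scores (>= 3 specimens).
#' @return Character vector of labels `"epithelial"`, `"mesenchymal"`,
#'   `"unassigned"`, named like `scores`.
#' @export
classify_states <- function(scores) {
  if (length(scores) < 3L) stop("need at least 3 specimens to call states")
  s <- sd(scores)
  if (s == 0) stop("zero variance in EMT scores: no state separation possible")
  m <- mean(scores)
  out <- rep("unassigned", length(scores))
  out[scores > m + s] <- "mesenchymal"
  out[scores < m - s] <- "epithelial"
  names(out) <- names(scores)
  out
}

#' Drop rows with too many missing entries
#'
#' Removes every feature whose missing-value count is greater than or equal
#' to `max_missing`; surviving row order is preserved.
#'
#' @param mat Feature-by-specimen matrix, possibly with `NA` entries.
#' @param max_missing Threshold (default 100, matching a 300-specimen
#'   cohort).
#' @return The filtered matrix, with attribute `dropped` listing removed
#'   feature IDs.
#' @export
filter_missing_rows <- function(mat, max_missing = 100L) {
  miss <- rowSums(is.na(mat))
  keep <- miss < max_missing
  if (!any(keep)) message("filter_missing_rows: all rows removed")
  out <- mat[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(mat)[!keep]
  out
}

#' Impute missing entries by k nearest feature rows
#'
#' For each missing cell, the k nearest rows by Euclidean distance over
#' mutually observed columns that have an observed value in that column are
#' averaged (unweighted). Rows with no usable neighbour fall back to their
#' row mean, with a message. Observed entries are never altered.
#'
#' @param mat Feature-by-specimen matrix with `NA` entries.
#' @param k Number of neighbouring rows to average. Default 1.
#' @return The completed matrix (no `NA` remaining).
#' @export
knn_impute <- function(mat, k = 1L) {
  stopifnot(k >= 1)
  if (!anyNA(mat)) return(mat)
  if (any(rowSums(!is.na(mat)) == 0L)) stop("a row has all entries missing; cannot impute")
  obs <- !is.na(mat)
  rows_missing <- which(rowSums(!obs) > 0L)
  out <- mat
  for (i in rows_missing) {
    shared <- obs & matrix(obs[i, ], nrow(mat), ncol(mat), byrow = TRUE)
    nshared <- rowSums(shared)
    diffs <- sweep(mat, 2L, mat[i, ])
    diffs[!shared] <- 0
    d2 <- rowSums(diffs^2, na.rm = TRUE)
    d2[i] <- Inf
    d2[nshared == 0L] <- Inf
    for (j in which(!obs[i, ])) {
      cand <- which(obs[, j] & is.finite(d2))
      if (length(cand) == 0L) {
        message("knn_impute: row ", rownames(mat)[i] %||% i,
                " has no usable neighbour; falling back to row mean")
        out[i, j] <- mean(mat[i, ], na.rm = TRUE)
      } else {
        nb <- cand[order(d2[cand], cand)][seq_len(min(k, length(cand)))]
        out[i, j] <- mean(mat[nb, j])
      }
    }
  }
  out
}

#' Drop constant rows
#'
#' Removes features whose row variance is exactly zero. Requires a complete
#' matrix (run after imputation).
#'
#' @param mat Complete feature-by-specimen matrix.
#' @return The filtered matrix, with attribute `dropped` listing removed
#'   feature IDs.
#' @export
drop_zero_variance <- function(mat) {
  if (anyNA(mat)) stop("matrix must be complete; impute first")
  v <- apply(mat, 1L, var)
  out <- mat[v > 0, , drop = FALSE]
  attr(out, "dropped") <- rownames(mat)[v == 0]
  out
}

#' Full cleaning pipeline for one matrix
#'
#' Applies, in order: missing-row filter, kNN imputation, zero-variance
#' filter. Idempotent on already-clean matrices. Returns the cleaned matrix
#' with a `cleaning_report` attribute (tibble of rows dropped per rule).
#'
#' @inheritParams filter_missing_rows
#' @inheritParams knn_impute
#' @return Cleaned complete matrix.
#' @export
preprocess_matrix <- function(mat, max_missing = 100L, k = 1L) {
  f <- filter_missing_rows(mat, max_missing = max_missing)
  imp <- knn_impute(f, k = k)
  out <- drop_zero_variance(imp)
  report <- tibble::tibble(
    rule = c("missing_rows", "zero_variance"),
    n_dropped = c(length(attr(f, "dropped")), length(attr(out, "dropped"))))
  attr(out, "dropped") <- NULL
  attr(out, "cleaning_report") <- report
  out
}
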