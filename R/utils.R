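# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. All stochastic stages go through this so pipelines are exactly
# reproducible per seed.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic substream seeds: small offsets keep everything < 2^31.
substream <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

#' Rank-based area under the ROC curve
#'
#' Computes the area under the receiver operating characteristic curve by
#' the trapezoidal rule, using the Mann-Whitney rank identity (ties receive
#' average ranks, equivalent to the trapezoid through tied score blocks).
#'
#' @param scores Numeric vector of candidate scores (larger = more likely
#'   positive).
#' @param labels Logical or 0/1 vector of the same length; `TRUE`/1 marks a
#'   true positive candidate.
#' @return A single number in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: need at least one positive and one negative label")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Min-max rescale to [0, 1]; constant input maps to 0.5.
rescale01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(rep(0.5, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
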