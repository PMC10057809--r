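# Reading and writing the delimited-table formats used throughout: expression
# matrices, specimen annotations, edge lists and the run configuration.
# Single home for format dialects; nothing else in the package parses files.

#' Read a feature-by-specimen expression matrix
#'
#' Expects a delimited text table whose first column holds feature
#' identifiers and whose header row holds specimen barcodes. Row and column
#' order are preserved exactly as on disk; entries equal to `missing_marker`
#' become `NA`.
#'
#' @param path Path to a delimited text file.
#' @param missing_marker String marking a missing cell. Default `"NA"`.
#' @param delim Field delimiter. Default tab.
#' @return A numeric matrix (features x specimens) with feature IDs as
#'   rownames and specimen barcodes as colnames. Missing cells are `NA`;
#'   every other cell is finite.
#' @export
read_expression <- function(path, missing_marker = "NA", delim = "\t") {
  tab <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE,
                           show_col_types = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs a feature column plus at least one specimen column")
  feat <- as.character(tab[[1L]])
  dup <- unique(feat[duplicated(feat)])
  if (length(dup) > 0L) {
    stop("duplicate feature IDs: ", paste(dup, collapse = ", "))
  }
  spec <- colnames(tab)[-1L]
  dup <- unique(spec[duplicated(spec)])
  if (length(dup) > 0L) {
    stop("duplicate specimen barcodes: ", paste(dup, collapse = ", "))
  }
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(cells) <- "character"
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & cells != missing_marker, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell at row %d (feature %s), column %d (specimen %s): '%s'",
                 bad[1, 1], feat[bad[1, 1]], bad[1, 2], spec[bad[1, 2]],
                 cells[bad[1, , drop = FALSE]]))
  }
  vals[cells == missing_marker] <- NA_real_
  if (any(!is.na(vals) & !is.finite(vals))) stop("non-finite entries in expression matrix")
  dimnames(vals) <- list(feat, spec)
  vals
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: tab-separated, first column `feature_id`,
#' one column per specimen, `NA` for missing cells. Round-trips losslessly
#' at full printed precision.
#'
#' @param mat Numeric matrix with feature rownames and specimen colnames.
#' @param path Output path.
#' @param missing_marker String to write for `NA` cells.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, missing_marker = "NA", delim = "\t") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  tab <- tibble::as_tibble(mat, .name_repair = "minimal")
  tab <- tibble::add_column(tab, feature_id = rownames(mat), .before = 1L)
  readr::write_delim(tab, path, delim = delim, na = missing_marker)
  invisible(path)
}

#' Read a specimen annotation table
#'
#' Expects columns `specimen_id` and `state` (1 = epithelial,
#' 2 = mesenchymal) and optional `stage` / `tnm` string columns. Empty
#' optional fields become `NA`.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter. Default tab.
#' @return A tibble with columns `specimen_id` (character), `state`
#'   (integer in \{1, 2\}), `stage`, `tnm` (character, `NA` where absent).
#' @export
read_annotation <- function(path, delim = "\t") {
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (!all(c("specimen_id", "state") %in% colnames(tab))) {
    stop("annotation table must have columns specimen_id and state")
  }
  out <- tibble::tibble(
    specimen_id = as.character(tab$specimen_id),
    state = suppressWarnings(as.integer(tab$state)),
    stage = if ("stage" %in% colnames(tab)) as.character(tab$stage) else NA_character_,
    tnm = if ("tnm" %in% colnames(tab)) as.character(tab$tnm) else NA_character_
  )
  out$stage[!is.na(out$stage) & out$stage == ""] <- NA_character_
  out$tnm[!is.na(out$tnm) & out$tnm == ""] <- NA_character_
  validate_annotation(out)
  out
}

validate_annotation <- function(annot) {
  if (anyNA(annot$state) || !all(annot$state %in% c(1L, 2L))) {
    bad <- unique(annot$specimen_id[is.na(annot$state) | !(annot$state %in% c(1L, 2L))])
    stop("state labels must be 1 (epithelial) or 2 (mesenchymal); offending specimens: ",
         paste(head(bad, 5L), collapse = ", "))
  }
  if (anyDuplicated(annot$specimen_id)) stop("duplicate specimen barcodes in annotation")
  invisible(annot)
}

#' Write / read a regulatory-network edge list
#'
#' Edge lists are tab-separated with columns `source`, `target`, `sign`,
#' `mean` (coefficient posterior mean), `ci_low`, `ci_high`, written in
#' deterministic order (source then target, lexicographic). An empty
#' network writes a header-only file.
#'
#' @param net A `regulatory_network` object (see [call_edges()]).
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path` invisibly for the writer; a `regulatory_network` for the
#'   reader.
#' @export
write_network <- function(net, path, delim = "\t") {
  stopifnot(inherits(net, "regulatory_network"))
  edges <- dplyr::arrange(net$edges, .data$source, .data$target)
  readr::write_delim(edges, path, delim = delim)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, delim = "\t") {
  edges <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                             progress = FALSE, show_col_types = FALSE)
  need <- c("source", "target", "sign", "mean", "ci_low", "ci_high")
  if (!all(need %in% colnames(edges))) {
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  }
  edges <- tibble::as_tibble(edges)[, need]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.character(edges$sign)
  nodes <- tibble::tibble(id = unique(c(edges$source, edges$target)),
                          type = NA_character_)
  new_regulatory_network(nodes, edges, state_tag = "all")
}

#' Run configuration
#'
#' Bundles every tunable of the pipeline with validated defaults. A
#' configuration can also be read from a YAML file with the same keys
#' (nested `mcmc` section).
#'
#' @param seed Integer seed threaded through all stochastic stages.
#' @param bandwidth Gaussian kernel bandwidth for trajectory smoothing, on
#'   the \[0, 1\] pseudotime scale; `NULL` (default) uses one mean specimen
#'   spacing (see [smooth_trajectory()]).
#' @param grid_size Number of uniform grid points for the smoothed
#'   trajectory; `NULL` means "number of specimens".
#' @param knn_k Neighbours for kNN imputation of missing values.
#' @param n_neighbors Neighbours for the pseudotime kNN graph.
#' @param mcmc List with `iterations`, `burn_in`, `thinning`.
#' @param ci_level Credible level for edge calling, in (0, 1).
#' @param top_as,top_rbp How many trend-ranked AS events / RBPs to keep.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, bandwidth = NULL, grid_size = NULL,
                       knn_k = 1L, n_neighbors = 15L,
                       mcmc = list(iterations = 5000L, burn_in = 1000L, thinning = 2L),
                       ci_level = 0.95, top_as = 50L, top_rbp = 10L) {
  stopifnot(is.null(bandwidth) || bandwidth > 0, is.null(grid_size) || grid_size >= 3,
            knn_k >= 1, n_neighbors >= 1,
            mcmc$iterations >= 1, mcmc$burn_in >= 0, mcmc$thinning >= 1,
            top_as >= 1, top_rbp >= 1)
  if (mcmc$burn_in >= mcmc$iterations) stop("mcmc burn_in must be < iterations")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  structure(list(seed = as.integer(seed), bandwidth = bandwidth,
                 grid_size = grid_size, knn_k = as.integer(knn_k),
                 n_neighbors = as.integer(n_neighbors),
                 mcmc = lapply(mcmc, as.integer), ci_level = ci_level,
                 top_as = as.integer(top_as), top_rbp = as.integer(top_rbp)),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML configuration file.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}
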