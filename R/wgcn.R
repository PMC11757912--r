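# Weighted gene co-expression network: |Pearson r| thresholding with
# soft-power edge weights |r|^beta, node weights as weighted degree, giant
# component extraction (graph.R), and the unsigned topological overlap
# measure on the resulting adjacency.

#' Correlation-thresholded co-expression network
#'
#' Nodes are the requested genes; an edge joins genes i and j iff
#' |Pearson r_ij| >= `r_min`, with weight |r_ij|^beta.  Genes with constant
#' expression are excluded with a warning (their correlation is undefined).
#'
#' @param em an [expression_matrix()] on a log scale.
#' @param genes character vector of gene ids (e.g. the DEG list); must be a
#'   subset of the matrix genes.
#' @param r_min correlation threshold in (0, 1).
#' @param beta soft power (>= 1) applied to |r|.
#' @return a [weighted_graph()] whose nodes are the non-constant genes.
#' @export
correlation_network <- function(em, genes, r_min = 0.7, beta = 1) {
  if (r_min <= 0 || r_min >= 1) stopf("r_min must lie in (0, 1)")
  if (beta < 1) stopf("beta must be >= 1")
  missing <- setdiff(genes, rownames(em$values))
  if (length(missing)) stopf("genes absent from matrix: %s",
                             paste(utils::head(missing, 5), collapse = ", "))
  vals <- em$values[genes, , drop = FALSE]
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0)) {
    warnf("excluding %d constant-expression gene(s)", sum(sds == 0))
    vals <- vals[sds > 0, , drop = FALSE]
  }
  if (nrow(vals) < 2) return(weighted_graph(nodes = rownames(vals)))
  r <- stats::cor(t(vals))
  a <- abs(r)
  a[a < r_min] <- 0
  diag(a) <- 0
  graph_from_adjacency(a^beta, eps = 0)
}

#' Topological overlap measure
#'
#' For an adjacency with entries a_ij in \[0, 1\]:
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) for
#' i != j, where k_i = sum_u a_iu; TOM_ii = 1.  The input is symmetrized as
#' (A + t(A))/2 before use as a guard.
#'
#' @param x a [weighted_graph()] with edge weights in \[0, 1\], or a
#'   symmetric adjacency matrix with such entries.
#' @return symmetric matrix with unit diagonal and entries in \[0, 1\].
#' @export
tom <- function(x) {
  a <- if (inherits(x, "weighted_graph")) adjacency_matrix(x) else as.matrix(x)
  if (nrow(a) != ncol(a)) stopf("adjacency must be square")
  diag(a) <- 0
  a <- (a + t(a)) / 2
  if (any(a < 0) || any(a > 1)) stopf("adjacency entries must lie in [0, 1]")
  k <- rowSums(a)
  l <- a %*% a
  kmin <- outer(k, k, pmin)
  tomm <- (l + a) / (kmin + 1 - a)
  diag(tomm) <- 1
  dimnames(tomm) <- dimnames(a)
  tomm
}

#' Graph with TOM similarities as edge weights
#'
#' Convenience wrapper: computes [tom()] on a graph's adjacency and returns
#' the graph whose edges connect node pairs with positive topological
#' overlap.
#'
#' @param graph a [weighted_graph()] with weights in \[0, 1\].
#' @return a [weighted_graph()] with TOM edge weights.
#' @export
tom_graph <- function(graph) {
  tm <- tom(graph)
  diag(tm) <- 0
  graph_from_adjacency(tm, eps = 0)
}
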