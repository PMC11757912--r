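# Core-proximity scoring: convert similarities to edge lengths, compute
# all-pairs shortest paths with Dijkstra's algorithm, and score each node j
# by
#
#   D_j = (mean SP from noncore genes to j - mean SP from core genes to j)
#         / (mean SP from all genes to j)
#
# so that D_j > 0 means node j sits closer to the designated core set than
# to the rest of the network.  Sums exclude i = j; the core/noncore counts
# are recomputed per node after that exclusion, which keeps the score
# defined for core members as well.

#' Convert similarity weights to shortest-path edge lengths
#'
#' `one_minus_sim`: length = max(1 - similarity, eps);
#' `reciprocal`: length = 1 / similarity (zero-similarity edges are dropped
#' with a warning).  Higher similarity always gives a strictly shorter edge.
#'
#' @param x a [weighted_graph()] whose weights are similarities, or a
#'   symmetric similarity matrix (e.g. a TOM) from which a graph is built.
#' @param mode `"one_minus_sim"` (default, natural for TOM in \[0,1\]) or
#'   `"reciprocal"`.
#' @param eps positive floor for lengths under `one_minus_sim`.
#' @return a [weighted_graph()] whose weights are lengths.
#' @export
edge_lengths <- function(x, mode = c("one_minus_sim", "reciprocal"),
                         eps = 1e-6) {
  mode <- match.arg(mode)
  g <- if (inherits(x, "weighted_graph")) x else {
    m <- as.matrix(x); diag(m) <- 0; graph_from_adjacency(m, eps = 0)
  }
  e <- g$edges
  if (mode == "one_minus_sim") {
    if (any(e$weight < 0 | e$weight > 1))
      stopf("one_minus_sim expects similarities in [0, 1]")
    e$weight <- pmax(1 - e$weight, eps)
  } else {
    drop <- e$weight == 0
    if (any(drop)) {
      warnf("dropping %d zero-similarity edge(s) under reciprocal mode",
            sum(drop))
      e <- e[!drop, , drop = FALSE]
    }
    e$weight <- 1 / e$weight
  }
  weighted_graph(e, nodes = g$nodes)
}

#' All-pairs shortest-path lengths (Dijkstra)
#'
#' @param graph a [weighted_graph()] whose weights are non-negative lengths.
#' @return symmetric matrix of shortest-path lengths with zero diagonal;
#'   unreachable pairs are `Inf`.
#' @export
all_pairs_dijkstra <- function(graph) {
  if (any(graph$edges$weight < 0)) stopf("edge lengths must be >= 0")
  n <- n_nodes(graph)
  nbr <- adjacency_list(graph)
  sp <- matrix(Inf, n, n, dimnames = list(graph$nodes, graph$nodes))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    done <- rep(FALSE, n)
    repeat {
      u <- NA_integer_
      best <- Inf
      for (v in seq_len(n)) {
        if (!done[v] && dist[v] < best) { best <- dist[v]; u <- v }
      }
      if (is.na(u)) break
      done[u] <- TRUE
      nb <- nbr[[u]]
      if (nrow(nb)) {
        alt <- dist[u] + nb[, 2L]
        upd <- alt < dist[nb[, 1L]]
        dist[nb[upd, 1L]] <- alt[upd]
      }
    }
    sp[s, ] <- dist
  }
  sp
}

#' Core-proximity D-scores
#'
#' For each node j, with sums over i != j restricted to nodes reachable
#' from j: D_j = (sum_{i notin core} SP_ij / NC - sum_{i in core} SP_ij / C)
#' / (sum_i SP_ij / (NC + C)).  Positive D_j means j lies nearer the core
#' set than the network background.
#'
#' @param sp shortest-path matrix from [all_pairs_dijkstra()].
#' @param core non-empty character vector of core node ids; must be a proper
#'   subset of the matrix nodes.
#' @return data frame: `gene`, `d_score`, `mean_sp_core`, `mean_sp_noncore`,
#'   `mean_sp_all`, `is_core`, `defined` (FALSE where C or NC is empty after
#'   excluding j and unreachable nodes).
#' @export
d_score <- function(sp, core) {
  nodes <- rownames(sp)
  if (is.null(nodes)) stopf("sp matrix must have node dimnames")
  core <- unique(as.character(core))
  if (length(core) == 0) stopf("core set is empty")
  if (!all(core %in% nodes))
    stopf("core ids absent from the SP matrix: %s",
          paste(utils::head(setdiff(core, nodes), 5), collapse = ", "))
  if (length(core) >= length(nodes))
    stopf("core must be a proper subset of the nodes")
  is_core <- nodes %in% core
  out <- data.frame(gene = nodes, d_score = NA_real_, mean_sp_core = NA_real_,
                    mean_sp_noncore = NA_real_, mean_sp_all = NA_real_,
                    is_core = is_core, defined = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_along(nodes)) {
    d <- sp[, j]
    reach <- is.finite(d) & seq_along(nodes) != j
    ci <- reach & is_core
    ni <- reach & !is_core
    C <- sum(ci); NC <- sum(ni)
    if (C == 0 || NC == 0) next       # score undefined; flagged
    mc <- sum(d[ci]) / C
    mn <- sum(d[ni]) / NC
    ma <- sum(d[ci | ni]) / (C + NC)
    if (ma <= 0) next
    out$mean_sp_core[j] <- mc
    out$mean_sp_noncore[j] <- mn
    out$mean_sp_all[j] <- ma
    out$d_score[j] <- (mn - mc) / ma
    out$defined[j] <- TRUE
  }
  out
}

#' Positive-D subnetwork around the core
#'
#' Induced subgraph on the core nodes plus every node with a positive
#' D-score.
#'
#' @param graph the [weighted_graph()] the scores were computed on.
#' @param dtable output of [d_score()].
#' @return list: `graph` (the induced subgraph), `core_nodes`,
#'   `neighbor_nodes` (positive-D noncore nodes).
#' @export
core_subnetwork <- function(graph, dtable) {
  core <- dtable$gene[dtable$is_core]
  pos <- dtable$gene[!dtable$is_core & dtable$defined & dtable$d_score > 0]
  if (length(pos) == 0)
    warnf("no noncore node has a positive D-score; returning the core alone")
  sub <- induced_subgraph(graph, c(core, pos))
  list(graph = sub, core_nodes = intersect(core, sub$nodes),
       neighbor_nodes = intersect(pos, sub$nodes))
}
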