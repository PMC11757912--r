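# Undirected weighted graph: the shared container for the co-expression and
# interaction network stages.  Deliberately minimal -- a node vector plus an
# edge data frame -- so every algorithm in the package states its own
# traversal explicitly.

#' Construct an undirected weighted graph
#'
#' @param edges data frame with columns `from`, `to` and optionally `weight`
#'   (default 1).  Self-loops are rejected; duplicate edges (either
#'   orientation) are merged keeping the maximum weight.
#' @param nodes character vector of node ids.  Defaults to the ids appearing
#'   in `edges`; isolated nodes can be added by passing a superset.
#' @return object of class `weighted_graph` with elements `nodes` (character)
#'   and `edges` (data frame `from`, `to`, `weight`, with `from < to`).
#' @export
weighted_graph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(edges)))
      stopf("edges must have columns 'from' and 'to'")
    if (is.null(edges$weight)) edges$weight <- 1
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
      stopf("edge weights must be finite and non-negative")
    if (any(edges$from == edges$to)) stopf("self-loops are not allowed")
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    key <- paste(a, b, sep = "\r")
    w <- tapply(edges$weight, key, max)
    keep <- !duplicated(key)
    edges <- data.frame(from = a[keep], to = b[keep],
                        weight = as.numeric(w[key[keep]]),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  if (anyDuplicated(nodes)) stopf("duplicate node ids")
  structure(list(nodes = nodes, edges = edges), class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_nodes <- function(g) length(g$nodes)
n_edges <- function(g) nrow(g$edges)

#' Dense adjacency matrix of a weighted graph
#'
#' @param graph a [weighted_graph()].
#' @param weighted logical; `FALSE` gives the 0/1 skeleton.
#' @return symmetric numeric matrix with dimnames = node ids, zero diagonal.
#' @export
adjacency_matrix <- function(graph, weighted = TRUE) {
  n <- n_nodes(graph)
  a <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (n_edges(graph) > 0) {
    i <- match(graph$edges$from, graph$nodes)
    j <- match(graph$edges$to, graph$nodes)
    w <- if (weighted) graph$edges$weight else 1
    a[cbind(i, j)] <- w
    a[cbind(j, i)] <- w
  }
  a
}

#' Build a weighted graph from a symmetric adjacency matrix
#'
#' Entries below `eps` are treated as absent; the diagonal is ignored.
#'
#' @param a symmetric numeric matrix with dimnames.
#' @param eps edges with |weight| <= eps are dropped.
#' @return a [weighted_graph()].
#' @export
graph_from_adjacency <- function(a, eps = 0) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  ids <- rownames(a) %||% sprintf("V%d", seq_len(nrow(a)))
  idx <- which(upper.tri(a) & a > eps, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      weight = a[idx], stringsAsFactors = FALSE)
  weighted_graph(edges, nodes = ids)
}

# adjacency list: for each node index, matrix of (neighbor index, weight)
adjacency_list <- function(graph) {
  n <- n_nodes(graph)
  nbr <- vector("list", n)
  for (k in seq_len(n)) nbr[[k]] <- cbind(integer(), numeric())
  if (n_edges(graph) > 0) {
    i <- match(graph$edges$from, graph$nodes)
    j <- match(graph$edges$to, graph$nodes)
    w <- graph$edges$weight
    ii <- c(i, j); jj <- c(j, i); ww <- c(w, w)
    ord <- order(ii)
    ii <- ii[ord]; jj <- jj[ord]; ww <- ww[ord]
    starts <- c(which(!duplicated(ii)), length(ii) + 1L)
    us <- unique(ii)
    for (k in seq_along(us)) {
      rng <- starts[k]:(starts[k + 1L] - 1L)
      nbr[[us[k]]] <- cbind(jj[rng], ww[rng])
    }
  }
  nbr
}

#' Connected components of a graph
#'
#' @param graph a [weighted_graph()].
#' @return integer vector of component memberships (1-based), named by node.
#' @export
graph_components <- function(graph) {
  n <- n_nodes(graph)
  comp <- rep(NA_integer_, n)
  nbr <- adjacency_list(graph)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (u in nbr[[v]][, 1L]) {
        if (is.na(comp[u])) { comp[u] <- cid; queue <- c(queue, u) }
      }
    }
  }
  stats::setNames(comp, graph$nodes)
}

#' Induced subgraph on a node subset
#'
#' @param graph a [weighted_graph()].
#' @param nodes character vector of node ids to keep.
#' @return a [weighted_graph()].
#' @export
induced_subgraph <- function(graph, nodes) {
  nodes <- intersect(graph$nodes, nodes)
  keep <- graph$edges$from %in% nodes & graph$edges$to %in% nodes
  weighted_graph(graph$edges[keep, , drop = FALSE], nodes = nodes)
}

#' Giant (largest connected) component
#'
#' Ties in component size are broken in favour of the component containing
#' the lexicographically smallest node id.
#'
#' @param graph a non-empty [weighted_graph()].
#' @return the induced subgraph on the largest component.
#' @export
giant_component <- function(graph) {
  if (n_nodes(graph) == 0) stopf("empty graph has no giant component")
  comp <- graph_components(graph)
  sizes <- table(comp)
  best_size <- max(sizes)
  cands <- as.integer(names(sizes)[sizes == best_size])
  # nodes are sorted, so the first node in a tied component is its smallest id
  first_node <- vapply(cands, function(cid) min(names(comp)[comp == cid]), "")
  chosen <- cands[order(first_node)[1L]]
  induced_subgraph(graph, names(comp)[comp == chosen])
}

#' Node weights as weighted degree (strength)
#'
#' Converts edge weights into per-node weights by summing incident edge
#' weights; isolated nodes get 0.
#'
#' @param graph a [weighted_graph()].
#' @return named numeric vector over all nodes.
#' @export
node_weights_from_edges <- function(graph) {
  w <- stats::setNames(rep(0, n_nodes(graph)), graph$nodes)
  if (n_edges(graph) > 0) {
    s <- tapply(c(graph$edges$weight, graph$edges$weight),
                c(graph$edges$from, graph$edges$to), sum)
    w[names(s)] <- as.numeric(s)
  }
  w
}

#' Unweighted node degrees
#'
#' @param graph a [weighted_graph()].
#' @return named integer vector.
#' @export
graph_degree <- function(graph) {
  d <- stats::setNames(integer(n_nodes(graph)), graph$nodes)
  if (n_edges(graph) > 0) {
    t <- table(c(graph$edges$from, graph$edges$to))
    d[names(t)] <- as.integer(t)
  }
  d
}
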