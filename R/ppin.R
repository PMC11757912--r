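# Protein-protein interaction network stage: STRING-dialect edge parsing,
# per-node topology statistics (degree K, betweenness BC, closeness CC,
# mean shortest-path distance) on the unweighted skeleton, whole-network
# metrics, hub/nonhub classification, and agglomerative greedy modularity
# clustering.
#
# Conventions chosen to match published node tables from this kind of
# analysis: BC is the raw (unnormalized) count of shortest-path pair
# fractions with each unordered pair counted once; CC is normalized per
# connected component as (n_comp - 1) / sum of distances, so CC and the
# per-node mean distance are reciprocal on a connected component.

#' Read a STRING-dialect interaction TSV
#'
#' Expects a header naming at least `protein1`, `protein2` and
#' `combined_score` (0-1000 scale); evidence-channel columns are optional.
#' Edges are kept iff combined_score >= `min_combined_score` and, when
#' `required_channels` is given, at least one listed channel score is > 0.
#' A-B / B-A duplicates are merged keeping the maximum score.  Edge weight
#' is combined_score / 1000.
#'
#' @param path TSV path.
#' @param min_combined_score minimum combined score (default 400, the usual
#'   medium-confidence cutoff).
#' @param required_channels optional character vector of channel column
#'   names.
#' @return a [weighted_graph()].
#' @export
read_string_edges <- function(path, min_combined_score = 400,
                              required_channels = NULL) {
  df <- read_tsv(path)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(df)))
    stopf("STRING file must have columns: %s", paste(need, collapse = ", "))
  keep <- df$combined_score >= min_combined_score
  if (!is.null(required_channels)) {
    missing <- setdiff(required_channels, names(df))
    if (length(missing))
      stopf("channel column(s) absent: %s", paste(missing, collapse = ", "))
    ch <- as.matrix(df[, required_channels, drop = FALSE])
    keep <- keep & rowSums(ch > 0) > 0
  }
  df <- df[keep, , drop = FALSE]
  weighted_graph(data.frame(from = df$protein1, to = df$protein2,
                            weight = df$combined_score / 1000,
                            stringsAsFactors = FALSE))
}

# BFS from one source on an adjacency list: distances, path counts (sigma)
# and visit order -- the ingredients of Brandes' betweenness accumulation.
bfs_counts <- function(nbr, s, n) {
  dist <- rep(-1L, n)
  sigma <- numeric(n)
  order_v <- integer(0)
  preds <- vector("list", n)
  dist[s] <- 0L
  sigma[s] <- 1
  queue <- s
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order_v <- c(order_v, v)
    for (u in nbr[[v]][, 1L]) {
      if (dist[u] < 0L) { dist[u] <- dist[v] + 1L; queue <- c(queue, u) }
      if (dist[u] == dist[v] + 1L) {
        sigma[u] <- sigma[u] + sigma[v]
        preds[[u]] <- c(preds[[u]], v)
      }
    }
  }
  list(dist = dist, sigma = sigma, order = order_v, preds = preds)
}

#' Per-node topology statistics
#'
#' Degree K, betweenness BC (Brandes' algorithm on the unweighted skeleton,
#' unordered-pair convention), closeness CC = (n_comp - 1) / sum of
#' distances within the node's component, and the mean shortest-path
#' distance = sum of distances / (n_comp - 1).  Singleton components get
#' CC = 0 and mean_distance `NA`.
#'
#' @param graph a non-empty [weighted_graph()].
#' @return data frame: `gene`, `K`, `BC`, `CC`, `mean_distance`,
#'   `component`.
#' @export
node_stats <- function(graph) {
  n <- n_nodes(graph)
  if (n == 0) stopf("empty graph")
  nbr <- adjacency_list(graph)
  comp <- graph_components(graph)
  comp_size <- table(comp)[as.character(comp)]
  K <- graph_degree(graph)
  bc <- numeric(n)
  dsum <- numeric(n)
  for (s in seq_len(n)) {
    b <- bfs_counts(nbr, s, n)
    dsum[s] <- sum(b$dist[b$dist > 0L])
    delta <- numeric(n)
    for (v in rev(b$order)) {
      for (p in b$preds[[v]]) {
        delta[p] <- delta[p] + b$sigma[p] / b$sigma[v] * (1 + delta[v])
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  bc <- bc / 2                          # each unordered pair once
  nc <- as.integer(comp_size)
  cc <- ifelse(nc > 1, (nc - 1) / dsum, 0)
  md <- ifelse(nc > 1, dsum / (nc - 1), NA_real_)
  data.frame(gene = graph$nodes, K = as.integer(K), BC = bc, CC = cc,
             mean_distance = md, component = as.integer(comp),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Whole-network topology metrics
#'
#' Transitivity (global clustering: 3 x triangles / connected triples),
#' edge density 2|E|/(n(n-1)), mean unweighted shortest-path distance over
#' reachable unordered pairs, and diameter (longest finite shortest path,
#' in edges).  Metrics that are undefined (no edges, no triples, single
#' node) are `NA`.
#'
#' @param graph a non-empty [weighted_graph()].
#' @return list: `transitivity`, `edge_density`, `mean_distance`,
#'   `diameter`.
#' @export
network_metrics <- function(graph) {
  n <- n_nodes(graph)
  if (n == 0) stopf("empty graph")
  a <- adjacency_matrix(graph, weighted = FALSE)
  k <- rowSums(a)
  triples <- sum(k * (k - 1) / 2)
  tri3 <- sum(diag(a %*% a %*% a)) / 2   # = 3 * number of triangles
  transitivity <- if (triples > 0) tri3 / triples else NA_real_
  density <- if (n > 1) 2 * n_edges(graph) / (n * (n - 1)) else NA_real_
  nbr <- adjacency_list(graph)
  tot <- 0; npairs <- 0L; diam <- 0L
  for (s in seq_len(n)) {
    d <- bfs_counts(nbr, s, n)$dist
    reach <- d > 0L
    tot <- tot + sum(d[reach])
    npairs <- npairs + sum(reach)
    if (any(reach)) diam <- max(diam, max(d[reach]))
  }
  mean_distance <- if (npairs > 0) tot / npairs else NA_real_
  diameter <- if (npairs > 0) as.integer(diam) else NA_integer_
  list(transitivity = transitivity, edge_density = density,
       mean_distance = mean_distance, diameter = diameter)
}

#' Hub / nonhub / other classification
#'
#' A node is a hub iff K > `k_hub` and BC > `bc_hub`.  Among the remaining
#' nodes, a nonhub is either (a) a direct neighbor of some hub with
#' K <= `k_nonhub` and BC < `bc_nonhub_direct`, or (b) a node at unweighted
#' distance exactly two from some hub with K <= `k_nonhub` and BC = 0.
#' Everything else is labeled `other`.  The degree bound is inclusive
#' (K <= 3 by default): published node tables of this kind label
#' degree-3 nodes as nonhubs even where the accompanying prose says
#' "less than three".
#'
#' When `graph` is `NULL` the hub-adjacency requirement cannot be checked
#' and the (K, BC)-eligibility bounds alone decide the nonhub label; this
#' mode is meant for re-scoring printed (K, BC) tables.
#'
#' @param stats data frame with columns `gene`, `K`, `BC` (e.g. from
#'   [node_stats()]).
#' @param graph the graph, or `NULL` for eligibility-only classification.
#' @param k_hub,bc_hub hub thresholds (strict >).
#' @param k_nonhub inclusive degree bound for nonhubs.
#' @param bc_nonhub_direct strict BC bound for direct-neighbor nonhubs.
#' @return `stats` with a `label` column (`hub` / `nonhub` / `other`).
#' @export
classify_nodes <- function(stats, graph = NULL, k_hub = 13, bc_hub = 63.94,
                           k_nonhub = 3, bc_nonhub_direct = 9) {
  hub <- stats$K > k_hub & stats$BC > bc_hub
  eligible_direct <- !hub & stats$K <= k_nonhub & stats$BC < bc_nonhub_direct
  if (is.null(graph)) {
    nonhub <- eligible_direct
  } else {
    hubs <- stats$gene[hub]
    dist_to_hub <- rep(Inf, nrow(stats))
    if (length(hubs)) {
      n <- n_nodes(graph)
      nbr <- adjacency_list(graph)
      dmin <- rep(Inf, n)
      for (h in intersect(hubs, graph$nodes)) {
        d <- bfs_counts(nbr, match(h, graph$nodes), n)$dist
        d[d < 0L] <- Inf
        dmin <- pmin(dmin, d)
      }
      dist_to_hub <- dmin[match(stats$gene, graph$nodes)]
    }
    nonhub <- !hub &
      ((dist_to_hub == 1 & stats$K <= k_nonhub &
          stats$BC < bc_nonhub_direct) |
       (dist_to_hub == 2 & stats$K <= k_nonhub & stats$BC == 0))
  }
  stats$label <- ifelse(hub, "hub", ifelse(nonhub, "nonhub", "other"))
  stats
}

#' Modularity of a partition
#'
#' Q = sum over communities of (e_c - a_c^2) where e_c is the fraction of
#' edges inside community c and a_c the fraction of edge endpoints in c,
#' on the unweighted graph.
#'
#' @param graph a [weighted_graph()].
#' @param membership named vector (node -> community id) covering all nodes.
#' @return modularity Q in \[-0.5, 1\].
#' @export
modularity_value <- function(graph, membership) {
  m <- n_edges(graph)
  if (m == 0) return(0)
  cm <- membership[graph$nodes]
  if (any(is.na(cm))) stopf("membership must cover every node")
  ef <- cm[graph$edges$from]; et <- cm[graph$edges$to]
  within <- sum(ef == et) / m
  deg <- graph_degree(graph)
  a_c <- tapply(deg, as.character(cm), sum) / (2 * m)
  within - sum(a_c^2)
}

#' Greedy modularity clustering (agglomerative)
#'
#' Clauset-Newman-Moore style agglomeration: every node starts in its own
#' community; at each step the pair of edge-connected communities whose
#' merge gives the largest modularity gain is merged, until no merge has a
#' positive gain.  Ties are broken by the lexicographically smallest pair
#' of community labels, a community's label being its smallest member node
#' id, so the result is deterministic.  Disconnected components are
#' clustered independently by construction (cross-component merges have no
#' edges and never gain modularity).
#'
#' @param graph a non-empty [weighted_graph()].
#' @return list: `membership` (named integer vector, clusters numbered by
#'   order of their smallest member id) and `modularity_q`.
#' @export
greedy_modularity_clusters <- function(graph) {
  n <- n_nodes(graph)
  if (n == 0) stopf("empty graph")
  m <- n_edges(graph)
  if (m == 0) {
    memb <- stats::setNames(seq_len(n), graph$nodes)
    return(list(membership = memb, modularity_q = 0))
  }
  # community-level edge fractions e (symmetric) and endpoint fractions a
  e <- matrix(0, n, n)
  i <- match(graph$edges$from, graph$nodes)
  j <- match(graph$edges$to, graph$nodes)
  for (k in seq_len(m)) {
    e[i[k], j[k]] <- e[i[k], j[k]] + 1 / (2 * m)
    e[j[k], i[k]] <- e[j[k], i[k]] + 1 / (2 * m)
  }
  a <- rowSums(e)
  active <- rep(TRUE, n)
  label <- graph$nodes                   # community label = smallest member id
  members <- as.list(seq_len(n))
  repeat {
    con <- which(e > 0 & upper.tri(e), arr.ind = TRUE)
    if (nrow(con) == 0) break
    dq <- 2 * (e[con] - a[con[, 1]] * a[con[, 2]])
    best <- max(dq)
    if (best <= 1e-12) break
    cand <- which(dq >= best - 1e-12)
    la <- pmin(label[con[, 1]], label[con[, 2]])[cand]
    lb <- pmax(label[con[, 1]], label[con[, 2]])[cand]
    pick <- cand[order(la, lb)[1L]]
    p <- con[pick, 1]; q <- con[pick, 2]
    # merge q into p (row then column keeps e symmetric and puts the two
    # internal fractions plus 2 e_pq on the new diagonal entry)
    e[p, ] <- e[p, ] + e[q, ]
    e[, p] <- e[, p] + e[, q]
    e[q, ] <- 0; e[, q] <- 0
    a[p] <- a[p] + a[q]; a[q] <- 0
    members[[p]] <- c(members[[p]], members[[q]])
    members[[q]] <- integer(0)
    label[p] <- min(label[p], label[q])
    active[q] <- FALSE
  }
  comms <- which(active)
  ord <- order(vapply(comms, function(c) min(graph$nodes[members[[c]]]), ""))
  memb <- stats::setNames(integer(n), graph$nodes)
  for (ci in seq_along(ord)) memb[members[[comms[ord[ci]]]]] <- ci
  list(membership = memb,
       modularity_q = modularity_value(graph, memb))
}
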