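# Independent oracles used across the suite.  These deliberately avoid the
# package's own traversal code: shortest paths come from Floyd-Warshall,
# path counts from adjacency-matrix powers, modularity maxima from
# exhaustive partition enumeration.

# Floyd-Warshall all-pairs shortest paths on a weighted_graph
oracle_floyd_warshall <- function(g) {
  n <- length(g$nodes)
  d <- matrix(Inf, n, n, dimnames = list(g$nodes, g$nodes))
  diag(d) <- 0
  for (r in seq_len(nrow(g$edges))) {
    i <- match(g$edges$from[r], g$nodes)
    j <- match(g$edges$to[r], g$nodes)
    w <- g$edges$weight[r]
    d[i, j] <- min(d[i, j], w)
    d[j, i] <- min(d[j, i], w)
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Unweighted shortest-path distances and path counts via matrix powers:
# the number of walks of minimal length equals the number of shortest
# paths, so sigma_st = (A^d_st)[s, t].
oracle_sp_counts <- function(g) {
  a <- adjacency_matrix(g, weighted = FALSE)
  n <- nrow(a)
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  diag(d) <- 0
  sigma <- matrix(0, n, n, dimnames = dimnames(a))
  diag(sigma) <- 1
  pw <- diag(n)
  for (len in seq_len(n)) {
    pw <- pw %*% a
    newly <- is.infinite(d) & pw > 0
    d[newly] <- len
    sigma[newly] <- pw[newly]
  }
  list(d = d, sigma = sigma)
}

# Betweenness (unordered-pair convention), closeness, per-node mean
# distance from the matrix-power oracle.
oracle_node_stats <- function(g) {
  sc <- oracle_sp_counts(g)
  d <- sc$d; sigma <- sc$sigma
  n <- nrow(d)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || is.infinite(d[s, t])) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  cc <- numeric(n); md <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    reach <- is.finite(d[v, ]) & seq_len(n) != v
    if (any(reach)) {
      cc[v] <- sum(reach) / sum(d[v, reach])
      md[v] <- sum(d[v, reach]) / sum(reach)
    }
  }
  data.frame(gene = g$nodes, BC = bc, CC = cc, mean_distance = md,
             stringsAsFactors = FALSE)
}

# Whole-network metrics by direct enumeration
oracle_metrics <- function(g) {
  a <- adjacency_matrix(g, weighted = FALSE)
  n <- nrow(a)
  tri <- 0; triples <- 0
  if (n >= 3) {
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      if (i != j && j != k && i != k && a[i, j] && a[j, k]) {
        triples <- triples + 1          # ordered open+closed triples
        if (a[i, k]) tri <- tri + 1
      }
    }
  }
  transitivity <- if (triples > 0) tri / triples else NA_real_
  d <- oracle_sp_counts(g)$d
  ut <- d[upper.tri(d)]
  fin <- ut[is.finite(ut)]
  list(transitivity = transitivity,
       edge_density = if (n > 1) nrow(g$edges) / choose(n, 2) else NA_real_,
       mean_distance = if (length(fin)) mean(fin) else NA_real_,
       diameter = if (length(fin)) as.integer(max(fin)) else NA_integer_)
}

# All set partitions of 1..n as membership vectors (restricted growth)
oracle_partitions <- function(n) {
  out <- list()
  rec <- function(memb, kmax) {
    i <- length(memb) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- memb; return(invisible()) }
    for (c in seq_len(kmax + 1L)) rec(c(memb, c), max(kmax, c))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive modularity maximum over all partitions
oracle_best_partition <- function(g) {
  parts <- oracle_partitions(length(g$nodes))
  best <- -Inf; best_memb <- NULL
  for (p in parts) {
    q <- modularity_value(g, stats::setNames(p, g$nodes))
    if (q > best + 1e-12) { best <- q; best_memb <- p }
  }
  list(membership = stats::setNames(best_memb, g$nodes), q = best)
}

# Random test graph (Erdos-Renyi, optionally weighted)
random_graph <- function(n, p = 0.4, weighted = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  nk <- sum(keep)
  edges <- data.frame(from = ids[pairs[keep, 1]], to = ids[pairs[keep, 2]],
                      weight = if (weighted)
                        stats::runif(nk, 0.1, 2) else rep(1, nk),
                      stringsAsFactors = FALSE)
  weighted_graph(edges, nodes = ids)
}

# Same-membership comparison up to relabeling
same_partition <- function(a, b) {
  a <- a[sort(names(a))]; b <- b[sort(names(b))]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Small expression matrix built by hand
toy_expression <- function(values, condition, batch = NULL,
                           scale = "log_normalized") {
  ns <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("S%02d", 1:ns)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  meta <- data.frame(sample = colnames(values), condition = condition,
                     batch = batch %||% rep("B1", ns),
                     stringsAsFactors = FALSE)
  expression_matrix(values, meta, scale = scale)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
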