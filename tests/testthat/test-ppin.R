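write_string_fixture <- function(path, rows) {
  df <- data.frame(protein1 = rows$a, protein2 = rows$b,
                   neighborhood = rows$nb %||% 0,
                   coexpression = rows$cx %||% 0,
                   experimental = rows$ex %||% rows$score,
                   database = 0, textmining = 0,
                   combined_score = rows$score)
  write_tsv(df, path)
  path
}

test_that("STRING parsing thresholds, dedups and scales weights", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_string_fixture(path, list(
    a = c("A", "B", "A", "C", "D", "E", "F", "G", "H", "A"),
    b = c("B", "A", "C", "D", "E", "F", "G", "H", "I", "D"),
    score = c(700, 700, 150, 400, 399, 955, 400, 820, 401, 640)))
  g <- read_string_edges(path, min_combined_score = 400)
  # hand count: rows >= 400 after A-B/B-A dedup -> 7 edges
  expect_equal(nrow(g$edges), 7)
  expect_equal(g$edges$weight[g$edges$from == "A" & g$edges$to == "B"], 0.7)
  expect_false(any(g$edges$from == "A" & g$edges$to == "C"))  # 150 dropped
  # channel requirement
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_string_fixture(path2, list(a = c("A", "B"), b = c("B", "C"),
                                   score = c(500, 500), ex = c(500, 0),
                                   cx = c(0, 0)))
  g2 <- read_string_edges(path2, 400, required_channels = "experimental")
  expect_equal(nrow(g2$edges), 1)
  expect_error(read_string_edges(path2, 400, required_channels = "fusion"),
               "absent")
  bad <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(x = 1), bad)
  expect_error(read_string_edges(bad), "columns")
})

test_that("node stats match hand computations on small graphs", {
  path <- weighted_graph(data.frame(from = c("A", "B"), to = c("B", "C")))
  st <- node_stats(path)
  b <- st[st$gene == "B", ]
  expect_equal(b$K, 2L)
  expect_equal(b$BC, 1)
  expect_equal(b$CC, 1)
  expect_equal(b$mean_distance, 1)
  a <- st[st$gene == "A", ]
  expect_equal(a$K, 1L)
  expect_equal(a$BC, 0)
  expect_equal(a$CC, 2 / 3)
  e4 <- t(combn(c("a", "b", "c", "d"), 2))
  k4 <- weighted_graph(data.frame(from = e4[, 1], to = e4[, 2]))
  st4 <- node_stats(k4)
  expect_true(all(st4$BC == 0))
  expect_true(all(st4$CC == 1))
})

test_that("BC/CC/mean distance match the matrix-power oracle", {
  for (seed in 1:20) {
    g <- random_graph(sample(4:10, 1), 0.4, seed = seed)
    st <- node_stats(g)
    or <- oracle_node_stats(g)
    expect_equal(st$BC, or$BC, tolerance = 1e-10)
    expect_equal(st$CC, or$CC, tolerance = 1e-10)
    expect_equal(st$mean_distance, or$mean_distance, tolerance = 1e-10)
  }
})

test_that("network metrics match enumeration on known and random graphs", {
  tri <- weighted_graph(data.frame(from = c("a", "a", "b"),
                                   to = c("b", "c", "c")))
  m <- network_metrics(tri)
  expect_equal(unlist(m), c(transitivity = 1, edge_density = 1,
                            mean_distance = 1, diameter = 1))
  p4 <- weighted_graph(data.frame(from = c("a", "b", "c"),
                                  to = c("b", "c", "d")))
  m4 <- network_metrics(p4)
  expect_equal(m4$transitivity, 0)
  expect_equal(m4$edge_density, 0.5)
  expect_equal(m4$mean_distance, 10 / 6)
  expect_equal(m4$diameter, 3L)
  for (seed in 1:15) {
    g <- random_graph(sample(3:10, 1), 0.4, seed = seed + 100)
    expect_equal(network_metrics(g), oracle_metrics(g), tolerance = 1e-10)
  }
})

test_that("hub/nonhub classification partitions nodes deterministically", {
  cfg <- simulation_config(n_hubs = 3, n_nonhubs = 8, seed = 2)
  gs <- simulate_graph(cfg)
  st <- classify_nodes(node_stats(gs$graph), gs$graph)
  expect_true(all(st$label[st$gene %in% gs$truth$planted_hubs] == "hub"))
  expect_true(all(st$label[st$gene %in% gs$truth$planted_nonhubs] == "nonhub"))
  expect_true(all(st$label %in% c("hub", "nonhub", "other")))
  st2 <- classify_nodes(node_stats(gs$graph), gs$graph)
  expect_identical(st, st2)
  # distance-2 rule requires BC exactly zero
  stf <- data.frame(gene = c("H", "M", "X"), K = c(20L, 2L, 2L),
                    BC = c(100, 5, 5))
  gsm <- weighted_graph(data.frame(from = c("H", "M"), to = c("M", "X")))
  lab <- classify_nodes(stf, gsm)$label
  expect_equal(lab, c("hub", "nonhub", "other"))
})

test_that("greedy modularity recovers planted cliques and maximizes Q", {
  cl <- function(v) as.data.frame(t(combn(v, 2)), stringsAsFactors = FALSE)
  e <- rbind(cl(paste0("a", 1:4)), cl(paste0("b", 1:4)),
             c("a1", "b1"))
  names(e) <- c("from", "to")
  g <- weighted_graph(e)
  res <- greedy_modularity_clusters(g)
  oracle <- oracle_best_partition(g)
  expect_true(same_partition(res$membership, oracle$membership))
  expect_equal(res$modularity_q, oracle$q, tolerance = 1e-12)
  # single clique stays one cluster
  k5 <- cl(paste0("c", 1:5)); names(k5) <- c("from", "to")
  res5 <- greedy_modularity_clusters(weighted_graph(k5))
  expect_equal(length(unique(res5$membership)), 1)
  # Q self-consistency and partition property on random graphs
  for (seed in 1:10) {
    g <- random_graph(sample(5:12, 1), 0.4, seed = seed + 50)
    r <- greedy_modularity_clusters(g)
    expect_setequal(names(r$membership), g$nodes)
    expect_false(any(is.na(r$membership)))
    expect_equal(r$modularity_q, modularity_value(g, r$membership),
                 tolerance = 1e-12)
  }
  expect_error(greedy_modularity_clusters(weighted_graph()), "empty")
})
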