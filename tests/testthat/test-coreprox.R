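test_that("similarity-to-length conversion is monotone in both modes", {
  g <- weighted_graph(data.frame(from = c("a", "b", "c"),
                                 to = c("b", "c", "d"),
                                 weight = c(1, 0.5, 0.25)))
  l1 <- edge_lengths(g, "one_minus_sim", eps = 1e-6)
  expect_equal(sort(l1$edges$weight), c(1e-6, 0.5, 0.75))
  l2 <- edge_lengths(g, "reciprocal")
  expect_equal(sort(l2$edges$weight), c(1, 2, 4))
  gz <- weighted_graph(data.frame(from = c("a", "b"), to = c("b", "c"),
                                  weight = c(0, 0.5)))
  expect_warning(lz <- edge_lengths(gz, "reciprocal"), "zero-similarity")
  expect_equal(nrow(lz$edges), 1)
})

test_that("Dijkstra equals Floyd-Warshall on random weighted graphs", {
  for (seed in 1:30) {
    g <- random_graph(sample(4:12, 1), 0.35, weighted = TRUE, seed = seed)
    expect_equal(all_pairs_dijkstra(g), oracle_floyd_warshall(g))
  }
  expect_error(all_pairs_dijkstra(weighted_graph(
    data.frame(from = "a", to = "b", weight = 1))), NA)
})

test_that("unreachable pairs are Inf and excluded from D sums", {
  g <- weighted_graph(data.frame(from = c("a", "x"), to = c("b", "y"),
                                 weight = 1), nodes = c("a", "b", "x", "y"))
  sp <- all_pairs_dijkstra(g)
  expect_true(is.infinite(sp["a", "x"]))
  dt <- d_score(sp, "a")
  # from b: core {a} at 1; noncore reachable set empty -> undefined
  expect_false(dt$defined[dt$gene == "b"])
})

test_that("D-scores match the hand-computed path and star examples", {
  path <- weighted_graph(data.frame(from = c("A", "B"), to = c("B", "C"),
                                    weight = 1))
  dt <- d_score(all_pairs_dijkstra(path), "A")
  expect_equal(dt$d_score[dt$gene == "B"], 0, tolerance = 1e-12)
  expect_equal(dt$d_score[dt$gene == "C"], -2 / 3, tolerance = 1e-12)
  star <- weighted_graph(data.frame(from = "C0", to = c("L1", "L2", "L3"),
                                    weight = 1))
  ds <- d_score(all_pairs_dijkstra(star), "C0")
  leaf <- ds[ds$gene == "L1", ]
  expect_equal(leaf$mean_sp_core, 1)
  expect_equal(leaf$mean_sp_noncore, 2)
  expect_equal(leaf$mean_sp_all, 5 / 3, tolerance = 1e-12)
  expect_equal(leaf$d_score, 0.6, tolerance = 1e-12)
  expect_error(d_score(all_pairs_dijkstra(star), character(0)), "empty")
  expect_error(d_score(all_pairs_dijkstra(star), star$nodes), "proper subset")
})

test_that("D is scale invariant and obeys the sign law", {
  for (seed in 1:25) {
    g <- random_graph(sample(6:12, 1), 0.5, weighted = TRUE, seed = seed)
    g <- giant_component(g)
    if (length(g$nodes) < 4) next
    core <- g$nodes[1:2]
    sp <- all_pairs_dijkstra(g)
    dt <- d_score(sp, core)
    # multiply all edge lengths by c > 0: D unchanged
    g2 <- g; g2$edges$weight <- g2$edges$weight * 7.3
    dt2 <- d_score(all_pairs_dijkstra(g2), core)
    expect_equal(dt2$d_score, dt$d_score, tolerance = 1e-10)
    # sign law: D > 0 iff mean SP to core < mean SP to noncore
    ok <- dt$defined
    expect_equal(dt$d_score[ok] > 0,
                 dt$mean_sp_core[ok] < dt$mean_sp_noncore[ok])
  }
})

test_that("positive-D subnetwork keeps the core and its neighborhood", {
  star <- weighted_graph(data.frame(from = "C0", to = c("L1", "L2", "L3"),
                                    weight = 1))
  dt <- d_score(all_pairs_dijkstra(star), "C0")
  sub <- core_subnetwork(star, dt)
  expect_setequal(sub$graph$nodes, star$nodes)       # all leaves have D > 0
  expect_equal(length(sub$core_nodes) + length(sub$neighbor_nodes),
               length(sub$graph$nodes))
  # all-noncore-negative case collapses to the core
  path <- weighted_graph(data.frame(from = c("A", "B", "C"),
                                    to = c("B", "C", "D"), weight = 1))
  dtp <- d_score(all_pairs_dijkstra(path), c("A", "B"))
  neg <- dtp[!dtp$is_core & dtp$defined & dtp$d_score <= 0, "gene"]
  if (length(neg) == 2) {
    expect_warning(subp <- core_subnetwork(path, dtp), "positive")
    expect_setequal(subp$graph$nodes, c("A", "B"))
  }
})

test_that("module genes around the core score higher than background", {
  for (seed in 1:3) {
    # 1000 genes at 5% DE gives 25 up-regulated genes, so the 12-gene core
    # module sits inside the DEG set and appears in the co-expression graph
    cfg <- simulation_config(n_genes = 1000, core_module_size = 12,
                             seed = seed)
    sim <- simulate_counts(cfg)
    em <- filter_low_expression(sim$matrix)
    adj <- combat_adjust(log_normalize(em, size_factors(em, by_batch = TRUE)))
    degs <- filter_degs(dge_table(moderated_t(adj)))
    gc <- giant_component(
      suppressWarnings(correlation_network(adj, c(degs$up, degs$down))))
    module <- intersect(sim$truth$core_genes, gc$nodes)
    seed_core <- module[seq_len(length(module) %/% 2)]
    rest <- setdiff(module, seed_core)
    bg <- setdiff(gc$nodes, module)
    if (length(rest) < 3 || length(bg) < 3) next
    lg <- edge_lengths(tom(gc), "one_minus_sim")
    dt <- d_score(all_pairs_dijkstra(induced_subgraph(lg, gc$nodes)),
                  seed_core)
    expect_gt(median(dt$d_score[dt$gene %in% rest], na.rm = TRUE),
              median(dt$d_score[dt$gene %in% bg], na.rm = TRUE))
  }
})
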