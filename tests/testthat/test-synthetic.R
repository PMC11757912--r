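test_that("config invariants are enforced", {
  expect_error(simulation_config(de_fraction = 1.2), "de_fraction")
  expect_error(simulation_config(n_genes = 100, de_fraction = 0.001),
               "de_fraction")
  expect_error(simulation_config(core_module_size = 1), "core_module_size")
  expect_error(simulation_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(simulation_config(libsize_range = c(2, 1)), "libsize_range")
})

test_that("same seed gives bit-identical counts and graphs", {
  cfg <- simulation_config(n_genes = 300, seed = 7, core_module_size = 10)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_graph(cfg)$graph, simulate_graph(cfg)$graph)
})

test_that("null configuration has no condition-dependent means", {
  cfg <- simulation_config(n_genes = 1000, de_fraction = 0,
                           batch_shift_sd = 0, batch_scale_sd = 0,
                           core_module_size = 10, seed = 3)
  sim <- simulate_counts(cfg)
  expect_length(sim$truth$de_genes, 0)
  grp <- sim$truth$condition[colnames(sim$matrix$values)]
  lfc <- log2(rowMeans(sim$matrix$values[, grp == "tumor"]) + 1) -
    log2(rowMeans(sim$matrix$values[, grp == "normal"]) + 1)
  expect_lt(abs(mean(lfc)), 0.05)
})

test_that("planted effect size is recovered from raw group means", {
  # oracle: log2 ratio of raw count group means, computed straight from the
  # sampled matrix, should sit near the planted effect
  cfg <- simulation_config(n_genes = 2000, n_tumor = 20, n_normal = 20,
                           de_fraction = 0.05, log2fc_effect = 2, seed = 42)
  sim <- simulate_counts(cfg)
  grp <- sim$truth$condition[colnames(sim$matrix$values)]
  up <- names(sim$truth$de_genes)[sim$truth$de_genes > 0]
  lfc <- log2(rowMeans(sim$matrix$values[up, grp == "tumor"])) -
    log2(rowMeans(sim$matrix$values[up, grp == "normal"]))
  expect_lt(abs(mean(lfc) - 2), 0.3)
})

test_that("core-module genes are more correlated than background", {
  for (seed in 1:3) {
    cfg <- simulation_config(n_genes = 500, core_module_size = 15,
                             seed = seed)
    sim <- simulate_counts(cfg)
    logc <- log2(sim$matrix$values + 1)
    core <- sim$truth$core_genes
    bg <- setdiff(sample(rownames(logc), 60), core)
    rc <- abs(stats::cor(t(logc[core, ])))
    rb <- abs(stats::cor(t(logc[bg, ])))
    expect_gt(mean(rc[upper.tri(rc)]), mean(rb[upper.tri(rb)]))
  }
})

test_that("graph models honour their construction guarantees", {
  cfg <- simulation_config(n_hubs = 2, n_nonhubs = 6, seed = 9)
  gs <- simulate_graph(cfg)
  sp <- all_pairs_dijkstra(weighted_graph(
    data.frame(from = gs$graph$edges$from, to = gs$graph$edges$to,
               weight = 1), nodes = gs$graph$nodes))
  for (nh in gs$truth$planted_nonhubs) {
    expect_lte(min(sp[nh, gs$truth$planted_hubs]), 2)
  }
  deg <- graph_degree(gs$graph)
  expect_true(all(deg[gs$truth$planted_nonhubs] <= 3))

  # complete graph at p = 1
  er <- simulate_graph(simulation_config(graph_model = "erdos_renyi",
                                         graph_nodes = 5, er_p = 1, seed = 1))
  expect_equal(nrow(er$graph$edges), choose(5, 2))

  # handshake identity for preferential attachment
  ba <- simulate_graph(simulation_config(graph_model = "barabasi_albert",
                                         graph_nodes = 100, ba_m = 2,
                                         seed = 4))
  expect_equal(sum(graph_degree(ba$graph)), 2 * nrow(ba$graph$edges))

  cfgbad <- simulation_config(seed = 1)
  cfgbad$graph_model <- "small_world"
  expect_error(simulate_graph(cfgbad))
})

test_that("fixtures round-trip and match the ground truth", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_genes = 400, core_module_size = 10, seed = 21)
  fx <- write_fixtures(cfg, dir)
  em <- read_expression(fx$counts, fx$samples)
  sim <- simulate_counts(cfg)
  expect_equal(em$values, sim$matrix$values)
  expect_equal(em$sample_meta, sim$matrix$sample_meta)

  edges <- read_tsv(fx$edges)
  expect_true(all(c("protein1", "protein2", "combined_score") %in%
                    names(edges)))
  expect_false(any(duplicated(
    paste(pmin(edges$protein1, edges$protein2),
          pmax(edges$protein1, edges$protein2)))))

  truth <- jsonlite::read_json(fx$ground_truth, simplifyVector = TRUE)
  expect_setequal(truth$core_genes, sim$truth$core_genes)
  expect_setequal(readLines(fx$core_genes), sim$truth$core_genes)
})

test_that("null simulations keep downstream BH discoveries rare", {
  # type-I control of the whole simulate -> normalize -> test -> BH chain
  flagged <- vapply(1:20, function(seed) {
    cfg <- simulation_config(n_genes = 400, n_tumor = 8, n_normal = 8,
                             de_fraction = 0, batch_shift_sd = 0,
                             batch_scale_sd = 0, core_module_size = 2,
                             core_loading = 0, seed = seed)
    sim <- simulate_counts(cfg)
    logn <- log_normalize(sim$matrix)
    tt <- dge_table(moderated_t(logn))
    mean(tt$p_adj < 0.05)
  }, numeric(1))
  expect_lte(mean(flagged), 0.07)
})
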