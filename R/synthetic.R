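# Synthetic-data generator: negative-binomial counts for a two-condition,
# multi-batch design with planted differentially expressed genes, a planted
# co-expressed core module (one shared latent factor), an anti-correlated
# "focal" gene, and interaction graphs with known hubs and nonhubs.  Every
# downstream stage of the pipeline is testable against this ground truth.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a mid-sized two-batch case/control study: 2000 genes,
#' 20 tumor + 20 normal samples, 5% DE genes at a planted effect of
#' |log2FC| = 2, NB dispersion 0.1, batch location shifts of sd 1 on the
#' log2 scale with mild scale effects, library sizes between 0.5x and 2x,
#' and a 30-gene co-expressed core module.
#'
#' @param n_genes,n_tumor,n_normal positive integers.
#' @param n_batches number of batches (>= 1); samples are assigned round-robin
#'   within each condition so no batch is confounded with condition.
#' @param de_fraction fraction of genes with a planted condition effect, in
#'   \[0, 1).
#' @param log2fc_effect absolute planted log2 fold change (> 0).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + mu^2 * dispersion).
#' @param batch_shift_sd sd of the additive per-gene-per-batch shift on the
#'   log2 scale.
#' @param batch_scale_sd sd (log scale) of the multiplicative
#'   per-gene-per-batch factor applied to biological noise.
#' @param libsize_range length-2 positive range of library-size factors.
#' @param core_module_size number of genes sharing the core latent factor
#'   (>= 2).
#' @param core_loading loading of core genes on the latent factor (log2 units
#'   per factor sd).
#' @param bio_noise_sd sd of per-gene-per-sample biological noise on the log2
#'   scale (before NB sampling).
#' @param graph_model `"planted_hub"`, `"erdos_renyi"` or `"barabasi_albert"`.
#' @param graph_nodes node count for the `erdos_renyi`/`barabasi_albert`
#'   models.
#' @param er_p edge probability for `erdos_renyi`.
#' @param ba_m edges added per node for `barabasi_albert`.
#' @param n_hubs,n_nonhubs,leaves_per_hub planted-hub model sizes.
#' @param seed integer seed; identical configurations give bit-identical
#'   output.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000, n_tumor = 20, n_normal = 20,
                              n_batches = 2, de_fraction = 0.05,
                              log2fc_effect = 2, nb_dispersion = 0.1,
                              batch_shift_sd = 1, batch_scale_sd = 0.2,
                              libsize_range = c(0.5, 2),
                              core_module_size = 30, core_loading = 0.8,
                              bio_noise_sd = 0.3,
                              graph_model = c("planted_hub", "erdos_renyi",
                                              "barabasi_albert"),
                              graph_nodes = 60, er_p = 0.1, ba_m = 2,
                              n_hubs = 3, n_nonhubs = 8, leaves_per_hub = 15,
                              seed = 1) {
  graph_model <- match.arg(graph_model)
  cfg <- list(n_genes = as.integer(n_genes), n_tumor = as.integer(n_tumor),
              n_normal = as.integer(n_normal), n_batches = as.integer(n_batches),
              de_fraction = de_fraction, log2fc_effect = log2fc_effect,
              nb_dispersion = nb_dispersion, batch_shift_sd = batch_shift_sd,
              batch_scale_sd = batch_scale_sd, libsize_range = libsize_range,
              core_module_size = as.integer(core_module_size),
              core_loading = core_loading, bio_noise_sd = bio_noise_sd,
              graph_model = graph_model, graph_nodes = as.integer(graph_nodes),
              er_p = er_p, ba_m = as.integer(ba_m), n_hubs = as.integer(n_hubs),
              n_nonhubs = as.integer(n_nonhubs),
              leaves_per_hub = as.integer(leaves_per_hub),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_genes < 1 || cfg$n_tumor < 1 || cfg$n_normal < 1)
    stopf("n_genes, n_tumor and n_normal must be positive")
  if (cfg$n_batches < 1) stopf("n_batches must be >= 1")
  if (cfg$de_fraction < 0 || cfg$de_fraction >= 1)
    stopf("de_fraction must lie in [0, 1)")
  if (cfg$de_fraction > 0 && cfg$de_fraction * cfg$n_genes < 1)
    stopf("de_fraction * n_genes must be >= 1 when de_fraction > 0")
  if (cfg$log2fc_effect <= 0) stopf("log2fc_effect must be > 0")
  if (cfg$nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  if (cfg$batch_shift_sd < 0 || cfg$batch_scale_sd < 0)
    stopf("batch effect sds must be >= 0")
  if (length(cfg$libsize_range) != 2 || any(cfg$libsize_range <= 0) ||
      cfg$libsize_range[1] > cfg$libsize_range[2])
    stopf("libsize_range must be an increasing pair of positive reals")
  if (cfg$core_module_size < 2 || cfg$core_module_size > cfg$n_genes)
    stopf("core_module_size must lie in [2, n_genes]")
  invisible(cfg)
}

gene_ids <- function(n) sprintf("G%06d", seq_len(n))
sample_ids <- function(n) sprintf("S%03d", seq_len(n))

#' Simulate a two-condition multi-batch count matrix with known ground truth
#'
#' Counts are negative-binomial with per-gene log2 baseline means drawn from
#' U(3, 9).  Planted DE genes shift the tumor mean by +/- `log2fc_effect`
#' (half up, half down).  Batch effects are a per-gene-per-batch additive
#' shift on the log2 mean plus a lognormal factor scaling the biological
#' noise, matching the location/scale model the adjustment stage estimates.
#' Core-module genes (chosen among up-regulated DE genes when possible) share
#' one latent factor; one additional DE-down "focal" gene loads negatively on
#' that factor, emulating a gene anti-correlated with the module.
#'
#' @param config a [simulation_config()].
#' @return list with `matrix` (an [expression_matrix()], raw counts) and
#'   `truth` (list: `de_genes` named vector of true log2FC, `core_genes`,
#'   `focal_gene`, `batch_assignment`, `condition`, `lib_sizes`).
#' @export
simulate_counts <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  ng <- config$n_genes
  ns <- config$n_tumor + config$n_normal
  genes <- gene_ids(ng)
  samples <- sample_ids(ns)
  condition <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
  # round-robin batches within condition: no batch/condition confounding
  batch <- character(ns)
  batch[condition == "tumor"] <-
    sprintf("B%d", (seq_len(config$n_tumor) - 1L) %% config$n_batches + 1L)
  batch[condition == "normal"] <-
    sprintf("B%d", (seq_len(config$n_normal) - 1L) %% config$n_batches + 1L)

  base <- stats::runif(ng, 3, 9)

  n_de <- if (config$de_fraction > 0) round(config$de_fraction * ng) else 0L
  de_idx <- if (n_de > 0) sort(sample.int(ng, n_de)) else integer()
  de_sign <- rep(c(1, -1), length.out = n_de)   # half up, half down
  true_fc <- stats::setNames(de_sign * config$log2fc_effect, genes[de_idx])

  up_idx <- de_idx[de_sign > 0]
  core_pool <- if (length(up_idx) >= config$core_module_size) up_idx else
    seq_len(ng)
  core_idx <- sort(sample(core_pool, config$core_module_size))
  down_idx <- de_idx[de_sign < 0]
  focal_pool <- setdiff(if (length(down_idx)) down_idx else seq_len(ng),
                        core_idx)
  focal_idx <- if (length(focal_pool)) focal_pool[[1L]] else NA_integer_

  loading <- numeric(ng)
  loading[core_idx] <- config$core_loading
  if (!is.na(focal_idx)) loading[focal_idx] <- -config$core_loading

  batches <- sort(unique(batch))
  gamma <- matrix(stats::rnorm(ng * length(batches), 0, config$batch_shift_sd),
                  ng, length(batches), dimnames = list(genes, batches))
  delta <- matrix(exp(stats::rnorm(ng * length(batches), 0,
                                   config$batch_scale_sd)),
                  ng, length(batches), dimnames = list(genes, batches))

  factor_s <- stats::rnorm(ns)
  lib <- stats::runif(ns, config$libsize_range[1], config$libsize_range[2])
  eps <- matrix(stats::rnorm(ng * ns, 0, config$bio_noise_sd), ng, ns)

  bi <- match(batch, batches)
  log2mu <- matrix(base, ng, ns)
  is_tumor <- condition == "tumor"
  if (n_de > 0)
    log2mu[de_idx, is_tumor] <- log2mu[de_idx, is_tumor] +
      de_sign * config$log2fc_effect
  log2mu <- log2mu + gamma[, bi, drop = FALSE] +
    outer(loading, factor_s) + delta[, bi, drop = FALSE] * eps

  mu <- sweep(2^log2mu, 2, lib, `*`)
  counts <- matrix(stats::rnbinom(ng * ns, mu = mu,
                                  size = 1 / config$nb_dispersion),
                   ng, ns, dimnames = list(genes, samples))

  meta <- data.frame(sample = samples, condition = condition, batch = batch,
                     stringsAsFactors = FALSE)
  truth <- list(de_genes = true_fc,
                core_genes = genes[core_idx],
                focal_gene = if (is.na(focal_idx)) NULL else genes[focal_idx],
                batch_assignment = stats::setNames(batch, samples),
                condition = stats::setNames(condition, samples),
                lib_sizes = stats::setNames(lib, samples))
  list(matrix = expression_matrix(counts, meta, scale = "raw_counts"),
       truth = truth)
}

#' Simulate an interaction graph with known topology
#'
#' Three models: `planted_hub` builds hubs (a hub clique, each hub with its
#' own leaves) plus designated low-degree nonhubs attached to a hub directly
#' or at distance two, so hub/nonhub classification has ground truth;
#' `erdos_renyi` is G(n, p); `barabasi_albert` is preferential attachment
#' with `ba_m` edges per new node.  Edge weights (interaction confidence on
#' the 0-1 scale) are drawn from U(0.4, 1).
#'
#' @param config a [simulation_config()].
#' @param node_ids optional character vector of node ids to use (in order);
#'   defaults to `"N001"`, `"N002"`, ...
#' @return list with `graph` (a [weighted_graph()]) and `truth` (list:
#'   `planted_hubs`, `planted_nonhubs`).
#' @export
simulate_graph <- function(config, node_ids = NULL) {
  validate_simulation_config(config)
  model <- config$graph_model
  if (!model %in% c("planted_hub", "erdos_renyi", "barabasi_albert"))
    stopf("unknown graph model: %s", model)
  set.seed(config$seed)
  if (model == "planted_hub") {
    n_need <- config$n_hubs * (1L + config$leaves_per_hub) + config$n_nonhubs
  } else n_need <- config$graph_nodes
  ids <- if (is.null(node_ids)) sprintf("N%03d", seq_len(n_need)) else {
    if (length(node_ids) < n_need)
      stopf("need %d node ids, got %d", n_need, length(node_ids))
    as.character(node_ids[seq_len(n_need)])
  }

  if (model == "planted_hub") {
    hubs <- ids[seq_len(config$n_hubs)]
    leaf_ids <- ids[config$n_hubs + seq_len(config$n_hubs * config$leaves_per_hub)]
    leaves <- split(leaf_ids, rep(seq_len(config$n_hubs),
                                  each = config$leaves_per_hub))
    nonhubs <- ids[n_need - config$n_nonhubs + seq_len(config$n_nonhubs)]
    ef <- character(); et <- character()
    if (config$n_hubs > 1) {
      hp <- utils::combn(hubs, 2)
      ef <- c(ef, hp[1, ]); et <- c(et, hp[2, ])
    }
    for (h in seq_len(config$n_hubs)) {
      ef <- c(ef, rep(hubs[h], config$leaves_per_hub))
      et <- c(et, leaves[[h]])
    }
    for (i in seq_along(nonhubs)) {
      h <- (i - 1L) %% config$n_hubs + 1L
      if (i %% 2L == 1L) {              # direct neighbor of a hub
        ef <- c(ef, hubs[h]); et <- c(et, nonhubs[i])
      } else {                          # distance two via a hub leaf
        ef <- c(ef, leaves[[h]][(i %/% 2L - 1L) %% config$leaves_per_hub + 1L])
        et <- c(et, nonhubs[i])
      }
    }
    truth <- list(planted_hubs = hubs, planted_nonhubs = nonhubs)
  } else if (model == "erdos_renyi") {
    n <- config$graph_nodes
    if (n < 2) stopf("erdos_renyi needs graph_nodes >= 2")
    pairs <- utils::combn(seq_len(n), 2)
    keep <- stats::runif(ncol(pairs)) < config$er_p
    ef <- ids[pairs[1, keep]]; et <- ids[pairs[2, keep]]
    truth <- list(planted_hubs = character(), planted_nonhubs = character())
  } else {                              # barabasi_albert
    n <- config$graph_nodes; m <- config$ba_m
    if (m < 1 || n <= m) stopf("barabasi_albert needs 1 <= ba_m < graph_nodes")
    ef <- integer(); et <- integer()
    repeated <- seq_len(m)              # degree-proportional sampling pool
    for (v in (m + 1L):n) {
      pool <- unique(repeated)
      targets <- if (length(pool) <= m) pool else {
        tab <- table(repeated)
        sample(as.integer(names(tab)), m, prob = as.numeric(tab))
      }
      ef <- c(ef, rep(v, length(targets))); et <- c(et, targets)
      repeated <- c(repeated, targets, rep(v, length(targets)))
    }
    ef <- ids[ef]; et <- ids[et]
    truth <- list(planted_hubs = character(), planted_nonhubs = character())
  }
  w <- stats::runif(length(ef), 0.4, 1)
  g <- weighted_graph(data.frame(from = ef, to = et, weight = w,
                                 stringsAsFactors = FALSE),
                      nodes = ids)
  list(graph = g, truth = truth)
}

#' Write a complete fixture set to a directory
#'
#' Emits the counts TSV, sample sheet TSV, a STRING-dialect interaction TSV
#' (whose nodes are the planted DE genes, so the interaction stage connects
#' to the expression stages), the core-gene list, a ground-truth JSON, and a
#' ready-to-run pipeline config JSON.
#'
#' @param config a [simulation_config()].
#' @param dir writable output directory (created if missing).
#' @return invisibly, a named list of file paths plus the ground truth.
#' @export
write_fixtures <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_counts(config)
  # graph nodes drawn from the planted DE genes (padded with other genes if
  # the DE set is too small) so PPIN ids resolve in the expression matrix
  all_genes <- rownames(sim$matrix$values)
  pool <- unique(c(sim$truth$core_genes, names(sim$truth$de_genes),
                   sim$truth$focal_gene, all_genes))
  gsim <- simulate_graph(config, node_ids = pool)

  paths <- list(counts = file.path(dir, "counts.tsv"),
                samples = file.path(dir, "samples.tsv"),
                edges = file.path(dir, "string_edges.tsv"),
                core_genes = file.path(dir, "core_genes.txt"),
                ground_truth = file.path(dir, "ground_truth.json"),
                config = file.path(dir, "config.json"))
  write_expression(sim$matrix, paths$counts, paths$samples)
  write_string_edges(gsim$graph, paths$edges)
  writeLines(sim$truth$core_genes, paths$core_genes)

  truth <- c(sim$truth[c("core_genes", "focal_gene", "batch_assignment")],
             list(de_genes = as.list(sim$truth$de_genes)),
             gsim$truth)
  jsonlite::write_json(truth, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  run_cfg <- default_run_config()
  run_cfg$counts <- paths$counts
  run_cfg$samples <- paths$samples
  run_cfg$edges <- paths$edges
  run_cfg$core_genes <- paths$core_genes
  run_cfg$focal_genes <- as.list(sim$truth$focal_gene)
  run_cfg$seed <- config$seed
  run_cfg$out_dir <- file.path(dir, "out")
  jsonlite::write_json(run_cfg, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, list(truth = truth)))
}

#' Write a graph as a STRING-dialect edge TSV
#'
#' Columns: `protein1`, `protein2`, the five evidence channels
#' (`neighborhood`, `coexpression`, `experimental`, `database`,
#' `textmining`), and `combined_score` on the 0-1000 scale (edge weight x
#' 1000, rounded).
#'
#' @param graph a [weighted_graph()] with weights in \[0, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_string_edges <- function(graph, path) {
  sc <- as.integer(round(graph$edges$weight * 1000))
  df <- data.frame(protein1 = graph$edges$from, protein2 = graph$edges$to,
                   neighborhood = 0L, coexpression = as.integer(round(sc / 2)),
                   experimental = sc, database = 0L, textmining = 0L,
                   combined_score = sc, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
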