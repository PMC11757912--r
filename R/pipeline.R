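# End-to-end orchestration: preprocess -> dge -> wgcn -> coreprox -> ppin ->
# association, with a JSON run config, per-stage TSV outputs, a run
# manifest, and a command-line entry point with one subcommand per stage.

#' Default pipeline configuration
#'
#' @return named list of every pipeline parameter with its default.
#' @export
default_run_config <- function() {
  list(counts = NULL, samples = NULL, edges = NULL, core_genes = NULL,
       focal_genes = list(),
       min_count = 10, min_fraction = 0.25, skip_combat = FALSE,
       alpha = 0.05, fc_min = 1,
       r_min = 0.7, beta = 1,
       length_mode = "one_minus_sim", top_k_core = 10,
       min_combined_score = 400,
       k_hub = 13, bc_hub = 63.94, k_nonhub = 3, bc_nonhub = 9,
       seed = 1, out_dir = "netprox_out")
}

#' Validate a pipeline configuration
#'
#' Collects every violation rather than stopping at the first.
#'
#' @param x path to a JSON config file, or a config list.
#' @return the completed config list (class `run_config`) when valid;
#'   otherwise a character vector of violations with class
#'   `config_violations`.
#' @export
validate_config <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stopf("config file not found: %s", x)
    x <- jsonlite::read_json(x, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_run_config(), as.list(x))
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(!is.null(cfg$counts), "missing required field: counts")
  chk(!is.null(cfg$samples), "missing required field: samples")
  for (f in c("counts", "samples", "edges", "core_genes")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      errs <- c(errs, sprintf("%s path does not exist: %s", f, cfg[[f]]))
  }
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "alpha outside (0,1)")
  chk(is.numeric(cfg$fc_min) && cfg$fc_min >= 0, "fc_min must be >= 0")
  chk(is.numeric(cfg$r_min) && cfg$r_min > 0 && cfg$r_min < 1,
      "r_min outside (0,1)")
  chk(is.numeric(cfg$beta) && cfg$beta >= 1, "beta must be >= 1")
  chk(cfg$length_mode %in% c("one_minus_sim", "reciprocal"),
      "length_mode must be one_minus_sim or reciprocal")
  chk(is.numeric(cfg$min_combined_score) && cfg$min_combined_score >= 0 &&
        cfg$min_combined_score <= 1000,
      "min_combined_score outside [0,1000]")
  chk(is.numeric(cfg$min_count) && cfg$min_count >= 0,
      "min_count must be >= 0")
  chk(is.numeric(cfg$min_fraction) && cfg$min_fraction >= 0 &&
        cfg$min_fraction <= 1, "min_fraction outside [0,1]")
  chk(is.numeric(cfg$top_k_core) && cfg$top_k_core >= 1,
      "top_k_core must be >= 1")
  chk(is.numeric(cfg$seed), "seed must be numeric")
  if (length(errs)) return(structure(errs, class = "config_violations"))
  structure(cfg, class = "run_config")
}

#' Run the full pipeline
#'
#' Stages: preprocess (filter, per-batch size factors, log-normalize,
#' batch-adjust), dge (moderated t + BH + FC filter), wgcn (correlation
#' network on the DEGs, giant component, node weights, TOM), coreprox
#' (edge lengths, all-pairs Dijkstra, D-scores, positive-D subnetwork),
#' ppin (STRING edges, node stats, metrics, classification, clustering;
#' skipped when no edge file is configured), association (pairwise Pearson
#' among hub/nonhub/focal genes).  Every stage writes its table under
#' `out_dir`; a JSON manifest records parameters and per-stage counts.
#' Rerunning with the same config reproduces identical outputs.
#'
#' @param config a validated config (list or `run_config`), or a path to a
#'   JSON config file.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  if (inherits(cfg, "config_violations"))
    stopf("invalid configuration:\n- %s", paste(cfg, collapse = "\n- "))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)), file = log_path, append = TRUE)
  }
  set.seed(cfg$seed)
  manifest <- list(package = "netprox",
                   version = as.character(utils::packageVersion("netprox")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   parameters = unclass(cfg), stages = list())
  stop_after <- cfg$stop_after %||% "association"
  stopped <- FALSE
  stage <- function(name, fun) {
    if (stopped) return(invisible())
    logf("stage %s: start", name)
    res <- tryCatch(fun(), error = function(e) {
      logf("stage %s: FAILED: %s", name, conditionMessage(e))
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      writeLines(name, file.path(cfg$out_dir, "FAILED"))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    logf("stage %s: done", name)
    if (identical(name, stop_after)) stopped <<- TRUE
    res
  }

  # -- preprocess ----------------------------------------------------------
  env <- new.env()
  stage("preprocess", function() {
    em <- read_expression(cfg$counts, cfg$samples)
    em <- filter_low_expression(em, cfg$min_count, cfg$min_fraction)
    sf <- size_factors(em, by_batch = length(unique(batch_of(em))) > 1)
    logn <- log_normalize(em, sf)
    adj <- if (isTRUE(cfg$skip_combat) ||
               length(unique(batch_of(em))) == 1) {
      suppressWarnings(
        expression_matrix(logn$values, logn$sample_meta,
                          scale = "batch_adjusted"))
    } else combat_adjust(logn)
    write_expression(adj, file.path(cfg$out_dir, "expression_adjusted.tsv"),
                     file.path(cfg$out_dir, "samples.tsv"))
    env$adj <- adj
    manifest$stages$preprocess <<- list(
      status = "ok", genes_kept = nrow(adj$values),
      samples = ncol(adj$values),
      batches = length(unique(batch_of(adj))))
  })

  # -- dge -----------------------------------------------------------------
  stage("dge", function() {
    tt <- dge_table(moderated_t(env$adj), cfg$alpha, cfg$fc_min)
    write_tsv(tt, file.path(cfg$out_dir, "dge.tsv"))
    env$dge <- tt
    env$degs <- filter_degs(tt, cfg$alpha, cfg$fc_min)
    manifest$stages$dge <<- list(
      status = "ok", n_tested = nrow(tt),
      n_significant = sum(tt$p_adj < cfg$alpha),
      n_up = length(env$degs$up), n_down = length(env$degs$down))
  })

  # -- wgcn ----------------------------------------------------------------
  stage("wgcn", function() {
    deg_ids <- c(env$degs$up, env$degs$down)
    if (length(deg_ids) < 2) {  # fall back to the most significant genes
      deg_ids <- env$dge$gene[order(env$dge$p_value)][
        seq_len(min(50, nrow(env$dge)))]
    }
    g <- suppressWarnings(
      correlation_network(env$adj, deg_ids, cfg$r_min, cfg$beta))
    gc <- giant_component(g)
    nw <- node_weights_from_edges(gc)
    tm <- tom(gc)
    write_tsv(gc$edges, file.path(cfg$out_dir, "wgcn_edges.tsv"))
    write_tsv(data.frame(gene = names(nw), node_weight = unname(nw)),
              file.path(cfg$out_dir, "wgcn_node_weights.tsv"))
    write_tsv(data.frame(gene = rownames(tm), tm, check.names = FALSE),
              file.path(cfg$out_dir, "wgcn_tom.tsv"))
    env$wgcn <- gc; env$tom <- tm
    manifest$stages$wgcn <<- list(
      status = "ok", n_candidate_genes = length(deg_ids),
      n_nodes_network = n_nodes(g), n_nodes_giant = n_nodes(gc),
      n_edges_giant = n_edges(gc))
  })

  # -- coreprox ------------------------------------------------------------
  stage("coreprox", function() {
    core <- if (!is.null(cfg$core_genes)) {
      readLines(cfg$core_genes)
    } else {                             # fallback: top-k DEGs by |log2FC|
      ord <- order(-abs(env$dge$log2fc))
      env$dge$gene[ord][seq_len(min(cfg$top_k_core, nrow(env$dge)))]
    }
    core <- intersect(core, env$wgcn$nodes)
    if (length(core) == 0 || length(core) >= n_nodes(env$wgcn))
      stopf("core set empty or spans the whole giant component")
    lg <- edge_lengths(env$tom, mode = cfg$length_mode)
    lg <- induced_subgraph(lg, env$wgcn$nodes)
    sp <- all_pairs_dijkstra(lg)
    dt <- d_score(sp, core)
    sub <- core_subnetwork(env$wgcn, dt)
    write_tsv(dt, file.path(cfg$out_dir, "d_scores.tsv"))
    write_tsv(sub$graph$edges, file.path(cfg$out_dir, "core_subnetwork.tsv"))
    env$dscores <- dt
    manifest$stages$coreprox <<- list(
      status = "ok", n_core = length(sub$core_nodes),
      n_neighbors = length(sub$neighbor_nodes),
      n_subnetwork = n_nodes(sub$graph))
  })

  # -- ppin ----------------------------------------------------------------
  stage("ppin", function() {
    if (is.null(cfg$edges)) {
      env$labels <- NULL
      manifest$stages$ppin <<- list(status = "skipped",
                                    reason = "no edge file configured")
      return(invisible())
    }
    g <- read_string_edges(cfg$edges, cfg$min_combined_score)
    st <- node_stats(g)
    st <- classify_nodes(st, g, cfg$k_hub, cfg$bc_hub, cfg$k_nonhub,
                         cfg$bc_nonhub)
    met <- network_metrics(g)
    cl <- greedy_modularity_clusters(g)
    write_tsv(st, file.path(cfg$out_dir, "ppin_node_stats.tsv"))
    write_tsv(data.frame(gene = names(cl$membership),
                         cluster = unname(cl$membership)),
              file.path(cfg$out_dir, "ppin_clusters.tsv"))
    jsonlite::write_json(c(met, list(modularity_q = cl$modularity_q,
                                     n_clusters = length(unique(cl$membership)))),
                         file.path(cfg$out_dir, "ppin_metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    env$labels <- stats::setNames(st$label, st$gene)
    manifest$stages$ppin <<- list(
      status = "ok", n_nodes = n_nodes(g), n_edges = n_edges(g),
      n_hubs = sum(st$label == "hub"), n_nonhubs = sum(st$label == "nonhub"),
      n_clusters = length(unique(cl$membership)))
  })

  # -- association ---------------------------------------------------------
  stage("association", function() {
    groups <- character(0)
    if (!is.null(env$labels)) {
      sel <- env$labels[env$labels %in% c("hub", "nonhub")]
      groups <- stats::setNames(unname(sel), names(sel))
    }
    for (fg in unlist(cfg$focal_genes)) groups[fg] <- "focal"
    groups <- groups[names(groups) %in% rownames(env$adj$values)]
    if (length(groups) < 2) {
      manifest$stages$association <<- list(status = "skipped",
                                           reason = "fewer than 2 grouped genes")
      return(invisible())
    }
    rep <- pairwise_pearson(env$adj, groups)
    summ <- sign_summary(rep, cfg$alpha)
    write_tsv(rep, file.path(cfg$out_dir, "correlations.tsv"))
    jsonlite::write_json(summ, file.path(cfg$out_dir, "correlation_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$stages$association <<- list(
      status = "ok", n_pairs = nrow(rep),
      n_groups = length(unique(groups)))
  })

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# minimal --flag value parser shared by the CLI subcommands
parse_cli_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stopf("unexpected argument: %s", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      val <- args[[i + 1L]]
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (!is.na(num)) num else val
      i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a fixture set), `run-all` (full
#' pipeline), and the per-stage commands `preprocess`, `dge`, `wgcn`,
#' `coreprox`, `ppin`, `associate`, each of which runs the pipeline up to
#' and including that stage.  Flags mirror the config fields
#' (`--counts`, `--samples`, `--edges`, `--core-genes`, `--alpha`,
#' `--fc-min`, `--r-min`, `--beta`, `--length-mode`, `--min-combined-score`,
#' `--k-hub`, `--bc-hub`, `--k-nonhub`, `--bc-nonhub`, `--min-count`,
#' `--min-fraction`, `--skip-combat`, `--top-k-core`, `--seed`,
#' `--out-dir`); `--config FILE` loads a JSON config first and explicit
#' flags override it.
#'
#' @param args character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status 0 invisibly; stops on error.
#' @export
netprox_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stopf(paste("usage: netprox <simulate|run-all|preprocess|dge|wgcn|",
                "coreprox|ppin|associate> [--flags]", sep = ""))
  cmd <- args[[1L]]
  flags <- parse_cli_flags(args[-1L])
  if (cmd == "simulate") {
    dir <- flags$out_dir %||% "netprox_fixtures"
    seed <- as.integer(flags$seed %||% 1)
    cfg <- simulation_config(seed = seed)
    write_fixtures(cfg, dir)
    message(sprintf("fixtures written to %s", dir))
    return(invisible(0L))
  }
  stages <- c("preprocess", "dge", "wgcn", "coreprox", "ppin", "associate",
              "run-all")
  if (!cmd %in% stages) stopf("unknown subcommand: %s", cmd)
  base <- if (!is.null(flags$config)) {
    v <- validate_config(flags$config)
    if (inherits(v, "config_violations"))
      stopf("invalid config:\n- %s", paste(v, collapse = "\n- "))
    unclass(v)
  } else default_run_config()
  flags$config <- NULL
  cfg <- utils::modifyList(base, flags)
  # per-stage commands run the pipeline prefix ending at that stage
  if (cmd != "run-all")
    cfg$stop_after <- if (cmd == "associate") "association" else cmd
  run_pipeline(cfg)
  invisible(0L)
}
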