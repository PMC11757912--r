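# Expression-correlation validation: pairwise Pearson correlation among the
# hub, nonhub and focal gene groups, with two-sided t-based p-values and
# optional BH adjustment across the report, then a per-group-pair summary of
# positive-significant / negative-significant / non-significant counts.

#' Pairwise Pearson correlations between grouped genes
#'
#' All unordered pairs among the grouped genes (within- and cross-group) are
#' reported.  Two-sided p-values use t = r sqrt((n-2)/(1-r^2)) with n-2
#' degrees of freedom; |r| = 1 gives p = 0.  Pairs involving a zero-variance
#' gene are flagged undefined.
#'
#' @param em an [expression_matrix()] (log scale recommended).
#' @param groups named character vector, gene id -> group label (e.g.
#'   `"hub"`, `"nonhub"`, `"focal"`).
#' @param adjust `"BH"` (default) adds BH-adjusted p-values across all
#'   defined pairs; `"none"` copies the raw p-values.
#' @return data frame: `gene_a`, `gene_b`, `group_a`, `group_b`, `r`,
#'   `p_value`, `p_adj`, `n`, `defined`.
#' @export
pairwise_pearson <- function(em, groups, adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  genes <- names(groups)
  if (is.null(genes) || length(genes) < 2)
    stopf("groups must be a named vector with >= 2 genes")
  missing <- setdiff(genes, rownames(em$values))
  if (length(missing)) stopf("grouped genes absent from matrix: %s",
                             paste(utils::head(missing, 5), collapse = ", "))
  n <- ncol(em$values)
  if (n < 3) stopf("need >= 3 samples for correlation tests")
  vals <- em$values[genes, , drop = FALSE]
  sds <- apply(vals, 1, stats::sd)
  r_mat <- suppressWarnings(stats::cor(t(vals)))
  pr <- utils::combn(seq_along(genes), 2)
  ia <- pr[1, ]; ib <- pr[2, ]
  r <- r_mat[cbind(ia, ib)]
  defined <- sds[ia] > 0 & sds[ib] > 0 & is.finite(r)
  r[!defined] <- NA_real_
  p <- rep(NA_real_, length(r))
  ok <- defined & abs(r) < 1
  p[ok] <- 2 * stats::pt(-abs(r[ok] * sqrt((n - 2) / (1 - r[ok]^2))),
                         df = n - 2)
  p[defined & abs(r) >= 1] <- 0
  out <- data.frame(gene_a = genes[ia], gene_b = genes[ib],
                    group_a = unname(groups[ia]), group_b = unname(groups[ib]),
                    r = r, p_value = p, p_adj = NA_real_, n = n,
                    defined = defined, stringsAsFactors = FALSE)
  if (adjust == "BH") {
    out$p_adj[out$defined] <- bh_adjust(out$p_value[out$defined])
  } else {
    out$p_adj <- out$p_value
  }
  out
}

#' Sign/significance summary per group pair
#'
#' Counts, for every unordered pair of group labels, how many gene pairs are
#' positive-significant, negative-significant, or not significant at
#' `alpha` (on the adjusted p-values by default).  Undefined pairs count as
#' not significant.
#'
#' @param report output of [pairwise_pearson()].
#' @param alpha significance level.
#' @param use_adjusted use `p_adj` (default) rather than `p_value`.
#' @return data frame: `group_a`, `group_b`, `positive_significant`,
#'   `negative_significant`, `not_significant`, `total`.
#' @export
sign_summary <- function(report, alpha = 0.05, use_adjusted = TRUE) {
  p <- if (use_adjusted) report$p_adj else report$p_value
  sig <- report$defined & !is.na(p) & p < alpha
  ga <- pmin(report$group_a, report$group_b)
  gb <- pmax(report$group_a, report$group_b)
  key <- paste(ga, gb, sep = "\r")
  ks <- sort(unique(key))
  out <- data.frame(group_a = sub("\r.*", "", ks),
                    group_b = sub(".*\r", "", ks),
                    positive_significant = NA_integer_,
                    negative_significant = NA_integer_,
                    not_significant = NA_integer_,
                    total = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(ks)) {
    idx <- key == ks[i]
    out$positive_significant[i] <- sum(idx & sig & report$r > 0)
    out$negative_significant[i] <- sum(idx & sig & report$r < 0)
    out$total[i] <- sum(idx)
    out$not_significant[i] <- out$total[i] - out$positive_significant[i] -
      out$negative_significant[i]
  }
  out
}
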