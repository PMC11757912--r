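# Differential expression: per-gene two-group comparison on the log2 scale
# with empirical-Bayes variance moderation (the pooled per-gene variance is
# shrunk toward a common prior estimated by method of moments on the
# log-variances), Benjamini-Hochberg step-up adjustment, and the standard
# padj < alpha, |log2FC| >= fc_min significance filter.

trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  repeat {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (-dif / x < 1e-8) return(x)
  }
}

#' Moderated two-group t statistics
#'
#' For each gene the tumor-minus-normal difference of means on the log2
#' scale is tested with a pooled-variance t statistic whose variance is
#' shrunk: s2_tilde = (d0 * s0^2 + d * s2) / (d0 + d), with the prior
#' degrees of freedom d0 and prior variance s0^2 estimated by method of
#' moments on log s2 (matching the scaled-F distribution of sample
#' variances).  Two-sided p-values use d0 + d degrees of freedom.
#'
#' @param em an [expression_matrix()] on the `log_normalized` or
#'   `batch_adjusted` scale, with >= 2 samples in each condition.
#' @param prior_df override for d0: `NULL` (estimate), `0` (ordinary
#'   pooled-variance t-test), or any non-negative value.
#' @return data frame: `gene`, `log2fc`, `t_stat`, `p_value`, plus the
#'   moderation parameters as attributes `d0` and `s02`.
#' @export
moderated_t <- function(em, prior_df = NULL) {
  if (!em$scale %in% c("log_normalized", "batch_adjusted"))
    stopf("moderated_t expects log-scale expression values")
  grp <- condition_of(em)
  n1 <- sum(grp == "tumor"); n0 <- sum(grp == "normal")
  if (n1 < 2 || n0 < 2) stopf("both conditions need >= 2 samples")
  d <- n1 + n0 - 2
  if (d <= 0) stopf("zero residual degrees of freedom")

  x1 <- em$values[, grp == "tumor", drop = FALSE]
  x0 <- em$values[, grp == "normal", drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  ss <- rowSums((x1 - m1)^2) + rowSums((x0 - m0)^2)
  s2 <- ss / d
  fc <- m1 - m0

  if (is.null(prior_df)) {
    z <- log(s2[s2 > 0 & is.finite(s2)])
    if (length(z) < 2) {
      d0 <- 0; s02 <- mean(s2)
    } else {
      e <- z - digamma(d / 2) + log(d / 2)
      excess <- stats::var(e) - trigamma(d / 2)
      if (is.finite(excess) && excess > 0) {
        d0 <- 2 * trigamma_inverse(excess)
        s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
      } else {                          # no excess spread: fully shrunk
        d0 <- Inf
        s02 <- exp(mean(e))
      }
    }
  } else {
    if (prior_df < 0) stopf("prior_df must be >= 0")
    d0 <- prior_df
    s02 <- if (d0 > 0) mean(s2) else 0
  }

  s2_tilde <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n0))
  t_stat <- ifelse(se > 0, fc / se, 0)
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)

  out <- data.frame(gene = rownames(em$values), log2fc = fc, t_stat = t_stat,
                    p_value = p, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' padj_(i) = min over k >= i of m * p_(k) / k, capped at 1, returned in the
#' original order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  padj <- numeric(m)
  padj[o] <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  padj
}

#' Full differential-expression table
#'
#' Adds BH-adjusted p-values and the up/down/ns direction label to the
#' output of [moderated_t()].
#'
#' @param tt data frame from [moderated_t()].
#' @param alpha adjusted-p threshold (strict: padj < alpha).
#' @param fc_min absolute log2FC threshold (inclusive: |log2fc| >= fc_min).
#' @return data frame with columns `gene`, `log2fc`, `t_stat`, `p_value`,
#'   `p_adj`, `direction`.
#' @export
dge_table <- function(tt, alpha = 0.05, fc_min = 1) {
  tt$p_adj <- bh_adjust(tt$p_value)
  tt$direction <- ifelse(tt$p_adj < alpha & tt$log2fc >= fc_min, "up",
                  ifelse(tt$p_adj < alpha & tt$log2fc <= -fc_min, "down",
                         "ns"))
  tt
}

#' Significant up- and down-regulated gene lists
#'
#' @param results a [dge_table()] (or [moderated_t()] output, in which case
#'   `p_adj` is computed here).
#' @param alpha,fc_min thresholds, as in [dge_table()].
#' @return list with character vectors `up` and `down` (disjoint).
#' @export
filter_degs <- function(results, alpha = 0.05, fc_min = 1) {
  if (is.null(results$p_adj)) results <- dge_table(results, alpha, fc_min)
  up <- results$gene[results$p_adj < alpha & results$log2fc >= fc_min]
  down <- results$gene[results$p_adj < alpha & results$log2fc <= -fc_min]
  list(up = up, down = down)
}
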