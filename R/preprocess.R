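# Normalization and batch adjustment: median-of-ratios size factors,
# log2(count/factor + 1) transform, and a parametric empirical-Bayes
# location/scale batch adjustment fitted on the log-normalized matrix with
# the tumor/normal condition protected as a covariate.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes of
#' count / geometric mean of that gene across samples, restricted to genes
#' whose geometric mean is positive (i.e. no zero count in any sample).
#'
#' @param em an [expression_matrix()] on the raw-count scale, or a count
#'   matrix.
#' @param by_batch if `TRUE`, factors are computed independently within each
#'   batch (the protocol used by the pipeline: normalize per batch, then
#'   batch-adjust).
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(em, by_batch = FALSE) {
  counts <- if (inherits(em, "expression_matrix")) em$values else em
  if (by_batch) {
    if (!inherits(em, "expression_matrix"))
      stopf("by_batch = TRUE needs an expression_matrix with sample metadata")
    out <- stats::setNames(rep(NA_real_, ncol(counts)), colnames(counts))
    for (b in unique(batch_of(em))) {
      idx <- batch_of(em) == b
      out[idx] <- size_factors(counts[, idx, drop = FALSE])
    }
    return(out)
  }
  if (any(counts < 0)) stopf("size_factors requires raw counts")
  if (all(counts == 0)) stopf("all-zero count matrix")
  if (ncol(counts) == 1)
    return(stats::setNames(1, colnames(counts)))
  loggm <- rowMeans(log(counts))            # -Inf whenever any count is 0
  use <- is.finite(loggm)
  if (!any(use))
    stopf("no gene has a positive geometric mean; cannot normalize")
  f <- apply(counts[use, , drop = FALSE], 2,
             function(cnt) stats::median(exp(log(cnt) - loggm[use])))
  if (any(!is.finite(f)) || any(f <= 0))
    stopf("degenerate size factor; is some sample all-zero on the used genes?")
  f
}

#' Log-normalize counts
#'
#' entry = log2(count / factor + 1).
#'
#' @param em an [expression_matrix()] on the raw-count scale.
#' @param factors per-sample positive size factors (default: [size_factors()]).
#' @return an [expression_matrix()] on the `log_normalized` scale.
#' @export
log_normalize <- function(em, factors = size_factors(em)) {
  if (em$scale != "raw_counts") stopf("log_normalize expects raw counts")
  if (any(factors <= 0) || any(!is.finite(factors)))
    stopf("size factors must be positive and finite")
  vals <- log2(sweep(em$values, 2, factors, `/`) + 1)
  expression_matrix(vals, em$sample_meta, scale = "log_normalized")
}

#' Filter low-expression genes
#'
#' Keeps genes with raw count >= `min_count` in at least `min_fraction` of
#' samples.
#'
#' @param em an [expression_matrix()] on the raw-count scale.
#' @param min_count,min_fraction filter thresholds.
#' @return filtered [expression_matrix()].
#' @export
filter_low_expression <- function(em, min_count = 10, min_fraction = 0.25) {
  if (em$scale != "raw_counts") stopf("filter expects raw counts")
  keep <- rowMeans(em$values >= min_count) >= min_fraction
  expression_matrix(em$values[keep, , drop = FALSE], em$sample_meta,
                    scale = "raw_counts")
}

#' Empirical-Bayes location/scale batch adjustment
#'
#' Parametric adjustment of a log-normalized matrix: fit per-gene batch and
#' condition effects by least squares, standardize residual variation,
#' estimate per-gene-per-batch location (gamma) and scale (delta^2)
#' parameters, shrink them toward batch-level hyperpriors estimated by the
#' method of moments (normal prior for gamma, inverse-gamma for delta^2),
#' then remove the shrunken batch effects and restore the condition effect
#' and overall scale.
#'
#' @param em an [expression_matrix()] on the `log_normalized` scale.
#' @param conv convergence tolerance of the EB fixed-point iteration.
#' @return an [expression_matrix()] on the `batch_adjusted` scale.
#' @export
combat_adjust <- function(em, conv = 1e-6) {
  if (!em$scale %in% c("log_normalized"))
    stopf("combat_adjust expects a log_normalized matrix")
  batch <- batch_of(em)
  batches <- unique(batch)
  nb <- length(batches)
  if (nb == 1) {
    warnf("single batch: batch adjustment is the identity")
    return(expression_matrix(em$values, em$sample_meta,
                             scale = "batch_adjusted"))
  }
  n_per <- table(batch)[batches]
  if (any(n_per < 2)) stopf("every batch needs >= 2 samples")
  for (b in batches) {
    if (length(unique(condition_of(em)[batch == b])) < 2)
      warnf("batch %s contains a single condition; effects are confounded", b)
  }

  dat <- em$values                      # genes x samples
  n <- ncol(dat)
  batch_design <- stats::model.matrix(~ 0 + factor(batch, levels = batches))
  colnames(batch_design) <- batches
  cond <- as.numeric(condition_of(em) == "tumor")
  design <- cbind(batch_design, condition = cond)

  b_hat <- t(solve(crossprod(design), crossprod(design, t(dat))))
  grand_mean <- as.numeric(b_hat[, seq_len(nb), drop = FALSE] %*%
                             (as.numeric(n_per) / n))
  var_pooled <- rowMeans((dat - b_hat %*% t(design))^2)
  var_pooled <- pmax(var_pooled, 1e-12)  # guard constant genes

  stand_mean <- matrix(grand_mean, nrow(dat), n) +
    b_hat[, nb + 1L, drop = FALSE] %*% t(cond)
  s_data <- (dat - stand_mean) / sqrt(var_pooled)

  adjusted <- s_data
  for (bi in seq_len(nb)) {
    idx <- batch == batches[bi]
    nbi <- sum(idx)
    sb <- s_data[, idx, drop = FALSE]
    gamma_hat <- rowMeans(sb)
    delta_hat <- apply(sb, 1, stats::var)
    # hyperpriors by method of moments
    gamma_bar <- mean(gamma_hat)
    t2 <- stats::var(gamma_hat)
    m <- mean(delta_hat); s2 <- stats::var(delta_hat)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    g_new <- gamma_hat; d_new <- delta_hat
    if (is.finite(t2) && t2 > 0 && is.finite(s2) && s2 > 0) {
      change <- 1
      while (change > conv) {
        g_old <- g_new; d_old <- d_new
        g_new <- (t2 * nbi * gamma_hat + d_old * gamma_bar) /
          (t2 * nbi + d_old)
        sum2 <- rowSums((sb - g_new)^2)
        d_new <- (0.5 * sum2 + b_prior) / (nbi / 2 + a_prior - 1)
        change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                      abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      }
    }
    adjusted[, idx] <- (sb - g_new) / sqrt(pmax(d_new, 1e-12))
  }
  out <- adjusted * sqrt(var_pooled) + stand_mean
  expression_matrix(out, em$sample_meta, scale = "batch_adjusted")
}

#' Fractions of variance explained by principal components
#'
#' Samples are observations, genes variables; components with numerically
#' zero variance are dropped, so a constant matrix yields an empty vector.
#'
#' @param em an [expression_matrix()] or a genes x samples matrix.
#' @return non-increasing numeric vector of variance fractions summing to 1
#'   (empty for a constant matrix).
#' @export
pca_variance <- function(em) {
  vals <- if (inherits(em, "expression_matrix")) em$values else em
  if (ncol(vals) < 2) stopf("pca_variance needs >= 2 samples")
  pc <- stats::prcomp(t(vals), center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  v <- v[v > max(v) * 1e-10]
  if (length(v) == 0 || max(v) == 0) return(numeric(0))
  v / sum(v)
}

#' Sample scores on the first principal component
#'
#' Diagnostic used to quantify batch separation before/after adjustment.
#'
#' @param em an [expression_matrix()] or a genes x samples matrix.
#' @return named numeric vector of PC1 scores per sample.
#' @export
pc1_scores <- function(em) {
  vals <- if (inherits(em, "expression_matrix")) em$values else em
  pc <- stats::prcomp(t(vals), center = TRUE, scale. = FALSE)
  stats::setNames(pc$x[, 1], colnames(vals))
}

#' R-squared of batch labels against PC1 scores
#'
#' @param em an [expression_matrix()].
#' @return fraction of PC1 variance explained by batch (one-way ANOVA R^2).
#' @export
batch_r2 <- function(em) {
  sc <- pc1_scores(em)
  b <- factor(batch_of(em))
  fit <- stats::lm(sc ~ b)
  summary(fit)$r.squared
}
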