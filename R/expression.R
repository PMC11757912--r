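# Expression-matrix container: genes x samples values plus a sample sheet
# (condition, batch) and a scale tag that records where in the pipeline the
# matrix sits (raw counts -> log-normalized -> batch-adjusted).

#' Construct an expression matrix with sample metadata
#'
#' @param values numeric matrix, genes in rows, samples in columns; dimnames
#'   give gene and sample ids.
#' @param sample_meta data frame with columns `sample`, `condition`
#'   (`"tumor"`/`"normal"`), `batch`; must cover every column of `values`.
#' @param scale one of `"raw_counts"`, `"log_normalized"`, `"batch_adjusted"`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_meta,
                              scale = c("raw_counts", "log_normalized",
                                        "batch_adjusted")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("values must have gene and sample dimnames")
  if (anyDuplicated(rownames(values))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stopf("duplicate sample ids")
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "batch")
  if (!all(need %in% names(sample_meta)))
    stopf("sample_meta needs columns: %s", paste(need, collapse = ", "))
  if (!all(colnames(values) %in% sample_meta$sample))
    stopf("sample_meta does not cover every sample")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  if (!all(sample_meta$condition %in% c("tumor", "normal")))
    stopf("condition must be 'tumor' or 'normal'")
  if (scale == "raw_counts") {
    if (any(values < 0) || any(values != round(values)))
      stopf("raw_counts scale requires non-negative integer entries")
  }
  structure(list(values = values, sample_meta = sample_meta, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix [%s]: %d genes x %d samples, %d batch(es)>\n",
              x$scale, nrow(x$values), ncol(x$values),
              length(unique(x$sample_meta$batch))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Write counts and sample sheet as TSV
#'
#' Counts: genes as rows, first column `gene`, remaining columns one per
#' sample.  Sample sheet: columns `sample`, `condition`, `batch`.
#'
#' @param em an [expression_matrix()].
#' @param counts_path,samples_path output paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(em, counts_path, samples_path) {
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(em$sample_meta, samples_path)
  invisible(c(counts_path, samples_path))
}

#' Read counts and sample sheet TSVs into an expression matrix
#'
#' @param counts_path TSV with first column `gene`, then one column per sample.
#' @param samples_path TSV with columns `sample`, `condition`, `batch`.
#' @param scale scale tag of the stored values (default raw counts).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(counts_path, samples_path, scale = "raw_counts") {
  df <- read_tsv(counts_path)
  if (names(df)[1] != "gene") stopf("counts TSV must start with a 'gene' column")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene
  meta <- read_tsv(samples_path)
  meta$batch <- as.character(meta$batch)
  expression_matrix(values, meta, scale = scale)
}

condition_of <- function(em) em$sample_meta$condition
batch_of <- function(em) as.character(em$sample_meta$batch)
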