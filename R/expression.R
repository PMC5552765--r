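# TVI x gene-expression correlation screen with BH FDR control.

#' Construct / validate an expression matrix
#'
#' Genes x samples matrix of normalized (log-scale) expression values with
#' unique gene and sample identifiers. Genes with zero variance across
#' samples are dropped (their ranks are undefined for a correlation screen);
#' the number dropped is reported via a message.
#'
#' @param values numeric matrix, genes in rows, samples in columns;
#'   rownames = gene ids, colnames = sample ids.
#' @param drop_zero_variance drop constant genes (default `TRUE`).
#' @return numeric matrix of class `expression_matrix`.
#' @export
expression_matrix <- function(values, drop_zero_variance = TRUE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (anyNA(values)) stop("missing expression values not supported")
  if (drop_zero_variance && ncol(values) >= 2L) {
    v <- apply(values, 1L, stats::var)
    if (any(v == 0)) {
      message(sum(v == 0), " zero-variance gene(s) dropped")
      values <- values[v > 0, , drop = FALSE]
    }
  }
  if (nrow(values) == 0L) stop("no genes left in expression matrix")
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Read a genes x samples expression matrix
#'
#' Tab-delimited text: first column gene id, header row = sample ids.
#'
#' @param path input file path.
#' @param ... passed to [expression_matrix()].
#' @return an `expression_matrix`.
#' @export
read_expression_matrix <- function(path, ...) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, fileEncoding = "UTF-8")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  storage.mode(m) <- "double"
  expression_matrix(m, ...)
}

#' Write a genes x samples expression matrix
#' @param expr an `expression_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  out <- data.frame(gene = rownames(expr), as.data.frame(unclass(expr)),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Screen genes for correlation with the TVI
#'
#' For every gene, the Spearman rank correlation between its expression
#' across lesion samples and the per-sample TVI, with a two-sided p-value
#' from the t approximation (df = n - 2) and Benjamini-Hochberg adjusted
#' q-values. A gene is called `positive`/`negative` when q < `fdr_threshold`
#' and `null` otherwise.
#'
#' @param expr an [expression_matrix()]; columns must match `names(tvi)`
#'   exactly (order may differ).
#' @param tvi named numeric vector of per-sample TVI values (>= 5 samples).
#' @param fdr_threshold FDR cutoff for direction calls (default 0.05).
#' @return data.frame with columns `gene_id`, `rho`, `p_value`, `q_value`,
#'   `direction`, in the gene order of `expr`.
#' @export
correlate_with_tvi <- function(expr, tvi, fdr_threshold = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(names(tvi))) stop("tvi must be a named per-sample vector")
  if (anyNA(tvi)) stop("missing TVI values not allowed")
  extra <- setdiff(colnames(expr), names(tvi))
  missing_s <- setdiff(names(tvi), colnames(expr))
  if (length(extra) || length(missing_s))
    stop("sample mismatch between expression matrix and TVI values; ",
         "expression-only: [", paste(extra, collapse = ", "),
         "], tvi-only: [", paste(missing_s, collapse = ", "), "]")
  if (length(tvi) < 5L) stop("need at least 5 samples for the screen")
  if (stats::sd(tvi) == 0) stop("degenerate TVI vector: all values equal")
  m <- unclass(expr)[, names(tvi), drop = FALSE]
  n <- length(tvi)
  res <- t(apply(m, 1L, function(g) {
    st <- spearman_correlation(g, tvi, p_value = TRUE)
    c(st$rho, st$p_value)
  }))
  q <- benjamini_hochberg(res[, 2L])
  direction <- ifelse(q < fdr_threshold,
                      ifelse(res[, 1L] > 0, "positive", "negative"),
                      "null")
  data.frame(gene_id = rownames(m), rho = res[, 1L], p_value = res[, 2L],
             q_value = q, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment: for sorted p-values
#' p_(i), q_(i) = min over j >= i of p_(j) * m / j, capped at 1; results are
#' returned in the input order. Rejecting all genes with q < alpha controls
#' the FDR at alpha.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values, same order as input.
#' @export
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("all p-values must lie in (0, 1]")
  m <- length(p)
  ord <- order(p, decreasing = TRUE)  # largest first for running minimum
  ranked <- p[ord] * m / seq(m, 1L)
  q <- pmin(cummin(ranked), 1)
  q[order(ord)]
}

#' Split screen results into positive / negative gene sets
#'
#' @param results output of [correlate_with_tvi()].
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return list with character vectors `positive` and `negative` (disjoint;
#'   union = all genes with q below the threshold).
#' @export
partition_gene_sets <- function(results, fdr_threshold = 0.05) {
  sig <- results$q_value < fdr_threshold
  list(positive = results$gene_id[sig & results$rho > 0],
       negative = results$gene_id[sig & results$rho < 0])
}
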