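# Survival stratification of a gene-module signature: unsupervised
# two-group clustering, Kaplan-Meier estimation, and the log-rank test.
# The product-limit estimator and the log-rank statistic are implemented
# here from first principles; the `survival` package is used only as an
# independent oracle in the test suite.

#' Validate a survival table
#'
#' @param table data.frame with columns `sample_id`, `time` (non-negative
#'   follow-up, consistent units), `event` (1 = death observed,
#'   0 = censored) and optionally `group` (binary labels).
#' @return the validated data.frame (class `survival_table`).
#' @export
survival_table <- function(table) {
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(table)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  if (anyNA(table$time) || any(table$time < 0))
    stop("follow-up times must be non-negative")
  if (!all(table$event %in% c(0, 1)))
    stop("event indicator must be 0 (censored) or 1 (death)")
  if (anyDuplicated(table$sample_id)) stop("duplicate sample ids")
  structure(as.data.frame(table),
            class = c("survival_table", "data.frame"))
}

#' Two-group stratification by unsupervised hierarchical clustering
#'
#' Samples are clustered on their signature-gene expression profiles:
#' genes are z-scored (per gene across samples), samples are compared by the
#' chosen distance on these standardized profiles, the agglomerative tree is
#' cut into exactly two groups, and group 0 is the one with the lower mean
#' signature expression (on the original scale), so labels are reproducible.
#'
#' @param expr_subset an [expression_matrix()] restricted to the signature
#'   genes (genes x samples, >= 2 samples).
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson correlation between sample profiles).
#' @param linkage agglomeration method for [stats::hclust()]: `"average"`
#'   (default), `"ward.D2"`, `"complete"`, ...
#' @return named integer vector of 0/1 labels, one per sample.
#' @export
two_group_clustering <- function(expr_subset,
                                 distance = c("euclidean", "correlation"),
                                 linkage = "average") {
  distance <- match.arg(distance)
  stopifnot(inherits(expr_subset, "expression_matrix"))
  m <- unclass(expr_subset)
  if (ncol(m) < 2L) stop("need at least 2 samples to cluster")
  z <- t(scale(t(m)))  # z-score each gene across samples
  z[is.nan(z)] <- 0
  d <- switch(distance,
    euclidean = stats::dist(t(z), method = "euclidean"),
    correlation = stats::as.dist(1 - stats::cor(z)))
  hc <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(hc, k = 2L) - 1L
  mean_expr <- colMeans(m)
  if (mean(mean_expr[labels == 0L]) > mean(mean_expr[labels == 1L]))
    labels <- 1L - labels
  labels
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) is multiplied by (1 - d_i / n_i) at each distinct event time t_i,
#' where d_i is the number of deaths and n_i the number at risk just before
#' t_i. At tied times events precede censorings (the standard convention:
#' a subject censored at t is still at risk for a death at t).
#'
#' @param table a [survival_table()] (the `group` column, if any, is
#'   ignored; estimate per group by subsetting).
#' @return data.frame of class `km_curve` with columns `time` (distinct
#'   event times, increasing), `n_risk`, `n_events`, `survival`
#'   (non-increasing, starts below 1). An attribute `all_censored` flags
#'   tables without any event, whose curve is constant 1.
#' @export
km_estimate <- function(table) {
  table <- survival_table(table)
  all_censored <- sum(table$event) == 0
  if (all_censored) {
    warning("no events observed: survival curve constant at 1")
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_events = integer(0), survival = numeric(0))
    attr(out, "all_censored") <- TRUE
    class(out) <- c("km_curve", "data.frame")
    return(out)
  }
  etimes <- sort(unique(table$time[table$event == 1]))
  n_risk <- vapply(etimes, function(t) sum(table$time >= t), numeric(1))
  n_events <- vapply(etimes, function(t)
    sum(table$time == t & table$event == 1), numeric(1))
  surv <- cumprod(1 - n_events / n_risk)
  out <- data.frame(time = etimes, n_risk = as.integer(n_risk),
                    n_events = as.integer(n_events), survival = surv)
  attr(out, "all_censored") <- FALSE
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed number of group-1 deaths is
#' compared with its hypergeometric expectation given the risk sets; the
#' statistic (O - E)^2 / V is chi-squared with 1 degree of freedom under the
#' null hypothesis of equal hazards.
#'
#' @param table a [survival_table()] with a binary `group` column.
#' @return list of class `logrank_result`: `chi_square`, `p_value`,
#'   `observed`, `expected` (group-1 totals), `group_sizes`.
#' @export
logrank_test <- function(table) {
  table <- survival_table(table)
  if (is.null(table$group)) stop("survival table needs a 'group' column")
  groups <- sort(unique(table$group))
  if (length(groups) != 2L)
    stop("log-rank test requires exactly 2 groups, got ", length(groups))
  if (sum(table$event) == 0) stop("no events observed")
  g1 <- table$group == groups[2L]
  etimes <- sort(unique(table$time[table$event == 1]))
  O <- E <- V <- 0
  for (t in etimes) {
    at_risk <- table$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(table$time == t & table$event == 1)
    d1 <- sum(table$time == t & table$event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) (O - E)^2 / V else 0
  p <- stats::pchisq(chi, df = 1L, lower.tail = FALSE)
  structure(list(chi_square = chi, p_value = p,
                 observed = O, expected = E,
                 group_sizes = stats::setNames(
                   as.integer(table(table$group)), as.character(groups))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f (1 df), p = %.4g; groups n = %s\n",
              x$chi_square, x$p_value,
              paste(x$group_sizes, collapse = " vs ")))
  invisible(x)
}

#' Stratified survival analysis of a gene-module signature
#'
#' Convenience wrapper: cluster samples into two groups on the signature
#' genes, attach the labels to the survival table, and run Kaplan-Meier
#' estimation per group plus the log-rank test.
#'
#' @param table a [survival_table()].
#' @param expr an [expression_matrix()] whose columns cover the table's
#'   samples.
#' @param signature_genes character vector of module gene ids.
#' @param ... passed to [two_group_clustering()].
#' @return list with `groups` (named 0/1 labels), `km` (list of two
#'   `km_curve`s, names `"0"` and `"1"`), `logrank` (a `logrank_result`).
#' @export
stratify_survival <- function(table, expr, signature_genes, ...) {
  table <- survival_table(table)
  genes <- intersect(signature_genes, rownames(expr))
  if (length(genes) == 0L) stop("no signature genes found in expression matrix")
  sub <- unclass(expr)[genes, table$sample_id, drop = FALSE]
  class(sub) <- c("expression_matrix", class(sub))
  labels <- two_group_clustering(sub, ...)
  table$group <- labels[table$sample_id]
  km <- lapply(split(table, table$group), km_estimate)
  list(groups = labels, km = km, logrank = logrank_test(table))
}
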