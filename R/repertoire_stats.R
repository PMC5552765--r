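# Per-sample descriptive statistics of a clonotype repertoire.

#' Most expanded clones of a repertoire
#'
#' Returns the `min(n, richness)` most frequent clones under the
#' deterministic total order (frequency descending, clone key ascending, so
#' ties at rank `n` resolve to the lexicographically smaller key).
#' Frequencies are NOT renormalized: they remain fractions of the whole
#' sample. With the default `n = 100` this is the TOP100 subset that
#' typically covers about half of all TCRb reads in gastric tissue.
#'
#' @param rep a [repertoire()].
#' @param n number of clones to keep (default 100).
#' @return a `repertoire`-shaped data.frame subset (class preserved).
#' @export
top_clones <- function(rep, n = 100) {
  stopifnot(inherits(rep, "repertoire"), n >= 1)
  k <- min(as.integer(n), nrow(rep))
  out <- rep[seq_len(k), , drop = FALSE]  # already in total order
  attributes(out)[c("sample_id", "stage", "key_mode")] <-
    attributes(rep)[c("sample_id", "stage", "key_mode")]
  class(out) <- class(rep)
  out
}

#' Cumulative frequency curve
#'
#' For k = 1..n_max, the summed frequency of the k most expanded clones:
#' the fraction of all TCRb reads covered when only the top k clones are
#' included. A sharply rising curve indicates a repertoire dominated by a
#' small number of highly expanded clones.
#'
#' @param rep a [repertoire()].
#' @param n_max largest number of clones to include (default 100).
#' @return data.frame of class `cumulative_curve` with columns `n_clones`
#'   and `cum_freq` (non-decreasing, final value <= 1 + 1e-6).
#' @export
cumulative_frequency_curve <- function(rep, n_max = 100) {
  stopifnot(inherits(rep, "repertoire"), n_max >= 1)
  k <- min(as.integer(n_max), nrow(rep))
  cf <- cumsum(rep$freq[seq_len(k)])
  out <- data.frame(n_clones = seq_len(k), cum_freq = cf)
  class(out) <- c("cumulative_curve", "data.frame")
  out
}

#' Shannon-Wiener diversity of a repertoire
#'
#' Shannon entropy of the clone frequency distribution, H = -sum p_i ln p_i,
#' in nats (natural log; set `base` for other units). Also reports richness
#' (number of distinct clones) and the normalized index H / ln(richness)
#' (Pielou evenness), defined as 0 for a single-clone repertoire.
#'
#' @param rep a [repertoire()].
#' @param base logarithm base (default `exp(1)` for nats).
#' @return list of class `diversity_result` with elements `shannon`,
#'   `normalized_shannon`, `richness`.
#' @export
shannon_diversity <- function(rep, base = exp(1)) {
  stopifnot(inherits(rep, "repertoire"))
  p <- rep$freq
  if (any(p <= 0)) stop("all clone frequencies must be positive")
  h <- -sum(p * log(p, base = base))
  h <- max(h, 0)  # guard -0 from single-clone p = 1
  r <- nrow(rep)
  structure(list(shannon = h,
                 normalized_shannon = if (r > 1L) h / log(r, base = base) else 0,
                 richness = r),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("Shannon diversity %.4f (normalized %.4f), richness %d\n",
              x$shannon, x$normalized_shannon, x$richness))
  invisible(x)
}

#' Clone counts by frequency bin
#'
#' Assigns each clone to one half-open frequency bin delimited by strictly
#' decreasing thresholds within (0, 1]. With edges (e1 > e2 > ... > em) the
#' bins are freq >= e1, e2 <= freq < e1, ..., freq < em. Default edges
#' (1e-1, 1e-2, 1e-3, 1e-4) summarize hyper-expanded through rare clones.
#'
#' @param rep a [repertoire()].
#' @param bin_edges strictly decreasing frequency thresholds in (0, 1].
#' @return data.frame with columns `bin` (label), `n_clones`,
#'   `percent_of_clones` (sums to 100 within 1e-6).
#' @export
frequency_bin_summary <- function(rep, bin_edges = c(1e-1, 1e-2, 1e-3, 1e-4)) {
  stopifnot(inherits(rep, "repertoire"))
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 1L || any(bin_edges <= 0) || any(bin_edges > 1) ||
      any(diff(bin_edges) >= 0))
    stop("bin_edges must be strictly decreasing thresholds within (0, 1]")
  labels <- c(paste0(">=", format(bin_edges[1L])),
              if (length(bin_edges) > 1L)
                paste0("[", format(bin_edges[-1L]), ",",
                       format(bin_edges[-length(bin_edges)]), ")"),
              paste0("<", format(bin_edges[length(bin_edges)])))
  # bin index = 1 + number of edges strictly above the clone's frequency
  idx <- 1L + colSums(outer(bin_edges, rep$freq, FUN = ">"))
  counts <- tabulate(idx, nbins = length(labels))
  data.frame(bin = labels, n_clones = counts,
             percent_of_clones = 100 * counts / nrow(rep))
}
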