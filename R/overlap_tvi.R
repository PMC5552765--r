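# Paired lesion/adjacent overlap statistics and the TCR repertoire
# variation index (TVI).
#
# TVI = 2 - F * (1 + C)
#   F: cumulative frequency of lesion-TOP100 clones also present anywhere
#      in the matched adjacent repertoire, renormalized within the TOP100
#      (shared TOP100 lesion frequency / total TOP100 lesion frequency).
#   C: Spearman rank correlation of the lesion vs adjacent frequencies of
#      the "top common clones" (shared clones in the TOP100 of either
#      sample).
# With F in [0,1] and C in [-1,1], TVI ranges from 0 (identical
# repertoires) to 2 (maximal divergence).

#' Clones shared between two repertoires
#'
#' @param a,b [repertoire()] objects built under the same key mode.
#' @return character vector of shared clone keys (symmetric in a, b),
#'   sorted ascending.
#' @export
common_clones <- function(a, b) {
  stopifnot(inherits(a, "repertoire"), inherits(b, "repertoire"))
  if (attr(a, "key_mode") != attr(b, "key_mode"))
    stop("repertoires use different clone key modes")
  sort(intersect(a$key, b$key), method = "radix")
}

#' Whole-repertoire overlap between a lesion and its adjacent tissue
#'
#' The clone overlap ratio is the number of shared unique clones divided by
#' the number of unique clones in the lesion; the cumulative frequency of
#' common clones sums the lesion-side frequencies of the shared clones.
#'
#' @param lesion,adjacent [repertoire()] objects (or a
#'   [lesion_adjacent_pair()] passed as `lesion`).
#' @return list of class `overlap_result`: `n_shared`, `overlap_ratio`,
#'   `common_cum_freq`, `direction` (denominator/frequency convention used).
#' @export
overlap_ratio <- function(lesion, adjacent) {
  if (inherits(lesion, "lesion_adjacent_pair")) {
    adjacent <- lesion$adjacent; lesion <- lesion$lesion
  }
  shared <- common_clones(lesion, adjacent)
  structure(list(
    n_shared = length(shared),
    overlap_ratio = length(shared) / nrow(lesion),
    common_cum_freq = sum(lesion$freq[lesion$key %in% shared]),
    direction = "lesion_denominator_lesion_frequencies"),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap: %d shared clones, ratio %.4f, common cum. freq %.4f (%s)\n",
              x$n_shared, x$overlap_ratio, x$common_cum_freq, x$direction))
  invisible(x)
}

#' Overlap between the lesion TOP-N and the full adjacent repertoire
#'
#' Restricts the lesion to its `n` most expanded clones and asks how many of
#' them occur anywhere in the matched adjacent repertoire. The cumulative
#' frequency (the F that enters the TVI) is renormalized within the TOP-N:
#' shared TOP-N lesion frequency divided by total TOP-N lesion frequency.
#' `renormalize = FALSE` gives the whole-repertoire-denominator variant
#' (shared TOP-N frequency as a fraction of all lesion reads).
#'
#' @param lesion,adjacent [repertoire()] objects (or a
#'   [lesion_adjacent_pair()] as `lesion`).
#' @param n TOP-N size (default 100).
#' @param renormalize renormalize F within the TOP-N (default `TRUE`).
#' @return `overlap_result` as in [overlap_ratio()]; `overlap_ratio` uses
#'   denominator `min(n, lesion richness)` and `common_cum_freq` is F.
#' @export
topn_overlap <- function(lesion, adjacent, n = 100, renormalize = TRUE) {
  if (inherits(lesion, "lesion_adjacent_pair")) {
    adjacent <- lesion$adjacent; lesion <- lesion$lesion
  }
  top <- top_clones(lesion, n)
  in_adj <- top$key %in% adjacent$key
  f_top <- sum(top$freq)
  f_shared <- sum(top$freq[in_adj])
  structure(list(
    n_shared = sum(in_adj),
    overlap_ratio = sum(in_adj) / nrow(top),
    common_cum_freq = if (renormalize) f_shared / f_top else f_shared,
    direction = sprintf("lesion_top%d_%s", as.integer(n),
                        if (renormalize) "renormalized" else "whole_repertoire")),
    class = "overlap_result")
}

#' Top common clones of a matched pair
#'
#' The "top common clones": clones shared between the lesion and the
#' adjacent tissue that rank in the TOP-N of either sample. Membership is
#' defined by the TOP-N condition, so the list may hold fewer or more than
#' `n` entries.
#'
#' @param lesion,adjacent [repertoire()] objects (or a
#'   [lesion_adjacent_pair()] as `lesion`).
#' @param n TOP-N size (default 100).
#' @return data.frame with columns `key`, `lesion_freq`, `adjacent_freq`,
#'   ordered by lesion frequency descending then key ascending.
#' @export
top_common_clones <- function(lesion, adjacent, n = 100) {
  if (inherits(lesion, "lesion_adjacent_pair")) {
    adjacent <- lesion$adjacent; lesion <- lesion$lesion
  }
  shared <- common_clones(lesion, adjacent)
  in_top <- shared %in% top_clones(lesion, n)$key |
            shared %in% top_clones(adjacent, n)$key
  keys <- shared[in_top]
  lf <- lesion$freq[match(keys, lesion$key)]
  af <- adjacent$freq[match(keys, adjacent$key)]
  ord <- order(-lf, keys, method = "radix")
  data.frame(key = keys[ord], lesion_freq = lf[ord], adjacent_freq = af[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Spearman rank correlation
#'
#' Rank correlation with average (mid-) ranks on ties: Pearson correlation
#' of the rank-transformed vectors. The optional test p-value uses the
#' two-sided t approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param p_value also return the t-approximation p-value (default `FALSE`).
#' @return `rho`, or `list(rho, p_value, n)` when `p_value = TRUE`.
#' @export
spearman_correlation <- function(x, y, p_value = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("Spearman correlation requires at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: zero rank variance")
  rho <- stats::cor(rx, ry, method = "pearson")
  if (!p_value) return(rho)
  p <- if (abs(rho) >= 1) {
    .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    min(max(2 * stats::pt(-abs(tstat), df = n - 2), .Machine$double.xmin), 1)
  }
  list(rho = rho, p_value = p, n = n)
}

#' TVI value from its two ingredients
#'
#' The repertoire variation index as a pure function of the cumulative
#' common-clone frequency F and the top-common-clone Spearman correlation C:
#' `TVI = 2 - F * (1 + C)`. Over F in \[0, 1\] and C in \[-1, 1\] the index
#' spans \[0, 2\]: 0 for identical repertoires (F = 1, C = 1), 2 for fully
#' divergent ones (F = 0).
#'
#' @param F cumulative frequency of common clones, in \[0, 1\].
#' @param C Spearman correlation of top common clones, in \[-1, 1\].
#' @return numeric TVI value(s) (vectorized).
#' @export
tvi_value <- function(F, C) {
  if (any(F < 0 | F > 1)) stop("F must lie in [0, 1]")
  if (any(C < -1 | C > 1)) stop("C must lie in [-1, 1]")
  2 - F * (1 + C)
}

#' TCR repertoire variation index of a matched pair
#'
#' Computes F via [topn_overlap()] (TOP-N-renormalized cumulative frequency
#' of lesion TOP-N clones shared with the adjacent repertoire), C via
#' [spearman_correlation()] over the lesion/adjacent frequencies of the
#' [top_common_clones()], and TVI = 2 - F (1 + C).
#'
#' When fewer than 3 top common clones exist C is undefined: if F = 0 the
#' index degenerates to its upper limit TVI = 2 regardless of C; otherwise
#' the TVI is reported missing with a warning.
#'
#' @param pair a [lesion_adjacent_pair()].
#' @param n TOP-N size (default 100).
#' @return list of class `tvi_result`: `patient_id`, `stage`, `F`, `C`,
#'   `n_common_top`, `tvi`.
#' @export
compute_tvi <- function(pair, n = 100) {
  stopifnot(inherits(pair, "lesion_adjacent_pair"))
  ov <- topn_overlap(pair$lesion, pair$adjacent, n = n)
  F <- ov$common_cum_freq
  tcc <- top_common_clones(pair$lesion, pair$adjacent, n = n)
  C <- NA_real_
  if (nrow(tcc) >= 3L) {
    C <- tryCatch(spearman_correlation(tcc$lesion_freq, tcc$adjacent_freq),
                  error = function(e) NA_real_)
  }
  tvi <- if (!is.na(C)) {
    tvi_value(F, C)
  } else if (F == 0) {
    2  # F = 0 short-circuit: the index is 2 whatever C would have been
  } else {
    warning("fewer than 3 top common clones (or degenerate ranks) with F > 0; ",
            "TVI undefined for patient ", pair$patient_id)
    NA_real_
  }
  if (!is.na(tvi) && (tvi < -1e-9 || tvi > 2 + 1e-9))
    stop("TVI outside [0, 2]: ", tvi)
  structure(list(patient_id = pair$patient_id,
                 stage = attr(pair$lesion, "stage"),
                 F = F, C = C, n_common_top = nrow(tcc), tvi = tvi),
            class = "tvi_result")
}

#' @export
print.tvi_result <- function(x, ...) {
  cat(sprintf("TVI %s (%s): F=%.4f C=%s n_common_top=%d tvi=%s\n",
              x$patient_id, x$stage, x$F,
              ifelse(is.na(x$C), "NA", sprintf("%.4f", x$C)),
              x$n_common_top,
              ifelse(is.na(x$tvi), "NA", sprintf("%.4f", x$tvi))))
  invisible(x)
}

#' Per-pair overlap/TVI summary table
#'
#' Runs the whole-repertoire overlap, TOP-N overlap and TVI computation for
#' a list of matched pairs and collects one row per pair.
#'
#' @param pairs list of [lesion_adjacent_pair()] objects.
#' @param n TOP-N size (default 100).
#' @return data.frame with columns `patient_id`, `stage`, `n_shared`,
#'   `overlap_ratio`, `common_cum_freq`, `topn_ratio`, `F`, `C`,
#'   `n_common_top`, `tvi`.
#' @export
tvi_table <- function(pairs, n = 100) {
  rows <- lapply(pairs, function(p) {
    ov <- overlap_ratio(p)
    tv <- compute_tvi(p, n = n)
    topn <- topn_overlap(p, n = n)
    data.frame(patient_id = p$patient_id, stage = tv$stage,
               n_shared = ov$n_shared, overlap_ratio = ov$overlap_ratio,
               common_cum_freq = ov$common_cum_freq,
               topn_ratio = topn$overlap_ratio,
               F = tv$F, C = tv$C, n_common_top = tv$n_common_top,
               tvi = tv$tvi, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
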