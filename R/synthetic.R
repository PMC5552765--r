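# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth.
#
# Stated world. Clone abundances follow a Zipf law with exponent 1.01 over
# 20,000 clones and 200,000 sequenced reads per sample, which puts the
# TOP100 cumulative frequency at ~0.51 - inside the 46-54% band observed
# for gastric tissue. Stage presets take their shared fractions directly
# from the observed lesion/adjacent clone overlap ratios (LGIN 15.11%,
# HGIN 10.74%, EGC 9.02%) and increase the log-normal rank perturbation
# across stages (0.35 / 0.8 / 1.3), so repertoire divergence - and with it
# the mean TVI - grows monotonically from LGIN to EGC.

#' Parameters for a simulated lesion/adjacent repertoire pair
#'
#' @param n_clones_lesion,n_clones_adjacent underlying clone numbers
#'   (default 20000 each; realized richness is lower because multinomial
#'   read sampling drops unseen clones).
#' @param zipf_exponent power-law exponent of the clone-abundance law,
#'   > 1 (default 1.01, calibrated so TOP100 coverage is ~50%).
#' @param shared_fraction fraction of lesion clones copied from the
#'   adjacent repertoire (default 0.15, the LGIN-like regime).
#' @param rank_noise standard deviation of the log-normal multiplicative
#'   perturbation applied to shared clones' lesion frequencies (default
#'   0.35).
#' @param total_reads sequenced reads per sample (default 200000).
#' @param stage lesion stage label (default `"LGIN"`).
#' @return list of class `repertoire_pair_params`.
#' @export
repertoire_pair_params <- function(n_clones_lesion = 20000,
                                   n_clones_adjacent = 20000,
                                   zipf_exponent = 1.01,
                                   shared_fraction = 0.15,
                                   rank_noise = 0.35,
                                   total_reads = 200000,
                                   stage = "LGIN") {
  p <- list(n_clones_lesion = as.integer(n_clones_lesion),
            n_clones_adjacent = as.integer(n_clones_adjacent),
            zipf_exponent = zipf_exponent,
            shared_fraction = shared_fraction,
            rank_noise = rank_noise,
            total_reads = as.integer(total_reads),
            stage = match.arg(stage, c("LGIN", "HGIN", "EGC")))
  if (p$zipf_exponent <= 1) stop("zipf_exponent must exceed 1")
  if (p$shared_fraction < 0 || p$shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]")
  if (p$rank_noise < 0) stop("rank_noise must be non-negative")
  if (p$n_clones_lesion < 1L || p$n_clones_adjacent < 1L ||
      p$total_reads < 1L) stop("sizes must be positive")
  class(p) <- "repertoire_pair_params"
  p
}

#' Stage presets for the repertoire-pair generator
#'
#' Divergence knobs per carcinogenesis stage: the shared fraction equals the
#' observed stage-wise overlap ratio (15.11 / 10.74 / 9.02%), and the rank
#' noise grows across stages, so LGIN-like pairs are similar (low TVI) and
#' EGC-like pairs divergent (high TVI).
#'
#' @param stage `"LGIN"`, `"HGIN"` or `"EGC"`.
#' @param ... overrides passed to [repertoire_pair_params()].
#' @return a `repertoire_pair_params` object.
#' @export
stage_preset <- function(stage = c("LGIN", "HGIN", "EGC"), ...) {
  stage <- match.arg(stage)
  knobs <- switch(stage,
    LGIN = list(shared_fraction = 0.1511, rank_noise = 0.35),
    HGIN = list(shared_fraction = 0.1074, rank_noise = 0.80),
    EGC  = list(shared_fraction = 0.0902, rank_noise = 1.30))
  args <- utils::modifyList(c(knobs, stage = stage), list(...))
  do.call(repertoire_pair_params, args)
}

# integer index -> deterministic CDR3 nucleotide string (base-4 over ACGT),
# fixed width 15 nt so keys are unique and alphabet-valid
index_to_cdr3 <- function(idx, width = 15L) {
  alphabet <- c("A", "C", "G", "T")
  out <- matrix("A", nrow = length(idx), ncol = width)
  rem <- as.numeric(idx)
  for (pos in width:1) {
    out[, pos] <- alphabet[rem %% 4 + 1]
    rem <- rem %/% 4
  }
  do.call(paste0, asplit(out, 2L))
}

# build a repertoire data.frame from clone ids and multinomial counts
clone_pool <- function(ids) {
  data.frame(
    cdr3nt = index_to_cdr3(ids),
    cdr3aa = "",  # amino-acid sequence unused by nt_vj keying
    v = paste0("TRBV", (ids %% 30) + 1),
    d = paste0("TRBD", (ids %% 2) + 1),
    j = paste0("TRBJ", (ids %% 13) + 1),
    stringsAsFactors = FALSE)
}

#' Simulate a matched lesion/adjacent repertoire pair
#'
#' The adjacent repertoire draws clone abundances from a Zipf law. A
#' frequency-weighted subset of its clones (size `shared_fraction *
#' n_clones_lesion`) is copied into the lesion with a multiplicative
#' log-normal perturbation of sd `rank_noise`; the remaining lesion clones
#' are fresh (lesion-specific) with Zipf tail abundances under the same
#' perturbation, so strong noise lets lesion-specific clones expand into
#' the TOP100. Read counts are multinomial over `total_reads`; clones with
#' zero realized reads are dropped. Deterministic given `seed`.
#'
#' @param params a [repertoire_pair_params()] (or a stage name for
#'   [stage_preset()]).
#' @param patient_id sample/patient identifier stem.
#' @param seed integer seed.
#' @return a [lesion_adjacent_pair()].
#' @export
simulate_paired_repertoires <- function(params = repertoire_pair_params(),
                                        patient_id = "SYN1", seed = 1) {
  if (is.character(params)) params <- stage_preset(params)
  stopifnot(inherits(params, "repertoire_pair_params"))
  set.seed(as.integer(seed))
  n_adj <- params$n_clones_adjacent
  n_les <- params$n_clones_lesion
  s <- params$zipf_exponent

  w_adj <- (seq_len(n_adj))^(-s)
  p_adj <- w_adj / sum(w_adj)
  adj_ids <- seq_len(n_adj)

  n_sh <- round(params$shared_fraction * n_les)
  if (n_sh > n_adj) stop("shared_fraction infeasible: more shared clones than adjacent clones")
  shared_idx <- if (n_sh > 0)
    sample(adj_ids, n_sh, replace = FALSE, prob = p_adj) else integer(0)
  n_fresh <- n_les - n_sh
  fresh_ids <- n_adj + seq_len(n_fresh)  # disjoint id space => new clone keys

  # lesion weights: shared clones inherit perturbed adjacent abundance;
  # fresh clones take Zipf tail ranks under the same perturbation
  noise <- function(n) exp(stats::rnorm(n, 0, params$rank_noise))
  w_shared <- p_adj[shared_idx] * noise(n_sh)
  w_fresh <- ((n_sh + seq_len(n_fresh))^(-s)) * noise(n_fresh)
  w_les <- c(w_shared, w_fresh)
  p_les <- w_les / sum(w_les)
  les_ids <- c(shared_idx, fresh_ids)

  counts_adj <- as.vector(stats::rmultinom(1L, params$total_reads, p_adj))
  counts_les <- as.vector(stats::rmultinom(1L, params$total_reads, p_les))

  make_rep <- function(ids, counts, sample_id, stage) {
    keep <- counts > 0
    df <- clone_pool(ids[keep])
    df$count <- counts[keep]
    repertoire(df, sample_id = sample_id, stage = stage)
  }
  adjacent <- make_rep(adj_ids, counts_adj,
                       paste0(patient_id, "_adj"), "adjacent")
  lesion <- make_rep(les_ids, counts_les,
                     paste0(patient_id, "_", params$stage), params$stage)
  lesion_adjacent_pair(patient_id, lesion, adjacent)
}

#' Simulate a TVI-correlated expression matrix with planted truth
#'
#' Planted positive (negative) genes follow +effect (-effect) times the
#' standardized rank of the per-sample TVI plus Gaussian noise; null genes
#' are pure noise. At the defaults (effect 1, noise sd 0.5, 22 samples) a
#' planted gene's expected Spearman correlation with the TVI is ~0.9, the
#' operating point at which essentially every planted gene survives an
#' FDR < 0.05 screen.
#'
#' @param tvi_values named per-sample TVI vector (>= 5 samples, not all
#'   equal).
#' @param n_genes total genes (default 1000).
#' @param n_pos,n_neg planted positively/negatively correlated genes
#'   (defaults 50 and 50).
#' @param effect signal amplitude in sd units (default 1).
#' @param noise_sd Gaussian noise sd (default 0.5).
#' @param seed integer seed.
#' @return list with `expr` (an [expression_matrix()]) and `truth` (list
#'   with `positive_genes`, `negative_genes`, `null_genes`).
#' @export
simulate_expression <- function(tvi_values, n_genes = 1000, n_pos = 50,
                                n_neg = 50, effect = 1, noise_sd = 0.5,
                                seed = 1) {
  if (is.null(names(tvi_values))) stop("tvi_values must be named by sample")
  n <- length(tvi_values)
  if (n < 5L) stop("need at least 5 samples")
  if (stats::sd(tvi_values) == 0) stop("degenerate TVI vector: all values equal")
  if (n_pos + n_neg > n_genes) stop("n_pos + n_neg must not exceed n_genes")
  set.seed(as.integer(seed))
  signal <- as.vector(scale(rank(tvi_values, ties.method = "average")))
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  sign_vec <- c(rep(1, n_pos), rep(-1, n_neg), rep(0, n_genes - n_pos - n_neg))
  m <- matrix(stats::rnorm(n_genes * n, 0, noise_sd), n_genes, n,
              dimnames = list(genes, names(tvi_values)))
  m <- m + effect * sign_vec %o% signal + 8  # shift to a microarray-like scale
  list(expr = expression_matrix(m),
       truth = list(positive_genes = genes[sign_vec == 1],
                    negative_genes = genes[sign_vec == -1],
                    null_genes = genes[sign_vec == 0]))
}

#' Simulate a STRING-style edge table with a planted CPM module
#'
#' The planted module is wired as a chain of overlapping k-cliques
#' (consecutive cliques share k - 1 nodes) spanning `planted_module_size`
#' nodes, so it forms exactly one k-clique percolation community. Background
#' edges are Erdos-Renyi at `background_edge_prob` (excluding planted
#' pairs). Planted and background edges get scores above the STRING cutoffs
#' (text mining > 200, combined > 400); an equal number of decoy edges with
#' sub-threshold scores exercises the score filter.
#'
#' @param gene_universe character vector of gene ids (module genes are drawn
#'   from its head).
#' @param planted_module_size module size (default 11).
#' @param planted_k clique size of the chain (default 5).
#' @param background_edge_prob Erdos-Renyi background density (default
#'   0.05, calibrated to stay below the k = 5 percolation regime).
#' @param seed integer seed.
#' @return list with `edges` (data.frame geneA/geneB/textmining/combined)
#'   and `truth` (list with `planted_module`, `planted_k`).
#' @export
simulate_ppi <- function(gene_universe, planted_module_size = 11,
                         planted_k = 5, background_edge_prob = 0.05,
                         seed = 1) {
  gene_universe <- as.character(gene_universe)
  n <- length(gene_universe)
  if (planted_module_size < planted_k)
    stop("planted_module_size must be at least planted_k")
  if (n < planted_module_size) stop("gene universe smaller than module")
  if (background_edge_prob < 0 || background_edge_prob > 1)
    stop("background_edge_prob must lie in [0, 1]")
  set.seed(as.integer(seed))
  module <- gene_universe[seq_len(planted_module_size)]

  # chain of overlapping k-cliques covering the module
  pairs <- matrix(character(0), 0L, 2L)
  n_cliques <- planted_module_size - planted_k + 1L
  for (start in seq_len(n_cliques)) {
    cl <- module[start:(start + planted_k - 1L)]
    pairs <- rbind(pairs, t(utils::combn(cl, 2L)))
  }
  pair_id <- function(a, b) paste(pmin(a, b), pmax(a, b))
  planted_pairs <- unique(pair_id(pairs[, 1L], pairs[, 2L]))

  all_pairs <- t(utils::combn(gene_universe, 2L))
  ids <- pair_id(all_pairs[, 1L], all_pairs[, 2L])
  is_planted <- ids %in% planted_pairs
  # background is Erdos-Renyi OUTSIDE the module: a chance chord inside the
  # planted clique chain would raise its percolation stringency above k
  in_module <- all_pairs[, 1L] %in% module & all_pairs[, 2L] %in% module
  bg <- !is_planted & !in_module &
    stats::runif(length(ids)) < background_edge_prob
  keep <- is_planted | bg

  kept <- all_pairs[keep, , drop = FALSE]
  n_kept <- nrow(kept)
  edges <- data.frame(
    geneA = kept[, 1L], geneB = kept[, 2L],
    textmining = sample(201:1000, n_kept, replace = TRUE),
    combined = sample(401:1000, n_kept, replace = TRUE),
    stringsAsFactors = FALSE)

  # decoys: sub-threshold scores on pairs that must NOT survive the filter
  decoy_pool <- all_pairs[!keep, , drop = FALSE]
  n_decoy <- min(n_kept, nrow(decoy_pool))
  if (n_decoy > 0) {
    di <- sample(nrow(decoy_pool), n_decoy)
    low_tm <- sample(c(TRUE, FALSE), n_decoy, replace = TRUE)
    decoys <- data.frame(
      geneA = decoy_pool[di, 1L], geneB = decoy_pool[di, 2L],
      textmining = ifelse(low_tm, sample(0:200, n_decoy, replace = TRUE),
                          sample(201:1000, n_decoy, replace = TRUE)),
      combined = ifelse(low_tm, sample(401:1000, n_decoy, replace = TRUE),
                        sample(0:400, n_decoy, replace = TRUE)),
      stringsAsFactors = FALSE)
    edges <- rbind(edges, decoys)
  }
  edges <- edges[sample(nrow(edges)), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges,
       truth = list(planted_module = sort(module), planted_k = planted_k))
}

#' Simulate two-group exponential survival data
#'
#' Event times are exponential with group-0 hazard `baseline_hazard` and
#' group-1 hazard `hazard_ratio` times that; censoring times are independent
#' exponentials with rate `censoring_rate` (0 disables censoring).
#'
#' @param n_per_group subjects per group (default 50).
#' @param hazard_ratio group-1 / group-0 hazard ratio (default 3).
#' @param baseline_hazard group-0 hazard rate (default 0.1 events per time
#'   unit).
#' @param censoring_rate exponential censoring rate (default 0.02).
#' @param seed integer seed.
#' @return a [survival_table()] with the true `group` column.
#' @export
simulate_survival <- function(n_per_group = 50, hazard_ratio = 3,
                              baseline_hazard = 0.1, censoring_rate = 0.02,
                              seed = 1) {
  if (n_per_group < 2L) stop("need at least 2 subjects per group")
  if (hazard_ratio <= 0 || baseline_hazard <= 0)
    stop("hazard rates must be positive")
  if (censoring_rate < 0) stop("censoring_rate must be non-negative")
  set.seed(as.integer(seed))
  n <- 2L * n_per_group
  group <- rep(0:1, each = n_per_group)
  rate <- baseline_hazard * ifelse(group == 1L, hazard_ratio, 1)
  t_event <- stats::rexp(n, rate)
  t_cens <- if (censoring_rate > 0) stats::rexp(n, censoring_rate) else Inf
  survival_table(data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    group = group))
}

#' Simulate a two-group signature expression matrix
#'
#' Signature genes are shifted by `separation` (in sd units) in group 1
#' relative to group 0, with unit Gaussian noise: the input expected by
#' [two_group_clustering()] when validating survival stratification.
#'
#' @param groups named 0/1 vector of true sample groups.
#' @param genes character vector of signature gene ids (default 11 module
#'   genes).
#' @param separation group mean shift in sd units (default 2).
#' @param seed integer seed.
#' @return an [expression_matrix()] (genes x samples).
#' @export
simulate_signature_expression <- function(groups,
                                          genes = sprintf("MOD%02d", 1:11),
                                          separation = 2, seed = 1) {
  if (is.null(names(groups))) stop("groups must be named by sample")
  set.seed(as.integer(seed))
  m <- matrix(stats::rnorm(length(genes) * length(groups)),
              length(genes), length(groups),
              dimnames = list(genes, names(groups)))
  m <- m + separation * rep(as.numeric(groups), each = length(genes)) + 8
  expression_matrix(m)
}
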