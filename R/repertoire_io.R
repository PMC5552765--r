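# Clonotype table input/output and clone identity.

CANONICAL_COLUMNS <- c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j")
REQUIRED_COLUMNS <- c("count", "cdr3nt", "cdr3aa", "v", "d", "j")
VALID_STAGES <- c("adjacent", "LGIN", "HGIN", "EGC")
KEY_SEP <- "|"  # never occurs in IMGT gene names or nucleotide strings

#' Construct a TCR repertoire
#'
#' A repertoire holds the full clonotype list of one sample: per-clone read
#' counts, frequencies, CDR3 nucleotide and amino-acid sequences, and V/D/J
#' gene assignments. Clone frequencies must sum to 1 (tolerance `1e-6`) and
#' clone keys (see [clone_key()]) must be unique within the sample.
#'
#' @param clones data.frame with columns `count`, `freq`, `cdr3nt`, `cdr3aa`,
#'   `v`, `d`, `j`. If `freq` is absent it is computed as `count / sum(count)`.
#' @param sample_id character scalar identifying the sample.
#' @param stage one of `"adjacent"`, `"LGIN"`, `"HGIN"`, `"EGC"`.
#' @param key_mode clone identity mode passed to [clone_key()].
#' @param recompute_freq if `TRUE` (default) a `freq` column whose sum
#'   deviates from 1 by more than `1e-3` (e.g. a rounded published table) is
#'   recomputed from counts; if `FALSE` such a table is rejected.
#' @return An object of class `repertoire`: the clone data.frame (with a
#'   `key` column, sorted by frequency descending then key ascending) plus
#'   `sample_id` and `stage` attributes.
#' @export
repertoire <- function(clones, sample_id, stage,
                       key_mode = c("nt_vj", "nt_only", "aa_vj"),
                       recompute_freq = TRUE) {
  key_mode <- match.arg(key_mode)
  stopifnot(is.data.frame(clones))
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(clones))
  if (length(missing_cols))
    stop("clonotype table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.character(sample_id) || length(sample_id) != 1L)
    stop("sample_id must be a single string")
  stage <- match.arg(stage, VALID_STAGES)
  if (nrow(clones) == 0L)
    stop("repertoire must contain at least one clone")

  clones$count <- as.numeric(clones$count)
  if (anyNA(clones$count) || any(clones$count < 0))
    stop("clone counts must be non-negative numbers")
  zero <- clones$count == 0
  if (any(zero)) {
    warning(sum(zero), " zero-count row(s) rejected")
    clones <- clones[!zero, , drop = FALSE]
    if (nrow(clones) == 0L) stop("no clones left after removing zero counts")
  }
  if (any(clones$cdr3nt == "" | is.na(clones$cdr3nt)))
    stop("cdr3nt must be non-empty for every clone")
  bad_nt <- grepl("[^ACGTacgt]", clones$cdr3nt)
  if (any(bad_nt))
    stop(sum(bad_nt), " clone(s) have cdr3nt outside the {A,C,G,T} alphabet")

  if (is.null(clones$freq) || all(is.na(clones$freq))) {
    clones$freq <- clones$count / sum(clones$count)
  } else {
    clones$freq <- as.numeric(clones$freq)
    s <- sum(clones$freq)
    if (abs(s - 1) > 1e-3) {
      if (!recompute_freq)
        stop("frequency column sums to ", format(s),
             " (outside 1 +/- 1e-3) and recomputation is disabled")
      clones$freq <- clones$count / sum(clones$count)
    } else if (abs(s - 1) > 1e-6) {
      # tolerate rounded tables: renormalize quietly within the loose band
      clones$freq <- clones$freq / s
    }
  }
  if (any(clones$freq <= 0))
    stop("all clone frequencies must be positive")
  if (abs(sum(clones$freq) - 1) > 1e-6)
    stop("clone frequencies must sum to 1 (tolerance 1e-6); got ",
         format(sum(clones$freq)))

  clones$key <- clone_key(clones$cdr3nt, clones$v, clones$j, clones$cdr3aa,
                          key_mode = key_mode)
  if (anyDuplicated(clones$key))
    stop("duplicate clone keys within repertoire: ",
         paste(utils::head(clones$key[duplicated(clones$key)], 3L),
               collapse = ", "))
  # deterministic total order: frequency descending, key ascending
  ord <- order(-clones$freq, clones$key, method = "radix")
  clones <- clones[ord, c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j",
                          "key")]
  rownames(clones) <- NULL
  structure(clones, sample_id = sample_id, stage = stage,
            key_mode = key_mode,
            class = c("repertoire", "data.frame"))
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("TCR repertoire '%s' (stage %s): %d clones, top frequency %.4g\n",
              attr(x, "sample_id"), attr(x, "stage"), nrow(x), x$freq[1L]))
  print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Number of unique clones in a repertoire
#' @param rep a [repertoire()].
#' @return integer richness (count of distinct clone keys).
#' @export
richness <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  nrow(rep)
}

#' Clone identity key
#'
#' Builds the deterministic string key that identifies a clonotype. The
#' default mode `nt_vj` concatenates the CDR3 nucleotide sequence with the V
#' and J gene names: nucleotide-level identity with segment context is the
#' conservative reading of "unique TCRb reads" from aligner output that
#' distinguishes V/J. Allele suffixes (`*01` etc.) are stripped before
#' keying by default to absorb dialect drift across upstream tools.
#'
#' @param cdr3_nt,v_gene,j_gene,cdr3_aa character vectors (recycled to a
#'   common length).
#' @param key_mode `"nt_vj"` (default), `"nt_only"` or `"aa_vj"`.
#' @param strip_alleles drop a trailing `*NN` allele designator from gene
#'   names before keying (default `TRUE`).
#' @return character vector of keys.
#' @export
clone_key <- function(cdr3_nt, v_gene = "", j_gene = "", cdr3_aa = "",
                      key_mode = c("nt_vj", "nt_only", "aa_vj"),
                      strip_alleles = TRUE) {
  key_mode <- match.arg(key_mode)
  if (strip_alleles) {
    v_gene <- sub("\\*[0-9]+$", "", v_gene)
    j_gene <- sub("\\*[0-9]+$", "", j_gene)
  }
  switch(key_mode,
    nt_vj   = paste(cdr3_nt, v_gene, j_gene, sep = KEY_SEP),
    nt_only = as.character(cdr3_nt),
    aa_vj   = paste(cdr3_aa, v_gene, j_gene, sep = KEY_SEP))
}

#' Clone keys of a repertoire
#' @param rep a [repertoire()].
#' @return character vector of clone keys in the repertoire's stored order
#'   (frequency descending, key ascending).
#' @export
clone_keys <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  rep$key
}

#' Read a clonotype table
#'
#' Ingests a tab-delimited post-alignment clonotype table (the VDJtools-like
#' shape: one row per clonotype with read count, frequency, CDR3 nucleotide
#' and amino-acid sequence and V/D/J assignments) and returns a validated
#' [repertoire()].
#'
#' @param path path to a tab-delimited UTF-8 text file with a header row.
#' @param sample_id,stage sample annotations (see [repertoire()]); by
#'   default `sample_id` is the file name without extension.
#' @param dialect optional named character vector mapping canonical column
#'   names (`count`, `freq`, `cdr3nt`, `cdr3aa`, `v`, `d`, `j`) to the
#'   header names actually present, e.g.
#'   `c(count = "#count", cdr3nt = "CDR3.nucleotide.sequence")`.
#' @param key_mode,recompute_freq passed to [repertoire()].
#' @return a validated [repertoire()].
#' @export
read_clonotype_table <- function(path, sample_id = NULL, stage = "adjacent",
                                 dialect = NULL,
                                 key_mode = "nt_vj", recompute_freq = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, quote = "",
                           fileEncoding = "UTF-8")
  if (!is.null(dialect)) {
    if (is.null(names(dialect)) || !all(names(dialect) %in% CANONICAL_COLUMNS))
      stop("dialect must be a named vector keyed by canonical column names")
    for (canon in names(dialect)) {
      actual <- dialect[[canon]]
      if (!actual %in% names(tab))
        stop("dialect maps '", canon, "' to missing column '", actual, "'")
      names(tab)[names(tab) == actual] <- canon
    }
  }
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("clonotype table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$count <- as.numeric(tab$count)
  if ("freq" %in% names(tab)) tab$freq <- as.numeric(tab$freq)
  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(path))
  repertoire(tab, sample_id = sample_id, stage = stage,
             key_mode = key_mode, recompute_freq = recompute_freq)
}

#' Write a clonotype table
#'
#' Emits the canonical 7-column tab-delimited clonotype table (`count`,
#' `freq`, `cdr3nt`, `cdr3aa`, `v`, `d`, `j`), rows sorted by frequency
#' descending then clone key ascending. Round-trips through
#' [read_clonotype_table()].
#'
#' @param rep a validated [repertoire()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(rep, path) {
  stopifnot(inherits(rep, "repertoire"))
  out <- as.data.frame(rep)[, CANONICAL_COLUMNS]
  out$freq <- format(out$freq, digits = 17, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pair a lesion repertoire with its matched adjacent-mucosa repertoire
#'
#' The matched pair is the unit on which overlap statistics and the TVI are
#' computed: one gastric lesion sample (LGIN, HGIN or EGC) and the adjacent
#' mucosa from the same patient.
#'
#' @param patient_id character scalar.
#' @param lesion a [repertoire()] with stage `LGIN`, `HGIN` or `EGC`.
#' @param adjacent a [repertoire()] with stage `adjacent`.
#' @return An object of class `lesion_adjacent_pair`.
#' @export
lesion_adjacent_pair <- function(patient_id, lesion, adjacent) {
  stopifnot(inherits(lesion, "repertoire"), inherits(adjacent, "repertoire"))
  if (!attr(lesion, "stage") %in% c("LGIN", "HGIN", "EGC"))
    stop("lesion repertoire must have stage LGIN, HGIN or EGC, got ",
         attr(lesion, "stage"))
  if (attr(adjacent, "stage") != "adjacent")
    stop("adjacent repertoire must have stage 'adjacent', got ",
         attr(adjacent, "stage"))
  if (attr(lesion, "key_mode") != attr(adjacent, "key_mode"))
    stop("lesion and adjacent repertoires use different clone key modes")
  structure(list(patient_id = as.character(patient_id),
                 lesion = lesion, adjacent = adjacent),
            class = "lesion_adjacent_pair")
}

#' @export
print.lesion_adjacent_pair <- function(x, ...) {
  cat(sprintf("Lesion/adjacent pair '%s': %s lesion (%d clones) vs adjacent (%d clones)\n",
              x$patient_id, attr(x$lesion, "stage"),
              nrow(x$lesion), nrow(x$adjacent)))
  invisible(x)
}
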