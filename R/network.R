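# Protein-protein interaction network filtering, scale-free topology
# check, hub extraction and k-clique percolation community detection.
#
# Graphs are igraph objects (simple, undirected) with per-edge attributes
# `textmining`, `combined` and, after co-expression filtering,
# `coexpression_rho`. igraph supplies the graph container, connected
# components, degrees and Bron-Kerbosch maximal-clique enumeration; the
# clique-percolation community logic itself is implemented here.

# give anonymous vertices stable character names so set operations and
# lexicographic tie-breaks are well defined
ensure_named <- function(graph) {
  if (is.null(igraph::V(graph)$name))
    graph <- igraph::set_vertex_attr(graph, "name",
                                     value = as.character(seq_len(igraph::vcount(graph))))
  graph
}

#' Build an interaction graph from a STRING-style edge table
#'
#' Retains edges whose text-mining score and combined score both exceed
#' their cutoffs (strict inequalities: the defaults reproduce the
#' "text mining > 200 and combined score > 400" rule on STRING's 0-1000
#' score scale) and whose two endpoints both belong to `gene_universe`
#' (e.g. the TVI-correlated gene set). Self-loops and duplicate pairs are
#' collapsed; malformed rows are dropped with a warning naming their count.
#'
#' @param edge_table data.frame with columns `geneA`, `geneB`, `textmining`,
#'   `combined`.
#' @param textmining_min,combined_min score cutoffs (strict `>`), defaults
#'   200 and 400.
#' @param gene_universe optional character vector restricting endpoints;
#'   `NULL` keeps all genes.
#' @return an igraph graph whose vertices are the retained genes.
#' @export
filter_string_edges <- function(edge_table, textmining_min = 200,
                                combined_min = 400, gene_universe = NULL) {
  need <- c("geneA", "geneB", "textmining", "combined")
  if (!all(need %in% names(edge_table)))
    stop("edge table must have columns: ", paste(need, collapse = ", "))
  et <- edge_table[, need]
  et$textmining <- suppressWarnings(as.numeric(et$textmining))
  et$combined <- suppressWarnings(as.numeric(et$combined))
  bad <- is.na(et$textmining) | is.na(et$combined) |
    is.na(et$geneA) | is.na(et$geneB) | et$geneA == "" | et$geneB == ""
  if (any(bad)) {
    warning(sum(bad), " malformed edge row(s) dropped")
    et <- et[!bad, , drop = FALSE]
  }
  keep <- et$textmining > textmining_min & et$combined > combined_min &
    et$geneA != et$geneB
  if (!is.null(gene_universe))
    keep <- keep & et$geneA %in% gene_universe & et$geneB %in% gene_universe
  et <- et[keep, , drop = FALSE]
  # collapse duplicate unordered pairs, keeping the first occurrence
  pair <- ifelse(et$geneA < et$geneB,
                 paste(et$geneA, et$geneB), paste(et$geneB, et$geneA))
  et <- et[!duplicated(pair), , drop = FALSE]
  g <- igraph::graph_from_data_frame(et, directed = FALSE)
  g
}

#' Filter network edges by co-expression
#'
#' Keeps an edge only when the absolute Spearman correlation between its two
#' genes' expression profiles reaches `rho_min`; the signed correlation is
#' stored on the surviving edges as `coexpression_rho`.
#'
#' @param graph igraph graph with gene-id vertex names.
#' @param expr an [expression_matrix()] covering the graph's genes.
#' @param rho_min minimum absolute Spearman correlation (default 0.5).
#' @param missing_genes `"error"` (default) or `"drop"` vertices absent
#'   from the expression matrix.
#' @return the filtered igraph graph.
#' @export
filter_edges_by_coexpression <- function(graph, expr, rho_min = 0.5,
                                         missing_genes = c("error", "drop")) {
  missing_genes <- match.arg(missing_genes)
  stopifnot(inherits(expr, "expression_matrix"))
  nodes <- igraph::V(graph)$name
  absent <- setdiff(nodes, rownames(expr))
  if (length(absent)) {
    if (missing_genes == "error")
      stop("genes absent from expression matrix: ",
           paste(utils::head(absent, 5L), collapse = ", "))
    graph <- igraph::delete_vertices(graph, absent)
  }
  if (igraph::ecount(graph) == 0L) return(graph)
  ends <- igraph::as_edgelist(graph)
  ranks <- t(apply(unclass(expr), 1L, rank, ties.method = "average"))
  rho <- vapply(seq_len(nrow(ends)), function(i)
    stats::cor(ranks[ends[i, 1L], ], ranks[ends[i, 2L], ]), numeric(1))
  keep <- abs(rho) >= rho_min
  graph <- igraph::set_edge_attr(graph, "coexpression_rho", value = rho)
  igraph::subgraph_from_edges(graph, igraph::E(graph)[keep],
                              delete.vertices = FALSE)
}

#' Maximal connected subnetwork
#'
#' Induced subgraph on the largest connected component; among equally large
#' components the one with the lexicographically smallest sorted vertex-name
#' set is returned, so the choice is deterministic.
#'
#' @param graph non-empty igraph graph.
#' @return igraph subgraph.
#' @export
maximal_connected_subnetwork <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  graph <- ensure_named(graph)
  comp <- igraph::components(graph)
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    keysets <- vapply(biggest, function(ci)
      paste(sort(igraph::V(graph)$name[comp$membership == ci]),
            collapse = "\r"), character(1))
    biggest <- biggest[order(keysets)[1L]]
  }
  igraph::induced_subgraph(graph,
                           which(comp$membership == biggest[1L]))
}

#' Scale-free topology fit of the degree distribution
#'
#' Least-squares regression of log10(frequency of degree k) on log10(k) over
#' the occupied degrees (optionally over logarithmically spaced degree
#' bins). The fit's R-squared is the conventional scale-free topology index:
#' values above ~0.85 indicate power-law-like connectivity. The slope's
#' negation is reported as the estimated power-law exponent.
#'
#' @param graph igraph graph with >= 10 vertices and >= 2 distinct positive
#'   degrees.
#' @param n_bins optional number of logarithmic degree bins; `NULL`
#'   (default) regresses over raw occupied degrees.
#' @return list of class `scale_free_fit`: `r_squared`, `exponent`,
#'   `n_points`, `degenerate` (TRUE when only 2 points support the fit).
#' @export
scale_free_fit <- function(graph, n_bins = NULL) {
  if (igraph::vcount(graph) < 10L) stop("need at least 10 nodes")
  deg <- igraph::degree(graph)
  deg <- deg[deg > 0]
  if (length(unique(deg)) < 2L) stop("undefined fit: all degrees equal")
  if (is.null(n_bins)) {
    tab <- table(deg)
    k <- as.numeric(names(tab))
    freq <- as.numeric(tab) / length(deg)
  } else {
    edges <- 10^seq(log10(min(deg)), log10(max(deg)), length.out = n_bins + 1L)
    edges[length(edges)] <- edges[length(edges)] + 1e-9
    idx <- findInterval(deg, edges, rightmost.closed = TRUE)
    k <- tapply(deg, idx, mean)
    freq <- as.numeric(table(idx)) / length(deg)
  }
  fit <- stats::lm(log10(freq) ~ log10(k))
  # R^2 computed directly: summary.lm() warns on an exactly perfect fit
  y <- log10(freq)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(r_squared = r2,
                 exponent = -unname(stats::coef(fit)[2L]),
                 n_points = length(k),
                 degenerate = length(k) == 2L),
            class = "scale_free_fit")
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("Scale-free fit: R^2 = %.3f, exponent = %.2f (%d degree points%s)\n",
              x$r_squared, x$exponent, x$n_points,
              if (x$degenerate) "; degenerate 2-point fit" else ""))
  invisible(x)
}

#' Hub network
#'
#' Hub nodes are those whose degree reaches the (1 - `top_fraction`)
#' quantile of the degree distribution, ties included (so the hub count may
#' differ from `ceiling(top_fraction * n)`); the hub network is the induced
#' subgraph on the hubs together with all of their first neighbours.
#'
#' @param graph igraph graph.
#' @param top_fraction degree-quantile fraction defining hubs (default 0.05).
#' @return igraph subgraph with a logical vertex attribute `is_hub`.
#' @export
hub_network <- function(graph, top_fraction = 0.05) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  graph <- ensure_named(graph)
  deg <- igraph::degree(graph)
  cutoff <- stats::quantile(deg, probs = 1 - top_fraction, names = FALSE,
                            type = 7)
  hubs <- which(deg >= cutoff)
  nb <- unique(unlist(igraph::adjacent_vertices(graph, hubs)))
  keep <- sort(unique(c(hubs, nb)))
  sub <- igraph::induced_subgraph(graph, keep)
  igraph::set_vertex_attr(sub, "is_hub",
                          value = igraph::V(sub)$name %in%
                            igraph::V(graph)$name[hubs])
}

#' k-clique percolation communities
#'
#' Clique Percolation Method: a community is the union of all k-cliques that
#' can be reached from one another through a chain of k-cliques sharing
#' k - 1 nodes. Implemented via maximal-clique enumeration (Bron-Kerbosch):
#' maximal cliques of size >= k are adjacent when they share at least k - 1
#' nodes; each connected component of that clique graph contributes the
#' union of its cliques' nodes. This is equivalent to percolating the
#' individual k-cliques, but enumerates far fewer objects.
#'
#' @param graph igraph graph.
#' @param k clique size, >= 3; larger k means higher stringency.
#' @return list of character vectors (sorted node names), ordered by
#'   community size descending then lexicographically; communities may
#'   overlap in nodes.
#' @export
k_clique_communities <- function(graph, k) {
  k <- as.integer(k)
  if (k < 3L) stop("k must be at least 3")
  graph <- ensure_named(graph)
  cl <- igraph::max_cliques(graph, min = k)
  if (length(cl) == 0L) return(list())
  members <- lapply(cl, function(v) sort(igraph::V(graph)$name[v]))
  nc <- length(members)
  # union-find over maximal cliques; adjacency = sharing >= k-1 nodes
  parent <- seq_len(nc)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nc > 1L) {
    for (i in seq_len(nc - 1L)) for (j in seq.int(i + 1L, nc)) {
      if (length(intersect(members[[i]], members[[j]])) >= k - 1L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(nc), find, integer(1))
  comms <- lapply(split(seq_len(nc), roots), function(idx)
    sort(unique(unlist(members[idx]))))
  names(comms) <- NULL
  sizes <- lengths(comms)
  keysets <- vapply(comms, paste, character(1), collapse = "\r")
  comms[order(-sizes, keysets)]
}

#' Select the highest-stringency clique-percolation module
#'
#' Runs [k_clique_communities()] for k = `k_min` upward until no community
#' remains; the selected stringency k* is the largest k still yielding at
#' least one community, and the selected module is the largest community at
#' k* (ties broken lexicographically).
#'
#' @param graph non-empty igraph graph.
#' @param k_min smallest stringency to consider (default 3).
#' @param k_max largest k to try; defaults to the graph's maximal clique
#'   size (communities are impossible beyond it).
#' @return list of class `community_result`: `k` (selected stringency, NA if
#'   no community at any k), `communities` (all communities at k*),
#'   `selected_module` (character vector, empty if none).
#' @export
select_module <- function(graph, k_min = 3, k_max = NULL) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  if (is.null(k_max)) k_max <- max(igraph::clique_num(graph), k_min)
  best_k <- NA_integer_
  best_comms <- list()
  for (k in seq.int(k_min, k_max)) {
    comms <- k_clique_communities(graph, k)
    if (length(comms) == 0L) break
    best_k <- k
    best_comms <- comms
  }
  structure(list(k = best_k, communities = best_comms,
                 selected_module = if (length(best_comms)) best_comms[[1L]]
                                   else character(0)),
            class = "community_result")
}

#' @export
print.community_result <- function(x, ...) {
  if (is.na(x$k)) {
    cat("No k-clique community at any stringency\n")
  } else {
    cat(sprintf("CPM module at highest stringency k = %d: %d nodes (%d communit%s at this k)\n",
                x$k, length(x$selected_module), length(x$communities),
                if (length(x$communities) == 1L) "y" else "ies"))
  }
  invisible(x)
}

#' Write an edge list with attributes as TSV
#' @param graph igraph graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  names(el)[1:2] <- c("geneA", "geneB")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
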