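# Fixture builders and independent brute-force oracles shared across tests.

# deterministic nucleotide string for clone i (base-4 encoding over ACGT)
nt_seq <- function(i, width = 10L) {
  alphabet <- c("A", "C", "G", "T")
  vapply(i, function(x) {
    out <- character(width)
    for (pos in width:1) { out[pos] <- alphabet[x %% 4 + 1]; x <- x %/% 4 }
    paste(out, collapse = "")
  }, character(1))
}

# small repertoire from a count vector; clone ids pick the CDR3s
make_rep <- function(counts, ids = seq_along(counts), sample_id = "S1",
                     stage = "adjacent", v = "TRBV1", j = "TRBJ1") {
  repertoire(data.frame(count = counts, cdr3nt = nt_seq(ids), cdr3aa = "",
                        v = v, d = "TRBD1", j = j),
             sample_id = sample_id, stage = stage)
}

# random repertoire with clone ids drawn from a pool (controls sharing)
random_rep <- function(n, id_pool = 1:1000, sample_id = "S1",
                       stage = "adjacent") {
  ids <- sample(id_pool, n)
  make_rep(sample(1:100, n, replace = TRUE), ids = ids,
           sample_id = sample_id, stage = stage)
}

# ---- independent oracles ---------------------------------------------------

# Spearman rho from first principles: explicit average ranks (computed by
# sorting, not rank()) then the textbook Pearson sum formula
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force k-clique percolation: enumerate ALL k-cliques, join those
# sharing exactly k-1 nodes, take connected components (own union-find)
oracle_cpm <- function(graph, k) {
  graph <- igraph::as_undirected(graph)
  n <- igraph::vcount(graph)
  if (is.null(igraph::V(graph)$name))
    graph <- igraph::set_vertex_attr(graph, "name", value = as.character(1:n))
  nm <- igraph::V(graph)$name
  adj <- as.matrix(igraph::as_adjacency_matrix(graph)) > 0
  if (n < k) return(list())
  combs <- utils::combn(n, k)
  is_clique <- apply(combs, 2L, function(v) all(adj[v, v][upper.tri(diag(k))]))
  cl <- combs[, is_clique, drop = FALSE]
  nc <- ncol(cl)
  if (nc == 0L) return(list())
  parent <- seq_len(nc)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nc > 1L) for (i in 1:(nc - 1L)) for (j in (i + 1L):nc) {
    if (length(intersect(cl[, i], cl[, j])) == k - 1L) {
      ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(nc), find, integer(1))
  comms <- lapply(split(seq_len(nc), roots), function(idx)
    sort(nm[unique(as.vector(cl[, idx]))]))
  names(comms) <- NULL
  sizes <- lengths(comms)
  keys <- vapply(comms, paste, character(1), collapse = "\r")
  comms[order(-sizes, keys)]
}

# canonical form for comparing community lists
comm_canon <- function(comms) {
  out <- lapply(comms, sort)
  keys <- vapply(out, paste, character(1), collapse = "\r")
  unname(out[order(keys)])
}
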