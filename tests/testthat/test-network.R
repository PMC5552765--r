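edge_df <- function(a, b, tm = 500, comb = 800)
  data.frame(geneA = a, geneB = b, textmining = tm, combined = comb,
             stringsAsFactors = FALSE)

test_that("STRING edge filter applies strict cutoffs and the gene universe", {
  et <- edge_df(c("A", "A", "B", "C", "X"), c("B", "C", "C", "D", "Y"),
                tm = c(500, 200, 201, 500, 500),
                comb = c(800, 500, 401, 400, 800))
  g <- filter_string_edges(et, gene_universe = c("A", "B", "C", "D"))
  kept <- apply(igraph::as_edgelist(g), 1L, function(r)
    paste(sort(r), collapse = "-"))
  # A-C dropped (tm = 200 not > 200), C-D dropped (comb = 400 not > 400),
  # X-Y dropped (outside universe); boundary+1 kept
  expect_setequal(kept, c("A-B", "B-C"))
  # idempotence on the surviving edge table
  g2 <- filter_string_edges(igraph::as_data_frame(g) |>
                              stats::setNames(c("geneA", "geneB", "textmining",
                                                "combined")),
                            gene_universe = c("A", "B", "C", "D"))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  # malformed rows dropped with a count
  bad <- rbind(et, data.frame(geneA = "E", geneB = "F", textmining = "oops",
                              combined = 900))
  expect_warning(filter_string_edges(bad), "1 malformed")
})

test_that("co-expression filter equals per-edge recomputation", {
  set.seed(81)
  genes <- paste0("g", 1:12)
  m <- matrix(rnorm(12 * 15), 12, 15, dimnames = list(genes, paste0("s", 1:15)))
  m["g2", ] <- m["g1", ]  # identical profiles -> rho 1
  em <- expression_matrix(m)
  pairs <- t(utils::combn(genes, 2L))
  et <- edge_df(pairs[, 1L], pairs[, 2L])
  g <- filter_string_edges(et)
  gf <- filter_edges_by_coexpression(g, em, rho_min = 0.3)
  el <- igraph::as_data_frame(gf)
  # brute-force per-edge recomputation
  for (i in seq_len(nrow(pairs))) {
    rho <- stats::cor(m[pairs[i, 1L], ], m[pairs[i, 2L], ],
                      method = "spearman")
    in_graph <- any((el$from == pairs[i, 1L] & el$to == pairs[i, 2L]) |
                    (el$from == pairs[i, 2L] & el$to == pairs[i, 1L]))
    expect_equal(in_graph, abs(rho) >= 0.3)
  }
  expect_true(all(abs(el$coexpression_rho) >= 0.3))
  # rho_min = 0 keeps every edge; missing gene handling
  expect_equal(igraph::ecount(filter_edges_by_coexpression(g, em, 0)),
               igraph::ecount(g))
  em_part <- expression_matrix(unclass(em)[-1, ])
  expect_error(filter_edges_by_coexpression(g, em_part, 0.3), "absent")
  g_dropped <- filter_edges_by_coexpression(g, em_part, 0.3,
                                            missing_genes = "drop")
  expect_false("g1" %in% igraph::V(g_dropped)$name)
})

test_that("maximal connected subnetwork picks the largest component deterministically", {
  g <- igraph::graph_from_literal(a - b, b - c, c - d, d - e, x - y, y - z)
  sub <- maximal_connected_subnetwork(g)
  expect_setequal(igraph::V(sub)$name, c("a", "b", "c", "d", "e"))
  # connected graph -> itself
  expect_equal(igraph::vcount(maximal_connected_subnetwork(sub)), 5)
  # equal-size components -> lexicographically smallest vertex set
  g2 <- igraph::graph_from_literal(m - n, p - q)
  expect_setequal(igraph::V(maximal_connected_subnetwork(g2))$name,
                  c("m", "n"))
  expect_error(maximal_connected_subnetwork(igraph::make_empty_graph()),
               "empty")
})

test_that("scale-free fit is exact on a power law and defined on a star", {
  # deterministic graph whose degree histogram is exactly n_k ~ k^-2 over
  # k in {1,2,4,8}: 4x K_{1,8}, 16x K_{1,4}, a 64-ring, 80 disjoint edges
  # gives counts (256, 64, 16, 4) over 340 nodes -> collinear log-log points
  parts <- c(replicate(4, igraph::make_star(9, mode = "undirected"),
                       simplify = FALSE),
             replicate(16, igraph::make_star(5, mode = "undirected"),
                       simplify = FALSE),
             list(igraph::make_ring(64)),
             replicate(80, igraph::make_full_graph(2), simplify = FALSE))
  g <- Reduce(igraph::disjoint_union, parts)
  expect_equal(unname(table(igraph::degree(g))[c("1", "2", "4", "8")]),
               c(256L, 64L, 16L, 4L), ignore_attr = TRUE)
  sf_exact <- scale_free_fit(g)
  expect_equal(sf_exact$r_squared, 1, tolerance = 1e-12)
  expect_equal(sf_exact$exponent, 2, tolerance = 1e-9)
  # star graph: two degree values, degenerate perfect fit, flagged
  star <- igraph::make_star(12, mode = "undirected")
  sf <- scale_free_fit(star)
  expect_equal(sf$r_squared, 1)
  expect_true(sf$degenerate)
  expect_error(scale_free_fit(igraph::make_ring(12)), "all degrees equal")
  expect_error(scale_free_fit(igraph::make_full_graph(5)), "at least 10")
})

test_that("Erdos-Renyi graphs rarely pass the scale-free bar", {
  set.seed(91)
  r2 <- replicate(20, {
    g <- igraph::sample_gnp(500, 0.02)
    scale_free_fit(g)$r_squared
  })
  expect_gte(mean(r2 < 0.85), 0.9)  # Poisson degrees are not power-law
})

test_that("hub network matches the quantile oracle and neighbour closure", {
  set.seed(101)
  g <- igraph::sample_gnp(40, 0.12)
  g <- igraph::set_vertex_attr(g, "name", value = sprintf("n%02d", 1:40))
  hn <- hub_network(g, top_fraction = 0.1)
  deg <- igraph::degree(g)
  cutoff <- stats::quantile(deg, 0.9, names = FALSE)
  hubs <- names(deg)[deg >= cutoff]
  expect_setequal(igraph::V(hn)$name[igraph::V(hn)$is_hub], hubs)
  nbrs <- unique(unlist(lapply(igraph::adjacent_vertices(g, hubs), names)))
  expect_setequal(igraph::V(hn)$name, union(hubs, nbrs))
  # every non-hub member is adjacent to a hub
  non_hub <- setdiff(igraph::V(hn)$name, hubs)
  expect_true(all(non_hub %in% nbrs))
  # star graph: hub = centre, network = whole star
  star <- igraph::make_star(10, mode = "undirected")
  hs <- hub_network(star, 0.05)
  expect_equal(igraph::vcount(hs), 10)
  expect_equal(sum(igraph::V(hs)$is_hub), 1)
})

test_that("k-clique communities reproduce the textbook cases", {
  tri <- igraph::graph_from_literal(a - b, b - c, a - c)
  expect_equal(k_clique_communities(tri, 3), list(c("a", "b", "c")))
  # two triangles sharing an edge percolate into one community
  bowtie_edge <- igraph::graph_from_literal(a - b, b - c, a - c, b - d, c - d)
  expect_equal(k_clique_communities(bowtie_edge, 3),
               list(c("a", "b", "c", "d")))
  # two triangles sharing only a node do NOT percolate (classic case)
  bowtie_node <- igraph::graph_from_literal(a - b, b - c, a - c,
                                            c - d, d - e, c - e)
  comms <- k_clique_communities(bowtie_node, 3)
  expect_equal(comm_canon(comms),
               comm_canon(list(c("a", "b", "c"), c("c", "d", "e"))))
  expect_error(k_clique_communities(tri, 2), "at least 3")
  # triangle-free graph: no community at any k
  ring <- igraph::make_ring(6)
  expect_length(k_clique_communities(ring, 3), 0L)
})

test_that("CPM equals the brute-force oracle on random graphs", {
  set.seed(111)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.3, 0.8))
    for (k in 3:4) {
      expect_equal(comm_canon(k_clique_communities(g, k)),
                   comm_canon(oracle_cpm(g, k)),
                   info = sprintf("seeded graph %d, k=%d", i, k))
    }
  }
})

test_that("CPM communities nest across k and contain their k-cliques", {
  set.seed(121)
  for (i in 1:10) {
    g <- igraph::sample_gnp(12, 0.5)
    c3 <- k_clique_communities(g, 3)
    c4 <- k_clique_communities(g, 4)
    for (comm in c4)  # each k+1 community sits inside some k community
      expect_true(any(vapply(c3, function(big) all(comm %in% big), logical(1))))
  }
})

test_that("select_module finds the highest percolating stringency", {
  k6 <- igraph::make_full_graph(6)
  res <- select_module(k6)
  expect_equal(res$k, 6L)
  expect_length(res$selected_module, 6L)
  ring <- igraph::make_ring(6)
  res2 <- select_module(ring)
  expect_true(is.na(res2$k))
  expect_length(res2$selected_module, 0L)
  # planted 11-node k=5 chain on clean background
  sim <- simulate_ppi(sprintf("G%03d", 1:60), background_edge_prob = 0,
                      seed = 5)
  g <- filter_string_edges(sim$edges)
  res3 <- select_module(g)
  expect_equal(res3$k, 5L)
  expect_identical(res3$selected_module, sim$truth$planted_module)
})
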