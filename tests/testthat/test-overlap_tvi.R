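test_that("common clones and overlap ratio follow the set algebra", {
  a <- make_rep(c(6, 3, 1), ids = 1:3, stage = "LGIN", sample_id = "L")
  b <- make_rep(c(4, 4, 2), ids = c(1, 8, 9), sample_id = "A")
  expect_identical(common_clones(a, b), common_clones(b, a))  # symmetric
  expect_length(common_clones(a, b), 1L)
  ov <- overlap_ratio(a, b)
  expect_equal(ov$overlap_ratio, 1 / 3)
  expect_equal(ov$common_cum_freq, 0.6)  # lesion-side frequency of clone 1
  # identical repertoires; disjoint repertoires
  expect_equal(overlap_ratio(a, a)$overlap_ratio, 1)
  expect_equal(overlap_ratio(a, a)$common_cum_freq, 1)
  d <- make_rep(c(1, 1), ids = 20:21)
  expect_equal(overlap_ratio(a, d)$overlap_ratio, 0)
  expect_equal(overlap_ratio(a, d)$common_cum_freq, 0)
})

test_that("overlap statistics match a brute-force oracle on random pairs", {
  set.seed(21)
  for (i in 1:10) {
    les <- random_rep(80, id_pool = 1:150, stage = "EGC", sample_id = "L")
    adj <- random_rep(90, id_pool = 1:150, sample_id = "A")
    shared <- intersect(clone_keys(les), clone_keys(adj))
    ov <- overlap_ratio(les, adj)
    expect_equal(ov$n_shared, length(shared))
    expect_equal(ov$overlap_ratio, length(shared) / richness(les))
    expect_equal(ov$common_cum_freq,
                 sum(les$freq[les$key %in% shared]), tolerance = 1e-12)
    # TOP-n variant against explicit set algebra
    n <- 25
    topk <- clone_keys(les)[1:n]
    tov <- topn_overlap(les, adj, n = n)
    expect_equal(tov$n_shared, sum(topk %in% clone_keys(adj)))
    expect_equal(tov$overlap_ratio, sum(topk %in% clone_keys(adj)) / n)
    f_top <- les$freq[1:n]
    expect_equal(tov$common_cum_freq,
                 sum(f_top[topk %in% clone_keys(adj)]) / sum(f_top),
                 tolerance = 1e-12)
    # whole-repertoire denominator variant
    expect_equal(topn_overlap(les, adj, n = n, renormalize = FALSE)$common_cum_freq,
                 sum(f_top[topk %in% clone_keys(adj)]), tolerance = 1e-12)
  }
})

test_that("topn_overlap covers its boundary cases", {
  les <- make_rep(c(5, 3, 2), stage = "LGIN", sample_id = "L")
  adj_all <- make_rep(c(1, 1, 1), sample_id = "A")
  adj_two <- make_rep(c(2, 1), ids = c(1, 3), sample_id = "A")
  adj_none <- make_rep(1, ids = 99, sample_id = "A")
  # two of TOP-3 shared, lesion freqs 0.5 and 0.2 -> ratio 2/3, F 0.7
  ov <- topn_overlap(les, adj_two, n = 3)
  expect_equal(ov$overlap_ratio, 2 / 3)
  expect_equal(ov$common_cum_freq, 0.7)
  expect_equal(topn_overlap(les, adj_all, n = 3)$common_cum_freq, 1)
  expect_equal(topn_overlap(les, adj_none, n = 3)$common_cum_freq, 0)
})

test_that("top common clones use the 'TOP-n of either sample' rule", {
  # clone 500th in lesion but 1st in adjacent must be included
  set.seed(5)
  les <- make_rep(c(1000, 999:1), ids = 1:1000, stage = "EGC", sample_id = "L")
  adj <- make_rep(c(5000, 10, 9), ids = c(600, 1, 50), sample_id = "A")
  tcc <- top_common_clones(les, adj, n = 100)
  expect_true(make_rep(1, ids = 600)$key %in% tcc$key)  # "either" condition
  # shared clone outside both TOP-n (lesion rank 50, adjacent rank 3) excluded
  tcc2 <- top_common_clones(les, adj, n = 2)
  expect_false(make_rep(1, ids = 50)$key %in% tcc2$key)
  # identical 50-clone repertoires, n = 100 -> all 50 returned
  r50 <- make_rep(sample(1:30, 50, TRUE), ids = 1:50, stage = "LGIN",
                  sample_id = "L")
  expect_equal(nrow(top_common_clones(r50, r50, n = 100)), 50L)
  # ordering: lesion frequency descending then key ascending
  expect_false(is.unsorted(rev(tcc$lesion_freq)))
})

test_that("spearman_correlation matches hand-ranked oracle incl. ties", {
  expect_equal(spearman_correlation(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_correlation(1:3, c(30, 20, 10)), -1)
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  expect_equal(spearman_correlation(x, y), oracle_spearman(x, y),
               tolerance = 1e-12)
  expect_equal(spearman_correlation(x, y),
               stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:20) {
    x <- sample(1:8, 10, TRUE); y <- sample(1:8, 10, TRUE)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
    expect_equal(spearman_correlation(x, y), oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
  expect_error(spearman_correlation(c(1, 1, 1), 1:3), "zero rank variance")
  # p-value agrees with the t approximation used by cor.test
  st <- spearman_correlation(c(1, 2, 3, 5, 4, 6), c(2, 1, 4, 3, 6, 5),
                             p_value = TRUE)
  ct <- suppressWarnings(stats::cor.test(c(1, 2, 3, 5, 4, 6),
                                         c(2, 1, 4, 3, 6, 5),
                                         method = "spearman", exact = FALSE))
  expect_equal(st$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(st$p_value, ct$p.value, tolerance = 1e-9)
})

test_that("TVI formula, bounds and monotonicity hold on a grid", {
  expect_equal(tvi_value(0.9, -0.5), 1.55)  # direct substitution
  expect_equal(tvi_value(1, 1), 0)
  expect_equal(tvi_value(0, -1), 2)
  expect_error(tvi_value(1.2, 0), "F must lie")
  expect_error(tvi_value(0.5, 2), "C must lie")
  F <- seq(0, 1, by = 0.05); C <- seq(-1, 1, by = 0.05)
  grid <- outer(F, C, tvi_value)
  expect_true(all(grid >= 0 & grid <= 2))
  # non-increasing in F at fixed C > -1, and in C at fixed F > 0
  expect_true(all(apply(grid[, C > -1], 2L, function(col) all(diff(col) <= 0))))
  expect_true(all(apply(grid[F > 0, ], 1L, function(row) all(diff(row) <= 0))))
})

test_that("compute_tvi handles identity, disjoint and degenerate pairs", {
  set.seed(13)
  base <- random_rep(60, id_pool = 1:500, stage = "LGIN", sample_id = "L")
  twin <- make_rep(base$count, ids = match(base$cdr3nt, nt_seq(1:500)),
                   sample_id = "A")
  pair <- lesion_adjacent_pair("P1", base, twin)
  tv <- compute_tvi(pair, n = 100)
  expect_equal(tv$F, 1)
  expect_equal(tv$C, 1)
  expect_equal(tv$tvi, 0)
  # disjoint: F = 0 short-circuit gives TVI = 2 despite undefined C
  les <- make_rep(c(3, 2, 1), ids = 1:3, stage = "EGC", sample_id = "L")
  adj <- make_rep(c(1, 1), ids = 50:51, sample_id = "A")
  tv2 <- compute_tvi(lesion_adjacent_pair("P2", les, adj))
  expect_equal(tv2$tvi, 2)
  expect_true(is.na(tv2$C))
  # < 3 common top clones with F > 0: TVI reported missing with a warning
  adj2 <- make_rep(c(1, 1), ids = c(1, 50), sample_id = "A")
  expect_warning(tv3 <- compute_tvi(lesion_adjacent_pair("P3", les, adj2)),
                 "fewer than 3")
  expect_true(is.na(tv3$tvi))
  expect_equal(tv3$n_common_top, 1L)
})
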