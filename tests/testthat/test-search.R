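# Clustering, initial-tree construction, and the staged robust search.

test_that("well-separated clones are clustered apart, identical cells together", {
  set.seed(71)
  a <- matrix(rpois(20 * 30, 4), 20, 30)
  b <- matrix(rpois(20 * 30, 4), 20, 30)
  b[, 1:10] <- b[, 1:10] + 12
  labels <- cluster_cells(rbind(a, b))
  expect_equal(length(unique(labels)), 2L)
  expect_equal(length(unique(labels[1:20])), 1L)
  expect_equal(length(unique(labels[21:40])), 1L)
  # identical rows collapse to one cluster
  expect_equal(unique(cluster_cells(matrix(3, 8, 10))), 1L)
})

test_that("cluster averaging preserves totals and weights", {
  set.seed(72)
  m <- matrix(rpois(12 * 5, 10), 12, 5)
  labels <- rep(1:3, each = 4)
  cm <- cluster_matrix(m, labels)
  expect_equal(sum(cm$weights), 12)
  expect_equal(cm$matrix[2, ], colMeans(m[5:8, ]))
  # singleton clusters reproduce the matrix
  cm1 <- cluster_matrix(m, 1:12)
  expect_equal(unname(cm1$matrix), m + 0)
  expect_true(all(cm1$weights == 1))
  # weighted cluster score equals the full-data score when members are equal
  D <- matrix(rep(c(10, 6, 4), each = 4), ncol = 3)[rep(1, 6), ] + 0
  tr <- cna_tree(0L, list(c(S1 = 1)), n_segments = 3)
  params <- likelihood_params(nu = 2)
  tab_full <- attachment_table(tr, D, c(1, 1, 1), params)
  full <- max_log_score(tr, tab_full)$total
  cmx <- cluster_matrix(D, rep(1L, 6))
  tab_cl <- attachment_table(tr, cmx$matrix, c(1, 1, 1), params)
  clustered <- max_log_score(tr, tab_cl, weights = cmx$weights)$total
  expect_equal(clustered, full, tolerance = 1e-9)
})

test_that("initial trees reconstruct simple clone structures and stay valid", {
  # all-diploid profiles: root-only tree
  tr <- initial_tree(matrix(2L, 4, 6))
  expect_equal(tr$n, 0L)
  # two clones differing in one segment
  prof <- rbind(c(2L, 2L, 2L), c(2L, 3L, 2L), c(2L, 3L, 2L))
  tr <- initial_tree(prof)
  expect_true(validate_tree(tr)$valid)
  gs <- genotype_set(tr)
  expect_true(any(apply(gs, 1, function(g) all(g == c(2, 3, 2)))))
  expect_true(any(apply(gs, 1, function(g) all(g == c(2, 2, 2)))))
  # random integer profiles always produce a valid tree
  set.seed(73)
  for (r in 1:20) {
    prof <- matrix(sample(0:4, 5 * 4, TRUE,
                          prob = c(0.05, 0.1, 0.6, 0.15, 0.1)), 5, 4)
    expect_true(validate_tree(initial_tree(prof))$valid)
  }
})

test_that("copy-number calls expand genotypes over segments", {
  tr <- fig_tree()
  seg <- build_segments(c(2, 4, 7, 9), 12)
  cnv <- call_copy_numbers(tr, c(0L, 5L), seg)
  expect_true(all(cnv[1, ] == 2L))
  # clone at node 5: 4 over S1's bins, 3 over S2's, 2 elsewhere
  expect_equal(cnv[2, ], c(4, 4, 3, 3, 2, 2, 2, 2, 2, 2, 2, 2))
  # rows stay within the genotype set
  gs <- genotype_set(tr)
  seg_cols <- c(1, 3, 5, 8, 10)
  expect_true(all(apply(cnv[, seg_cols], 1, function(r)
    any(apply(gs, 1, function(g) all(g == r))))))
})

test_that("robust search recovers structure on a small simulation", {
  set.seed(74)
  st <- sim_settings(n_bins = 200, n_nodes = 4, n_segments = 8,
                     reads_per_bin = 8, n_cells = 30)
  sim <- generate_dataset(st)
  agg <- aggregate_counts(sim$counts, sim$segments)
  cfg <- search_config(n_chains = 4, chain_length_factor = 400,
                       min_chain_length = 800, max_rounds = 2)
  set.seed(75)
  res <- robust_infer(agg$D, agg$sizes, config = cfg,
                      params = likelihood_params(nu = 4))
  cnv <- call_copy_numbers(res$tree, res$sigma, sim$segments)
  d_inf <- delta_rmse(sim$profiles, cnv)
  d_dip <- delta_rmse(sim$profiles, matrix(2L, 30, 200))
  expect_lt(d_inf, d_dip)
  # reproducibility under the same seed
  set.seed(75)
  res2 <- robust_infer(agg$D, agg$sizes, config = cfg,
                       params = likelihood_params(nu = 4))
  expect_identical(res$score, res2$score)
  expect_identical(res$sigma, res2$sigma)
})

test_that("a diploid truth yields a root-only or near-empty tree", {
  set.seed(76)
  counts <- matrix(rpois(25 * 100, 6), 25, 100)
  agg <- aggregate_counts(counts, build_segments(c(30, 60), 100))
  cfg <- search_config(n_chains = 3, chain_length_factor = 300,
                       min_chain_length = 600, max_rounds = 1)
  res <- robust_infer(agg$D, agg$sizes, config = cfg,
                      params = likelihood_params(nu = 4))
  # every cell should be called diploid everywhere
  cnv <- call_copy_numbers(res$tree, res$sigma, build_segments(c(30, 60), 100))
  expect_true(mean(cnv == 2L) > 0.95)
})

test_that("root-ploidy comparison prefers the generating baseline", {
  set.seed(77)
  # tetraploid truth with one extra amplification
  st <- sim_settings(n_bins = 120, n_nodes = 2, n_segments = 6,
                     reads_per_bin = 8, n_cells = 20, root_ploidy = 4L)
  sim <- generate_dataset(st)
  agg <- aggregate_counts(sim$counts, sim$segments)
  cfg <- search_config(n_chains = 2, chain_length_factor = 200,
                       min_chain_length = 400, max_rounds = 1)
  set.seed(78)
  cmp <- compare_root_ploidies(agg$D, agg$sizes, ploidies = list(2L, 4L),
                               config = cfg, params = likelihood_params(nu = 4))
  expect_gt(cmp$scores["4"], cmp$scores["2"])
})
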