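# Event-vector prior, tree-size penalty, and the marginal/maximized scores.

test_that("the event prior matches the generative event distribution", {
  # one node, one segment of K = 1, |delta| = 1: Pois terms, sign, and a
  # trivial subset choice
  tr <- cna_tree(0L, matrix(1L, 1, 1))
  expect_equal(event_vector_log_prior(tr, prior_params(lambda_s = 0.1, lambda_c = 0.2)),
               log(exp(-0.1)) + log(exp(-0.2)) + log(0.5))
  # with K = 4 segments the uniform subset choice contributes -log C(4, 1)
  tr4 <- cna_tree(0L, matrix(c(1L, 0L, 0L, 0L), 1, 4))
  expect_equal(event_vector_log_prior(tr4),
               -0.1 - 0.2 + log(0.5) - log(4))
  # empty tree: empty product
  empty <- cna_tree(integer(0), matrix(0L, 0, 3))
  expect_equal(event_vector_log_prior(empty), 0)
  # prior decreases as any |delta| grows
  lp <- vapply(1:4, function(d) {
    event_vector_log_prior(cna_tree(0L, matrix(c(d, 0L), 1, 2)))
  }, numeric(1))
  expect_true(all(diff(lp) < 0))
})

test_that("the tree penalty is linear in size", {
  expect_equal(tree_log_penalty(0), 0)
  expect_equal(tree_log_penalty(20, prior_params(kappa = 1)), -20)
  pen <- vapply(0:10, tree_log_penalty, numeric(1))
  expect_true(all(diff(pen) < 0))
})

test_that("sum score matches a direct evaluation of its definition", {
  set.seed(41)
  for (r in 1:25) {
    n <- sample(1:4, 1); K <- sample(2:4, 1); m <- sample(2:6, 1)
    tr <- oracle_random_tree(n, K)
    D <- matrix(rpois(m * K, 15), m, K)
    sizes <- sample(1:8, K, replace = TRUE)
    nu <- runif(1, 1, 6)
    params <- likelihood_params(nu = nu)
    tab <- attachment_table(tr, D, sizes, params)
    sc <- sum_log_score(tr, tab)
    expect_equal(sc$total,
                 oracle_sum_score(tr, D, sizes, nu, params$eta, FALSE,
                                  0.1, 0.2, 1),
                 tolerance = 1e-9, info = paste("replicate", r))
    expect_equal(sc$total, sc$log_event_prior + sc$log_tree_penalty +
                   sc$log_attachment_term)
  }
})

test_that("root-only trees score the bare root log-likelihood", {
  empty <- cna_tree(integer(0), matrix(0L, 0, 3))
  D <- matrix(rpois(12, 10), 4, 3)
  tab <- attachment_table(empty, D, c(2, 3, 1), likelihood_params(nu = 2))
  sc <- sum_log_score(empty, tab)
  expect_equal(sc$total, sum(tab$root_loglik))
  expect_equal(max_log_score(empty, tab)$total, sum(tab$root_loglik))
})

test_that("invalid trees score minus infinity in both modes", {
  dup <- cna_tree(c(0, 0), rbind(c(1L, 0L), c(1L, 0L)))
  D <- matrix(rpois(6, 10), 3, 2)
  tab <- structure(list(loglik = matrix(0, 3, 3), root_loglik = rep(0, 3)),
                   class = "scn_attachment")
  expect_identical(sum_log_score(dup, tab)$total, -Inf)
  expect_identical(max_log_score(dup, tab)$total, -Inf)
  expect_equal(sum_log_score(dup, tab)$reason, "duplicate_genotype")
})

test_that("max score bounds and cell-reordering invariance hold", {
  set.seed(42)
  tr <- oracle_random_tree(3, 3)
  m <- 5
  D <- matrix(rpois(m * 3, 20), m, 3)
  sizes <- c(2, 1, 3)
  params <- likelihood_params(nu = 4)
  tab <- attachment_table(tr, D, sizes, params)
  smax <- max_log_score(tr, tab)
  ssum <- sum_log_score(tr, tab)
  # max over attachments <= marginal sum, after aligning the differing
  # normalization and penalty terms
  expect_lte(smax$total,
             ssum$total + m * log(tr$n + 1) - tree_log_penalty(tr$n))
  # reordering cells leaves both scores unchanged
  perm <- sample(m)
  tab2 <- attachment_table(tr, D[perm, ], sizes, params)
  expect_equal(max_log_score(tr, tab2)$total, smax$total)
  expect_equal(sum_log_score(tr, tab2)$total, ssum$total)
})

test_that("normalized sum scores over a small space form the exact posterior", {
  # exhaustive check that exp(score) normalizes to the brute-force posterior
  set.seed(43)
  sizes <- c(3, 4)
  D <- matrix(rpois(3 * 2, 25), 3, 2)
  params <- likelihood_params(nu = 2)
  states <- enumerate_small_space(max_d = 1L)
  scores <- vapply(states, function(tr) {
    sum_log_score(tr, attachment_table(tr, D, sizes, params))$total
  }, numeric(1))
  oracle <- vapply(states, function(tr) {
    oracle_sum_score(tr, D, sizes, 2, params$eta, FALSE, 0.1, 0.2, 1)
  }, numeric(1))
  p1 <- exp(scores - max(scores)); p1 <- p1 / sum(p1)
  p2 <- exp(oracle - max(oracle)); p2 <- p2 / sum(p2)
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("best attachments take per-cell argmaxes with root-first ties", {
  tab <- structure(list(loglik = matrix(0, 3, 4), root_loglik = rep(0, 3)),
                   class = "scn_attachment")
  expect_equal(best_attachments(tab), rep(0L, 3))
  tab$loglik[2, 3] <- 5
  tab$loglik[3, c(2, 4)] <- c(7, 7)
  expect_equal(best_attachments(tab), c(0L, 2L, 1L))
})
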