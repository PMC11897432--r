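# Dirichlet-multinomial attachment likelihoods, the multinomial limit, and
# the incremental traversal against brute-force recomputation.

test_that("segment probabilities follow c*s/Z with the eta floor", {
  p <- segment_probabilities(c(2, 2), c(1, 1))
  expect_equal(as.numeric(p), c(0.5, 0.5))
  # the worked-example clone profile over unit segments
  p <- segment_probabilities(c(4, 3, 2, 2, 2), rep(1, 5))
  expect_equal(as.numeric(p), c(4, 3, 2, 2, 2) / 13)
  expect_equal(attr(p, "Z"), 13)
  # a fully deleted segment keeps residual mass eta
  eta <- 1e-4
  p <- segment_probabilities(c(0, 2), c(5, 5), eta = eta)
  expect_equal(as.numeric(p), c(5 * eta, 10) / (5 * eta + 10))
  expect_equal(sum(p), 1)
})

test_that("closed-form single-cell log-likelihoods are reproduced", {
  # Gamma-ratio evaluation: D=(2,0), diploid two segments, nu=1 -> log(0.3)
  expect_equal(dm_cell_loglik(c(2, 0), c(2, 2), c(1, 1), likelihood_params(nu = 1)),
               log(0.3), tolerance = 1e-12)
  # multinomial: Z=4, p1=1/2, two reads in segment 1 -> log(1/4)
  expect_equal(multinomial_cell_loglik(c(2, 0), c(2, 2), c(1, 1)),
               log(0.25), tolerance = 1e-12)
  # no reads: empty product
  expect_equal(dm_cell_loglik(rep(0, 4), c(2, 1, 3, 2), rep(2, 4),
                              likelihood_params(nu = 2)), 0)
  # reads concentrated where the genotype is amplified favour that genotype
  D_row <- c(30, 5)
  hi <- multinomial_cell_loglik(D_row, c(4, 1), c(1, 1))
  lo <- multinomial_cell_loglik(D_row, c(1, 4), c(1, 1))
  expect_gt(hi, lo)
})

test_that("the Dirichlet-multinomial converges to the multinomial limit", {
  set.seed(31)
  diffs <- matrix(NA_real_, 20, 4)
  nus <- c(1e2, 1e4, 1e6, 1e8)
  for (r in 1:20) {
    K <- sample(3:6, 1)
    geno <- sample(0:4, K, replace = TRUE)
    sizes <- sample(1:20, K, replace = TRUE)
    # reads drawn from the observation model itself, so deleted segments
    # carry (almost) no reads, as in data
    p <- segment_probabilities(geno, sizes)
    D_row <- as.numeric(rmultinom(1, 10 * K, p))
    mult <- multinomial_cell_loglik(D_row, geno, sizes)
    for (i in seq_along(nus)) {
      dm <- dm_cell_loglik(D_row, geno, sizes, likelihood_params(nu = nus[i]))
      diffs[r, i] <- abs(dm - mult)
    }
  }
  expect_lt(max(diffs[, 4]), 1e-3)                   # agreement at nu = 1e8
  expect_true(all(apply(diffs, 1, diff) <= 1e-12))   # shrinks monotonically in nu
})

test_that("root log-likelihood matches its closed forms and caching contract", {
  # multinomial limit is ploidy independent and scale invariant
  r1 <- root_loglik(c(2, 0), c(1, 1), root_ploidy = 2,
                    likelihood_params(use_multinomial = TRUE))
  expect_equal(unname(r1), log(0.25), tolerance = 1e-12)
  r2 <- root_loglik(c(2, 0), c(1, 1), root_ploidy = 7,
                    likelihood_params(use_multinomial = TRUE))
  expect_equal(r1, r2)
  r3 <- root_loglik(c(2, 0), c(2, 2), root_ploidy = 2,
                    likelihood_params(use_multinomial = TRUE))
  expect_equal(r1, r3)  # doubling all sizes changes nothing
  # finite-nu root equals the DM likelihood on the root genotype
  params <- likelihood_params(nu = 3)
  D_row <- c(5, 2, 9)
  expect_equal(unname(root_loglik(D_row, c(2, 4, 1), c(2, 2, 2), params)),
               dm_cell_loglik(D_row, c(2, 2, 2), c(2, 4, 1), params))
})

test_that("log-likelihoods are invariant under joint segment permutation", {
  set.seed(32)
  K <- 5
  geno <- c(3, 0, 2, 1, 4)
  sizes <- c(2, 7, 1, 4, 3)
  D_row <- rpois(K, 8)
  perm <- sample(K)
  params <- likelihood_params(nu = 2.5)
  expect_equal(dm_cell_loglik(D_row, geno, sizes, params),
               dm_cell_loglik(D_row[perm], geno[perm], sizes[perm], params))
  expect_equal(multinomial_cell_loglik(D_row, geno, sizes),
               multinomial_cell_loglik(D_row[perm], geno[perm], sizes[perm]))
})

test_that("traversal attachment table equals brute-force recomputation", {
  set.seed(33)
  for (r in 1:60) {
    n <- sample(1:8, 1); K <- sample(2:6, 1); m <- sample(1:20, 1)
    tr <- oracle_random_tree(n, K)
    D <- matrix(rpois(m * K, 12), m, K)
    sizes <- sample(1:10, K, replace = TRUE)
    nu <- runif(1, 0.5, 8)
    multi <- r %% 3 == 0
    params <- likelihood_params(nu = nu, use_multinomial = multi)
    tab <- attachment_table(tr, D, sizes, params)
    oracle <- oracle_attachment_table(tr, D, sizes, nu, params$eta, multi)
    expect_equal(unname(tab$loglik), oracle, tolerance = 1e-9)
    expect_equal(tab$loglik[, 1], rep(0, m), ignore_attr = TRUE)
  }
})

test_that("a cell generated from a node attaches there at high depth", {
  set.seed(34)
  tr <- fig_tree()
  gen <- compute_genotypes(tr)
  sizes <- rep(1, 5)
  p <- gen["5", ] / sum(gen["5", ])
  D <- matrix(as.numeric(rmultinom(1, 250, p)), 1)
  tab <- attachment_table(tr, D, sizes, likelihood_params(nu = 4))
  expect_equal(best_attachments(tab), 5L)
})

test_that("attachment_table rejects inconsistent input", {
  tr <- fig_tree()
  bad <- cna_tree(c(0, 0), rbind(c(1L, 0L), c(1L, 0L)))
  expect_error(attachment_table(bad, matrix(1, 1, 2), c(1, 1)), "invalid tree")
  expect_error(attachment_table(tr, matrix(1, 1, 3), c(1, 1, 1)), "mismatch")
})
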