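# CNA-tree construction, genotype derivation, and validity constraints.

test_that("the worked-example tree yields the published clone profiles", {
  tr <- fig_tree()
  gen <- compute_genotypes(tr)
  # clone attached at node 5 (root -> +S1+S2 -> +S1)
  expect_equal(unname(gen["5", ]), c(4L, 3L, 2L, 2L, 2L))
  # hand-accumulated path root -> 1 -> 2 -> 3
  expect_equal(unname(gen["3", ]), c(2L, 4L, 3L, 2L, 2L))
  # root row is the ploidy itself
  expect_equal(unname(gen["0", ]), rep(2L, 5))
  expect_true(validate_tree(tr)$valid)
})

test_that("events given as named vectors and as a dense matrix agree", {
  tr1 <- fig_tree()
  ev <- matrix(0L, 5, 5)
  ev[1, 1:2] <- 1L; ev[2, 2:3] <- 1L; ev[3, 1] <- -1L; ev[4, 4] <- -1L; ev[5, 1] <- 1L
  tr2 <- cna_tree(c(0, 1, 2, 2, 1), ev)
  expect_identical(tr1$events, tr2$events)
  # repeated touches of a segment are normalized to the net delta
  tr3 <- cna_tree(0L, list(c(S1 = 2, S1 = -1)), n_segments = 2)
  expect_equal(tr3$events[1, ], c(1L, 0L))
})

test_that("constructor rejects malformed input", {
  expect_error(cna_tree(c(0, 3), matrix(1L, 2, 2)), "0..n")
  expect_error(cna_tree(c(2, 1), matrix(1L, 2, 2)), "rooted tree")  # cycle
  expect_error(cna_tree(0L, list(c(S7 = 1)), n_segments = 5), "out of range")
  expect_error(cna_tree(0L, list(c(S1 = 1)), n_segments = 2, root_ploidy = c(2L, -1L)),
               "non-negative")
})

test_that("genotype conservation: child minus parent equals the event", {
  set.seed(11)
  for (r in 1:25) {
    tr <- oracle_random_tree(sample(1:6, 1), sample(2:5, 1))
    gen <- compute_genotypes(tr)
    for (u in seq_len(tr$n)) {
      expect_equal(gen[u + 1L, ] - gen[tr$parents[u] + 1L, ], tr$events[u, ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("segment relabelling permutes genotype columns identically", {
  set.seed(12)
  tr <- oracle_random_tree(5, 4)
  perm <- sample(4)
  tr2 <- cna_tree(tr$parents, tr$events[, perm, drop = FALSE],
                  root_ploidy = tr$root_ploidy[perm])
  expect_equal(unname(compute_genotypes(tr2)),
               unname(compute_genotypes(tr)[, perm]))
})

test_that("validity reason codes fire on the canonical violations", {
  # identical single events on two root children duplicate a genotype
  dup <- cna_tree(c(0, 0), rbind(c(1L, 0L), c(1L, 0L)))
  expect_false(validate_tree(dup)$valid)
  expect_equal(validate_tree(dup)$reason, "duplicate_genotype")
  # a fully deleted segment cannot be regained below
  regain <- cna_tree(c(0, 1), rbind(c(-2L, 0L), c(1L, 0L)))
  expect_equal(validate_tree(regain)$reason, "regain_after_zero")
  # deleting below zero is negative
  neg <- cna_tree(c(0, 1), rbind(c(-2L, 0L), c(-1L, 1L)))
  expect_equal(validate_tree(neg)$reason, "negative_state")
  # a node whose net effect is zero recreates an ancestor genotype
  net0 <- cna_tree(c(0, 1), rbind(c(1L, 0L), c(0L, 0L)))
  expect_equal(validate_tree(net0)$reason, "duplicate_genotype")
})

test_that("validate_tree agrees with the exhaustive trajectory checker", {
  set.seed(13)
  for (r in 1:300) {
    tr <- oracle_random_tree_any(sample(1:6, 1), sample(2:5, 1))
    v <- validate_tree(tr)
    expect_equal(if (v$valid) "valid" else v$reason, oracle_validate(tr),
                 info = paste("replicate", r))
  }
})

test_that("genotype_set returns n + 1 distinct profiles for valid trees", {
  tr <- fig_tree()
  gs <- genotype_set(tr)
  expect_equal(nrow(gs), 6L)
  expect_true(any(apply(gs, 1, function(r) all(r == c(2, 2, 2, 2, 2)))))
  expect_true(any(apply(gs, 1, function(r) all(r == c(4, 3, 2, 2, 2)))))
  set.seed(14)
  for (r in 1:20) {
    tr <- oracle_random_tree(sample(1:6, 1), sample(2:5, 1))
    expect_equal(nrow(genotype_set(tr)), tr$n + 1L)
  }
  single <- cna_tree(0L, list(c(S1 = 1)), n_segments = 2)
  expect_equal(nrow(genotype_set(single)), 2L)
})

test_that("trees round-trip through JSON and export to DOT", {
  tr <- fig_tree()
  js <- tree_to_json(tr)
  tr2 <- tree_from_json(js)
  expect_equal(tr2$parents, tr$parents)
  expect_equal(tr2$events, tr$events)
  expect_equal(tr2$root_ploidy, tr$root_ploidy)

  path <- tempfile(fileext = ".json")
  tree_to_json(tr, path)
  expect_equal(tree_from_json(path)$events, tr$events)

  dot <- tree_to_dot(tr, sigma = c(3L, 4L, 1L, 5L))
  expect_true(dot[1] == "digraph cna_tree {")
  expect_true(dot[length(dot)] == "}")
  expect_equal(sum(grepl("->", dot, fixed = TRUE)), tr$n)
})
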