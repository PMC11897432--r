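# Sampler mechanics: reproducibility, best-state tracking, validity of
# visited states, and stationarity against an enumerated posterior.

make_small_data <- function(seed = 42, reads = 60) {
  set.seed(seed)
  sizes <- c(5, 5)
  truth <- cna_tree(c(0L, 1L), rbind(c(1L, 0L), c(0L, -1L)), root_ploidy = 2L)
  gen <- compute_genotypes(truth)
  D <- t(sapply(c(0L, 1L, 2L), function(s) {
    p <- pmax(gen[s + 1L, ], 1e-4) * sizes
    as.numeric(rmultinom(1, reads, p / sum(p)))
  }))
  list(D = D, sizes = sizes, truth = truth)
}

test_that("chains are reproducible and the best score never decreases", {
  dat <- make_small_data()
  set.seed(7)
  ch1 <- run_chain(dat$truth, dat$D, dat$sizes, iterations = 3000, nu = 1)
  set.seed(7)
  ch2 <- run_chain(dat$truth, dat$D, dat$sizes, iterations = 3000, nu = 1)
  expect_identical(ch1$best_score, ch2$best_score)
  expect_identical(ch1$final_tree$parents, ch2$final_tree$parents)
  expect_identical(ch1$final_tree$events, ch2$final_tree$events)
  expect_identical(ch1$final_nu, ch2$final_nu)
  expect_true(all(diff(ch1$improvements$score) > 0))
  expect_gte(ch1$best_score, ch1$final_score - 1e-9)
})

test_that("every state the chain reports is a valid tree", {
  dat <- make_small_data(43)
  set.seed(8)
  ch <- run_chain(dat$truth, dat$D, dat$sizes, iterations = 2000, nu = 2)
  expect_true(validate_tree(ch$best_tree)$valid)
  expect_true(validate_tree(ch$final_tree)$valid)
  # visit-count keys decode to valid trees as well
  set.seed(9)
  ch <- run_chain(dat$truth, dat$D, dat$sizes, iterations = 500, nu = 2,
                  moves = move_config(n_min = 1L, n_max = 2L, max_abs_delta = 2L),
                  track_states = TRUE)
  states <- enumerate_small_space()
  keys <- vapply(states, scnatree:::.state_key, character(1))
  expect_true(all(names(ch$visits) %in% keys))
  expect_equal(sum(ch$visits), 500)
})

test_that("chain-reported scores equal the R-side score of the same state", {
  dat <- make_small_data(44)
  for (mode in c("max", "sum")) {
    set.seed(10)
    ch <- run_chain(dat$truth, dat$D, dat$sizes, iterations = 1500, nu = 3,
                    score = mode)
    tab <- attachment_table(ch$best_tree, dat$D, dat$sizes,
                            likelihood_params(nu = ch$best_nu))
    sc <- if (mode == "max") max_log_score(ch$best_tree, tab)
          else sum_log_score(ch$best_tree, tab)
    expect_equal(ch$best_score, sc$total, tolerance = 1e-8)
  }
})

test_that("the nu walk respects its bounds and a zero step is the identity", {
  dat <- make_small_data(45)
  nu_only <- move_config(prune_reattach = 0, label_swap = 0, event_change = 0,
                         add_remove_node = 0, condense_split = 0,
                         genotype_preserving = 0, nu_walk = 1,
                         nu_sd = 0.5, nu_bounds = c(0.5, 10))
  set.seed(11)
  ch <- run_chain(dat$truth, dat$D, dat$sizes, iterations = 2000, nu = 2,
                  moves = nu_only)
  expect_gte(ch$final_nu, 0.5)
  expect_lte(ch$final_nu, 10)
  nu_frozen <- nu_only
  nu_frozen$nu_sd <- 0
  set.seed(12)
  ch0 <- run_chain(dat$truth, dat$D, dat$sizes, iterations = 200, nu = 2,
                   moves = nu_frozen)
  expect_identical(ch0$final_nu, 2)
})

test_that("label swaps explore both labelings of a symmetric pair evenly", {
  dat <- make_small_data(46)
  start <- cna_tree(c(0L, 0L), rbind(c(1L, 0L), c(0L, 1L)), root_ploidy = 2L)
  swap_only <- move_config(prune_reattach = 0, label_swap = 1, event_change = 0,
                           add_remove_node = 0, condense_split = 0,
                           genotype_preserving = 0, nu_walk = 0)
  set.seed(13)
  ch <- run_chain(start, dat$D, dat$sizes, iterations = 20000, nu = 1,
                  params = likelihood_params(use_multinomial = TRUE),
                  moves = swap_only, track_states = TRUE)
  expect_equal(length(ch$visits), 2L)
  # both labelings carry identical posterior; occupancy should be near-even
  expect_lt(abs(ch$visits[1] / sum(ch$visits) - 0.5), 0.05)
})

test_that("visit frequencies match the enumerated posterior on a small space", {
  # reduced-size stationarity audit across all move types (the full-scale
  # version runs in the acceptance suite)
  dat <- make_small_data(47)
  params <- likelihood_params(nu = 1, use_multinomial = TRUE)
  states <- enumerate_small_space()
  keys <- vapply(states, scnatree:::.state_key, character(1))
  scores <- vapply(states, function(tr) {
    sum_log_score(tr, attachment_table(tr, dat$D, dat$sizes, params))$total
  }, numeric(1))
  post <- exp(scores - max(scores))
  post <- setNames(post / sum(post), keys)
  moves <- move_config(nu_walk = 0, n_min = 1L, n_max = 2L, max_abs_delta = 2L)
  set.seed(14)
  ch <- run_chain(states[[which.max(scores)]], dat$D, dat$sizes,
                  iterations = 120000, nu = 1, params = params, moves = moves,
                  score = "sum", track_states = TRUE)
  expect_lt(oracle_tv(ch$visits, post), 0.06)
})
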