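# Step-change statistic, cross-cell signal collation, breakpoint calling,
# and segment aggregation.

test_that("the step statistic is zero for constant rows and peaks at a step", {
  const_row <- rep(4, 100)
  expect_equal(per_cell_step_statistic(const_row, window = 10),
               rep(0, 99), tolerance = 1e-12)
  # clean step 4 -> 8 between bins 50 and 51 (boundary index 50)
  step_row <- c(rep(4, 50), rep(8, 50))
  s <- per_cell_step_statistic(step_row, window = 10)
  expect_equal(which.max(s), 50L)
  expect_gt(max(s), 0)
})

test_that("noise-only rows score below a clean step", {
  # null rows share the step row's mean depth so only the step differs
  set.seed(21)
  step_max <- max(per_cell_step_statistic(c(rep(4, 50), rep(8, 50)), window = 10))
  wins <- vapply(1:100, function(r) {
    noise <- rpois(100, 6)
    max(per_cell_step_statistic(noise, window = 10)) < step_max
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("window preconditions are enforced", {
  expect_error(per_cell_step_statistic(rep(1, 10), window = 6), "B/2")
  expect_error(per_cell_step_statistic(rep(1, 10), window = 1), "at least 2")
})

test_that("combined signal collates cells and is permutation invariant", {
  # all cells constant: zero everywhere
  expect_equal(combined_signal(matrix(5, 10, 60), window = 5), rep(0, 59))
  # single cell: combined equals the rectified per-cell statistic
  set.seed(22)
  row <- rpois(80, 6)
  expect_equal(combined_signal(matrix(row, 1), window = 8, normalize = FALSE),
               pmax(per_cell_step_statistic(row, window = 8), 0))
  # permuting cell rows leaves the signal unchanged
  m <- matrix(rpois(20 * 80, 5), 20, 80)
  expect_equal(combined_signal(m, window = 8),
               combined_signal(m[sample(20), ], window = 8))
})

test_that("scaling a cell's counts leaves its statistic argmax unchanged", {
  set.seed(23)
  row <- c(rpois(60, 6), rpois(60, 12))
  m1 <- matrix(row, 1)
  m2 <- matrix(row * 7, 1)
  s1 <- combined_signal(m1, window = 10)
  s2 <- combined_signal(m2, window = 10)
  expect_equal(which.max(s1), which.max(s2))
})

test_that("breakpoint calling thresholds and separates candidates", {
  expect_length(call_breakpoints(rep(0, 99))$boundaries, 0L)
  # two isolated spikes, plus a shoulder next to the larger one
  sig <- rep(0.01, 199)
  sig[50] <- 10; sig[51] <- 8; sig[120] <- 9
  bp <- call_breakpoints(sig, threshold_sd = 5, min_separation = 10)
  expect_equal(bp$boundaries, c(50L, 120L))
  # equal signals break ties toward the lower index
  sig2 <- rep(0.01, 99); sig2[40] <- 5; sig2[45] <- 5
  expect_equal(call_breakpoints(sig2, min_separation = 10)$boundaries, 40L)
})

test_that("segments partition the bins and aggregation conserves reads", {
  seg <- build_segments(integer(0), 100)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$size, 100L)
  seg <- build_segments(c(25, 50, 75), 100)
  expect_equal(seg$size, rep(25L, 4))
  # four breakpoints define five segments
  expect_equal(nrow(build_segments(c(10, 20, 30, 40), 100)), 5L)
  expect_error(build_segments(c(0), 100), "1..B-1")

  set.seed(24)
  counts <- matrix(rpois(15 * 60, 5), 15, 60)
  seg <- build_segments(sort(sample(1:59, 4)), 60)
  agg <- aggregate_counts(counts, seg)
  expect_equal(rowSums(agg$D), rowSums(counts), ignore_attr = TRUE)
  # direct two-loop oracle
  idx <- rep(seq_len(nrow(seg)), seg$size)
  for (j in 1:15) for (k in seq_len(nrow(seg)))
    expect_equal(agg$D[j, k], sum(counts[j, idx == k]), ignore_attr = TRUE)
  # identity segmentation returns the matrix itself
  ident <- aggregate_counts(counts, build_segments(1:59, 60))
  expect_equal(unname(ident$D), counts)
  # single segment returns row sums
  one <- aggregate_counts(counts, build_segments(integer(0), 60))
  expect_equal(as.numeric(one$D), rowSums(counts), ignore_attr = TRUE)
})

test_that("a multi-cell step is recovered with high power", {
  # single step of one copy in 20% of cells at depth 8 per bin
  set.seed(25)
  hits <- vapply(1:15, function(r) {
    B <- 200
    start_bin <- sample(60:140, 1)
    prof <- matrix(2, 50, B)
    prof[sample(50, 10), start_bin:B] <- 3
    counts <- matrix(rpois(50 * B, prof / 2 * 8), 50, B)
    called <- detect_breakpoints(counts, window = 10)$boundaries
    length(called) > 0 && min(abs(called - (start_bin - 1L))) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("outlier bins are masked by the median-multiple rule", {
  counts <- matrix(5, 10, 50)
  counts[, 7] <- 60
  expect_equal(which(outlier_bin_mask(counts, factor = 3)), 7L)
})
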