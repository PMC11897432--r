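# Generative model for benchmarking: random CNA trees, uniform cell
# attachments, and Dirichlet-multinomial read counts over bins, with the
# ground truth retained.

#' Simulation settings
#'
#' Defaults follow the benchmark design: 10 000 bins, 20-node trees over 40
#' segments, 400 cells, overdispersion concentration 4, an average of
#' `reads_per_bin` reads per bin per cell, events touching 1 + Poisson(0.1)
#' segments with 1 + Poisson(0.2) copies each and uniform sign.
#'
#' @param n_bins number of genomic bins.
#' @param n_nodes event nodes in the generating tree.
#' @param n_segments contiguous segments the bins are partitioned into.
#' @param reads_per_bin mean sequencing depth per bin (2, 4 or 8 in the
#'   benchmark).
#' @param n_cells number of cells.
#' @param lambda_s,lambda_c shifted-Poisson event-size parameters.
#' @param nu_sim Dirichlet-multinomial concentration of the read model.
#' @param eta zero-state floor applied when building read probabilities.
#' @param root_ploidy root copy number (scalar or per-segment).
#' @return list of validated settings.
#' @export
sim_settings <- function(n_bins = 10000L, n_nodes = 20L, n_segments = 40L,
                         reads_per_bin = 4, n_cells = 400L,
                         lambda_s = 0.1, lambda_c = 0.2, nu_sim = 4,
                         eta = 1e-4, root_ploidy = 2L) {
  stopifnot(n_bins >= 1, n_segments >= 1, n_segments <= n_bins,
            n_nodes >= 0, n_cells >= 1, reads_per_bin > 0, nu_sim > 0)
  list(n_bins = as.integer(n_bins), n_nodes = as.integer(n_nodes),
       n_segments = as.integer(n_segments), reads_per_bin = reads_per_bin,
       n_cells = as.integer(n_cells), lambda_s = lambda_s,
       lambda_c = lambda_c, nu_sim = nu_sim, eta = eta,
       root_ploidy = root_ploidy)
}

#' Sample a random partition of bins into segments
#'
#' A uniform composition: the `n_segments - 1` internal boundaries are a
#' uniform subset of the `n_bins - 1` possible bin boundaries, so every
#' composition with all sizes >= 1 is equally likely.
#'
#' @param n_bins,n_segments see [sim_settings()].
#' @return an `scn_segments` data frame (see [build_segments()]).
#' @export
sample_segments <- function(n_bins, n_segments) {
  stopifnot(n_segments <= n_bins)
  b <- if (n_segments > 1L) sort(sample.int(n_bins - 1L, n_segments - 1L)) else integer(0)
  build_segments(b, n_bins)
}

#' Sample a random valid CNA tree
#'
#' Tree structure: node `i`'s parent is uniform over the root and all earlier
#' nodes (a uniform increasing-labelled rooted tree). Events: each node
#' touches `1 + Poisson(lambda_s)` distinct segments chosen uniformly, with
#' magnitude `1 + Poisson(lambda_c)` and uniform sign per segment. Trees
#' violating the biological constraints are rejected and fully resampled.
#'
#' @param settings a [sim_settings()].
#' @param max_tries rejection-sampling cap.
#' @return a valid [cna_tree()].
#' @export
sample_tree <- function(settings = sim_settings(), max_tries = 10000L) {
  K <- settings$n_segments
  n <- settings$n_nodes
  rootp <- if (length(settings$root_ploidy) == 1L)
    rep(as.integer(settings$root_ploidy), K) else as.integer(settings$root_ploidy)
  for (try in seq_len(max_tries)) {
    parents <- if (n > 0L) vapply(seq_len(n), function(i) sample.int(i, 1L) - 1L,
                                  integer(1)) else integer(0)
    ev <- matrix(0L, nrow = n, ncol = K)
    for (i in seq_len(n)) {
      k <- 1L + stats::rpois(1L, settings$lambda_s)
      while (k > K) k <- 1L + stats::rpois(1L, settings$lambda_s)
      segs <- sample.int(K, k)
      mag <- 1L + stats::rpois(k, settings$lambda_c)
      sgn <- ifelse(stats::runif(k) < 0.5, 1L, -1L)
      ev[i, segs] <- mag * sgn
    }
    tr <- cna_tree(parents, ev, root_ploidy = rootp)
    if (validate_tree(tr)$valid) return(tr)
  }
  stop("failed to sample a valid tree in ", max_tries, " tries")
}

#' Attach cells uniformly and derive their true bin profiles
#'
#' @param tree a valid [cna_tree()].
#' @param segments an `scn_segments` partition of the bins.
#' @param n_cells number of cells.
#' @return list with `sigma` (uniform attachments in `0..n`) and `profiles`
#'   (`m x n_bins` integer copy numbers, the node genotypes expanded over
#'   bins).
#' @export
attach_and_profile <- function(tree, segments, n_cells) {
  sigma <- sample.int(tree$n + 1L, n_cells, replace = TRUE) - 1L
  gen <- compute_genotypes(tree)
  expand <- rep(seq_len(nrow(segments)), segments$size)
  profiles <- gen[sigma + 1L, expand, drop = FALSE]
  dimnames(profiles) <- NULL
  list(sigma = sigma, profiles = profiles)
}

#' Sample read counts from true profiles
#'
#' Each cell receives exactly `reads_per_bin * n_bins` reads, allocated over
#' bins by a Dirichlet-multinomial: bin probabilities are drawn from a
#' Dirichlet with parameters `nu_sim` times the (eta-floored) per-bin copy
#' number, then counts are multinomial.
#'
#' @param profiles `m x n_bins` integer copy-number matrix.
#' @param settings a [sim_settings()].
#' @return `m x n_bins` integer count matrix.
#' @export
sample_counts <- function(profiles, settings = sim_settings()) {
  m <- nrow(profiles)
  B <- ncol(profiles)
  N <- round(settings$reads_per_bin * B)
  counts <- matrix(0L, nrow = m, ncol = B)
  for (j in seq_len(m)) {
    alpha <- settings$nu_sim * pmax(profiles[j, ], settings$eta)
    g <- stats::rgamma(B, shape = alpha, rate = 1)
    if (sum(g) <= 0) g <- alpha
    counts[j, ] <- as.integer(stats::rmultinom(1L, N, g / sum(g)))
  }
  counts
}

#' Generate a complete simulated dataset with ground truth
#'
#' Composes [sample_segments()], [sample_tree()], [attach_and_profile()] and
#' [sample_counts()]; fully reproducible given the R random seed.
#'
#' @param settings a [sim_settings()].
#' @param seed optional seed set via [set.seed()] before sampling.
#' @return object of class `scn_sim`: list with `tree`, `segments`, `sigma`,
#'   `profiles`, `counts`, and the `settings` used.
#' @export
generate_dataset <- function(settings = sim_settings(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  segments <- sample_segments(settings$n_bins, settings$n_segments)
  tree <- sample_tree(settings)
  ap <- attach_and_profile(tree, segments, settings$n_cells)
  counts <- sample_counts(ap$profiles, settings)
  structure(list(tree = tree, segments = segments, sigma = ap$sigma,
                 profiles = ap$profiles, counts = counts,
                 settings = settings),
            class = "scn_sim")
}

#' @export
print.scn_sim <- function(x, ...) {
  cat("simulated dataset: ", nrow(x$counts), " cells x ", ncol(x$counts),
      " bins; tree with ", x$tree$n, " nodes over ",
      nrow(x$segments), " segments; ",
      x$settings$reads_per_bin, " reads/bin, nu = ", x$settings$nu_sim,
      "\n", sep = "")
  invisible(x)
}
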