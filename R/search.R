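# Staged maximal search: cluster cells for a cheap first pass, infer a
# cluster-level tree with multiple chains and robustness checks, then refine
# on the full data starting from the cluster tree.

#' Cluster cells by their read-count profiles
#'
#' Ward hierarchical clustering on mean-normalized profiles, with the number
#' of clusters chosen by the Calinski-Harabasz index over `2..k_max`
#' (one cluster when all profiles coincide). The clustering backend is
#' pluggable: any integer labelling can be passed downstream.
#'
#' @param counts `m x B` (or `m x K`) count matrix.
#' @param k_max largest number of clusters considered.
#' @return integer vector of cluster labels `1..C`.
#' @export
cluster_cells <- function(counts, k_max = 15L) {
  x <- as.matrix(counts)
  rm <- rowMeans(x)
  rm[rm == 0] <- 1
  x <- x / rm
  m <- nrow(x)
  if (m == 1L) return(1L)
  d <- stats::dist(x)
  if (max(d) == 0) return(rep(1L, m))
  hc <- stats::hclust(d, method = "ward.D2")
  ks <- 2:min(k_max, m - 1L)
  ch <- vapply(ks, function(k) .calinski_harabasz(x, stats::cutree(hc, k)),
               numeric(1))
  k <- ks[which.max(ch)]
  stats::cutree(hc, k)
}

.calinski_harabasz <- function(x, labels) {
  m <- nrow(x)
  k <- length(unique(labels))
  if (k < 2L || k >= m) return(-Inf)
  centre <- colMeans(x)
  ssb <- 0
  ssw <- 0
  for (g in unique(labels)) {
    xi <- x[labels == g, , drop = FALSE]
    mu <- colMeans(xi)
    ssb <- ssb + nrow(xi) * sum((mu - centre)^2)
    ssw <- ssw + sum(sweep(xi, 2L, mu)^2)
  }
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (m - k))
}

#' Average counts per cluster with weights
#'
#' @param counts `m x K` matrix.
#' @param labels cluster labels of length `m`.
#' @return list with `matrix` (one averaged row per cluster, in label order)
#'   and `weights` (cluster sizes; weighted log-likelihoods multiply each
#'   cluster row's contribution by its size).
#' @export
cluster_matrix <- function(counts, labels) {
  counts <- as.matrix(counts)
  stopifnot(length(labels) == nrow(counts))
  gs <- sort(unique(labels))
  avg <- t(vapply(gs, function(g) colMeans(counts[labels == g, , drop = FALSE]),
                  numeric(ncol(counts))))
  list(matrix = avg, weights = as.numeric(table(factor(labels, levels = gs))))
}

#' Initial tree from rounded profiles
#'
#' Builds a starting tree for the search: Ward's dendrogram over integer
#' segment profiles, internal-node genotypes filled by unanimity among
#' descendant leaves (falling back to the parent's value where leaves
#' disagree), events taken as genotype differences along edges, zero-change
#' nodes pruned, and duplicate genotypes merged so the result always passes
#' [validate_tree()].
#'
#' @param profiles `C x K` matrix of non-negative integer copy-number states
#'   (e.g. normalized cluster counts rounded to integers).
#' @param root_ploidy per-segment root states (scalar recycled).
#' @return a valid [cna_tree()]; root-only if nothing distinguishes the
#'   profiles.
#' @export
initial_tree <- function(profiles, root_ploidy = 2L) {
  profiles <- as.matrix(profiles)
  mode(profiles) <- "integer"
  K <- ncol(profiles)
  if (length(root_ploidy) == 1L) root_ploidy <- rep(as.integer(root_ploidy), K)
  genos <- list()   # genotype per created dendrogram vertex
  parent <- list()  # parent genotype index (0 = root)

  add_vertex <- function(geno, parent_idx) {
    genos[[length(genos) + 1L]] <<- geno
    parent[[length(parent) + 1L]] <<- parent_idx
    length(genos)
  }

  C <- nrow(profiles)
  if (C == 1L) {
    if (!all(profiles[1L, ] == root_ploidy)) add_vertex(profiles[1L, ], 0L)
  } else {
    hc <- stats::hclust(stats::dist(profiles), method = "ward.D2")
    # descend the dendrogram; each merge vertex gets the unanimous value per
    # segment, else its parent's value
    leaves_under <- function(v) {
      if (v < 0L) return(-v)
      c(leaves_under(hc$merge[v, 1L]), leaves_under(hc$merge[v, 2L]))
    }
    assign_vertex <- function(v, parent_geno, parent_idx) {
      if (v < 0L) {
        geno <- profiles[-v, ]
      } else {
        lv <- leaves_under(v)
        sub <- profiles[lv, , drop = FALSE]
        unan <- apply(sub, 2L, function(col) if (all(col == col[1L])) col[1L] else NA_integer_)
        geno <- ifelse(is.na(unan), parent_geno, unan)
      }
      idx <- parent_idx
      if (!all(geno == parent_geno)) idx <- add_vertex(geno, parent_idx)
      if (v > 0L) {
        assign_vertex(hc$merge[v, 1L], geno, idx)
        assign_vertex(hc$merge[v, 2L], geno, idx)
      }
    }
    assign_vertex(nrow(hc$merge), root_ploidy, 0L)
  }

  if (!length(genos))
    return(cna_tree(integer(0), matrix(0L, 0L, K), root_ploidy = root_ploidy))

  # merge duplicate genotypes (keep the first; re-parent children)
  keymap <- new.env()
  remap <- integer(length(genos))
  keep <- logical(length(genos))
  rootkey <- paste(root_ploidy, collapse = ",")
  assign(rootkey, 0L, envir = keymap)
  for (i in seq_along(genos)) {
    key <- paste(genos[[i]], collapse = ",")
    if (exists(key, envir = keymap, inherits = FALSE)) {
      remap[i] <- get(key, envir = keymap)
    } else {
      keep[i] <- TRUE
      remap[i] <- i
      assign(key, i, envir = keymap)
    }
  }
  resolve <- function(i) {
    while (i != 0L && !keep[i]) i <- remap[[i]]
    i
  }
  kept <- which(keep)
  newlab <- integer(length(genos))
  newlab[kept] <- seq_along(kept)
  parents <- integer(length(kept))
  ev <- matrix(0L, nrow = length(kept), ncol = K)
  for (j in seq_along(kept)) {
    i <- kept[j]
    p <- parent[[i]]
    p <- if (p == 0L) 0L else resolve(p)
    parents[j] <- if (p == 0L) 0L else newlab[p]
    pg <- if (p == 0L) root_ploidy else genos[[p]]
    ev[j, ] <- genos[[i]] - pg
  }
  tr <- cna_tree(parents, ev, root_ploidy = root_ploidy)
  # rounding can still produce negative or regained states; drop offenders
  tries <- 0L
  while (!validate_tree(tr)$valid && tries < 50L) {
    tr <- .drop_one_invalid(tr)
    tries <- tries + 1L
  }
  if (!validate_tree(tr)$valid)
    tr <- cna_tree(integer(0), matrix(0L, 0L, K), root_ploidy = root_ploidy)
  tr
}

# remove the first node implicated in a validity violation, re-parenting its
# children and absorbing its event into them
.drop_one_invalid <- function(tree) {
  gen <- compute_genotypes(tree)
  bad <- which(apply(gen, 1L, function(r) any(r < 0L)))[1L]
  if (is.na(bad)) {
    dup <- which(duplicated(gen))[1L]
    bad <- if (!is.na(dup)) dup else 2L
  }
  drop <- max(bad - 1L, 1L)  # node label to remove
  n <- tree$n
  keep <- setdiff(seq_len(n), drop)
  newlab <- integer(n)
  newlab[keep] <- seq_along(keep)
  parents <- integer(length(keep))
  ev <- matrix(0L, nrow = length(keep), ncol = ncol(tree$events))
  for (j in seq_along(keep)) {
    i <- keep[j]
    p <- tree$parents[i]
    addev <- tree$events[i, ]
    while (p == drop) {
      addev <- addev + tree$events[p, ]
      p <- tree$parents[p]
    }
    parents[j] <- if (p == 0L) 0L else newlab[p]
    ev[j, ] <- addev
  }
  empty <- which(apply(ev, 1L, function(r) all(r == 0L)))
  tr <- cna_tree(parents, ev, root_ploidy = tree$root_ploidy)
  for (e in rev(empty)) tr <- .remove_node(tr, e)
  tr
}

.remove_node <- function(tree, i) {
  n <- tree$n
  keep <- setdiff(seq_len(n), i)
  newlab <- integer(n)
  newlab[keep] <- seq_along(keep)
  parents <- integer(length(keep))
  for (j in seq_along(keep)) {
    p <- tree$parents[keep[j]]
    if (p == i) p <- tree$parents[i]
    parents[j] <- if (p == 0L) 0L else newlab[p]
  }
  cna_tree(parents, tree$events[keep, , drop = FALSE],
           root_ploidy = tree$root_ploidy)
}

#' Search configuration
#'
#' @param n_chains chains per robustness round (default 10).
#' @param chain_length_factor iterations per event node of the starting tree
#'   (default 4000; at least `min_chain_length` in total).
#' @param min_chain_length chain-length floor.
#' @param score_window robustness window: at least half the chains must score
#'   within this many log units of the best (default 5).
#' @param distance_threshold full-data robustness alternative: mean pairwise
#'   tree distance of the best half below this value (default 0.02).
#' @param max_rounds robustness rounds per stage before giving up.
#' @param k_max largest cluster count considered.
#' @param nu_learn_iterations fixed-tree iterations used to learn `nu` on the
#'   full data before the full-data tree search.
#' @return list of validated settings.
#' @export
search_config <- function(n_chains = 10L, chain_length_factor = 4000L,
                          min_chain_length = 1000L, score_window = 5,
                          distance_threshold = 0.02, max_rounds = 3L,
                          k_max = 15L, nu_learn_iterations = 2000L) {
  stopifnot(n_chains >= 1, chain_length_factor >= 1, score_window > 0,
            distance_threshold > 0, max_rounds >= 1)
  list(n_chains = as.integer(n_chains),
       chain_length_factor = as.integer(chain_length_factor),
       min_chain_length = as.integer(min_chain_length),
       score_window = score_window, distance_threshold = distance_threshold,
       max_rounds = as.integer(max_rounds), k_max = as.integer(k_max),
       nu_learn_iterations = as.integer(nu_learn_iterations))
}

# run one robustness round: n_chains chains from `tree`, returning per-chain
# results sorted as given
.run_round <- function(tree, D, sizes, nu, config, params, prior, moves,
                       score, weights) {
  len <- max(config$min_chain_length,
             config$chain_length_factor * max(tree$n, 1L))
  lapply(seq_len(config$n_chains), function(i) {
    run_chain(tree, D, sizes, iterations = len, nu = nu, params = params,
              prior = prior, moves = moves, score = score, weights = weights)
  })
}

.best_half_window <- function(scores, window) {
  keep <- ceiling(length(scores) / 2)
  sorted <- sort(scores, decreasing = TRUE)
  (sorted[1L] - sorted[keep]) <= window
}

#' Staged robust tree inference
#'
#' Stage 1 clusters the cells, averages their segment counts (weighted by
#' cluster size) and searches for a cluster-level tree with `n_chains` chains,
#' repeating from the best tree so far until at least half the chains agree
#' within `score_window` log units. Stage 2 first learns the overdispersion
#' on the full data with the cluster tree fixed, then refines the tree on the
#' full data, stopping when either the score window or the mean pairwise
#' tree-distance criterion among the best half of chains is met.
#'
#' @param D `m x K` segment count matrix.
#' @param sizes segment sizes in bins.
#' @param config a [search_config()].
#' @param params a [likelihood_params()] (its `nu` seeds the overdispersion).
#' @param prior a [prior_params()].
#' @param moves a [move_config()].
#' @param score `"max"` or `"sum"`.
#' @param root_ploidy per-segment root states (scalar recycled).
#' @return list with `tree`, `nu`, `score`, `table`, `sigma`, and
#'   `diagnostics` (per-stage chain scores, robustness flags, rounds used,
#'   convergence summary).
#' @export
robust_infer <- function(D, sizes, config = search_config(),
                         params = likelihood_params(), prior = prior_params(),
                         moves = move_config(), score = c("max", "sum"),
                         root_ploidy = 2L) {
  score <- match.arg(score)
  D <- as.matrix(D)
  K <- ncol(D)
  if (length(root_ploidy) == 1L) root_ploidy <- rep(as.integer(root_ploidy), K)
  diag_out <- list()

  # ---- stage 1: clustered data ----
  labels <- cluster_cells(D, k_max = config$k_max)
  cm <- cluster_matrix(D, labels)
  mean_ploidy <- mean(root_ploidy)
  rates <- sweep(cm$matrix, 2L, as.numeric(sizes), "/")
  # per-copy rate from the size-weighted mean, assuming the average state is
  # near the root ploidy
  per_copy <- rowSums(cm$matrix) / (mean_ploidy * sum(sizes))
  profiles <- round(rates / per_copy)
  profiles[profiles < 0] <- 0L
  tree <- initial_tree(profiles, root_ploidy = root_ploidy)

  # bound the tree-size random walk: under the maximized score the sampling
  # target is near-flat in n once the data are explained, so without a bound
  # chains waste most of their time in oversized trees
  stage_moves <- moves
  stage_moves$n_max <- min(moves$n_max, max(30L, 3L * max(tree$n, 1L) + 10L))

  nu <- params$nu
  best <- NULL
  for (round in seq_len(config$max_rounds)) {
    chains <- .run_round(tree, cm$matrix, sizes, nu, config, params, prior,
                         stage_moves, score, cm$weights)
    scores <- vapply(chains, function(ch) ch$best_score, numeric(1))
    top <- which.max(scores)
    if (is.null(best) || scores[top] > best$best_score) best <- chains[[top]]
    diag_out$stage1_scores <- c(diag_out$stage1_scores, list(scores))
    robust <- .best_half_window(scores, config$score_window)
    tree <- best$best_tree
    nu <- best$best_nu
    if (robust) break
  }
  diag_out$stage1_rounds <- length(diag_out$stage1_scores)
  diag_out$stage1_robust <- robust
  cluster_tree <- best$best_tree

  # ---- stage 2: full data ----
  # learn nu with the cluster tree fixed (only the nu walk enabled)
  nu_moves <- move_config(prune_reattach = 0, label_swap = 0, event_change = 0,
                          add_remove_node = 0, condense_split = 0,
                          genotype_preserving = 0, nu_walk = 1,
                          nu_sd = moves$nu_sd, nu_bounds = moves$nu_bounds)
  if (!params$use_multinomial && config$nu_learn_iterations > 0) {
    nu_chain <- run_chain(cluster_tree, D, sizes,
                          iterations = config$nu_learn_iterations, nu = nu,
                          params = params, prior = prior, moves = nu_moves,
                          score = score)
    nu <- nu_chain$best_nu
  }
  diag_out$nu_learned <- nu

  tree <- cluster_tree
  stage_moves$n_max <- min(moves$n_max, max(30L, 3L * max(tree$n, 1L) + 10L))
  best <- NULL
  for (round in seq_len(config$max_rounds)) {
    chains <- .run_round(tree, D, sizes, nu, config, params, prior,
                         stage_moves, score, weights = NULL)
    scores <- vapply(chains, function(ch) ch$best_score, numeric(1))
    top <- which.max(scores)
    if (is.null(best) || scores[top] > best$best_score) best <- chains[[top]]
    diag_out$stage2_scores <- c(diag_out$stage2_scores, list(scores))
    robust <- .best_half_window(scores, config$score_window)
    mean_tau <- NA_real_
    if (!robust) {
      segs <- build_segments(cumsum(sizes)[-length(sizes)], sum(sizes))
      keep <- order(scores, decreasing = TRUE)[seq_len(ceiling(length(scores) / 2))]
      annots <- lapply(keep, function(i) {
        ch <- chains[[i]]
        tb <- attachment_table(ch$best_tree, D, sizes,
                               likelihood_params(nu = ch$best_nu,
                                                 eta = params$eta,
                                                 use_multinomial = params$use_multinomial))
        annotated_tree(ch$best_tree, segs, best_attachments(tb))
      })
      conv <- convergence_summary(scores[keep], annots)
      mean_tau <- conv$mean_pairwise_tau
      robust <- mean_tau < config$distance_threshold
    }
    diag_out$stage2_tau <- c(diag_out$stage2_tau, mean_tau)
    tree <- best$best_tree
    nu <- best$best_nu
    if (robust) break
  }
  diag_out$stage2_rounds <- length(diag_out$stage2_scores)
  diag_out$stage2_robust <- robust

  final_params <- likelihood_params(nu = best$best_nu, eta = params$eta,
                                    use_multinomial = params$use_multinomial)
  table <- attachment_table(best$best_tree, D, sizes, final_params)
  list(tree = best$best_tree, nu = best$best_nu, score = best$best_score,
       score_mode = score, table = table, sigma = best_attachments(table),
       cluster_labels = labels, cluster_tree = cluster_tree,
       diagnostics = diag_out)
}

#' Expand attached genotypes to per-cell, per-bin copy numbers
#'
#' @param tree a valid [cna_tree()].
#' @param sigma per-cell attachment labels in `0..n`.
#' @param segments an `scn_segments` partition of the bins.
#' @return `m x n_bins` integer matrix; every row is a genotype of the tree
#'   expanded over its segments.
#' @export
call_copy_numbers <- function(tree, sigma, segments) {
  gen <- compute_genotypes(tree)
  expand <- rep(seq_len(nrow(segments)), segments$size)
  out <- gen[sigma + 1L, expand, drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Compare alternative root ploidies
#'
#' Runs the full staged inference once per candidate root state (e.g. diploid
#' versus tetraploid, the latter modelling a whole-genome duplication) and
#' reports the best scores side by side. No automatic decision is made; large
#' score differences indicate which baseline the data supports.
#'
#' @param D `m x K` segment count matrix.
#' @param sizes segment sizes in bins.
#' @param ploidies list (or vector) of root-ploidy settings to compare.
#' @param ... passed to [robust_infer()].
#' @return list with `fits` (one [robust_infer()] result per ploidy) and
#'   `scores` (named vector of best scores).
#' @export
compare_root_ploidies <- function(D, sizes, ploidies = list(2L, 4L), ...) {
  if (!is.list(ploidies)) ploidies <- as.list(ploidies)
  fits <- lapply(ploidies, function(p) robust_infer(D, sizes, root_ploidy = p, ...))
  scores <- vapply(fits, function(f) f$score, numeric(1))
  names(scores) <- vapply(ploidies, function(p) paste(p, collapse = ","), character(1))
  list(fits = fits, scores = scores)
}
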