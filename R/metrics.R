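# Evaluation metrics: copy-number RMSE (delta), the event-path tree distance
# (tau) between annotated trees, and multi-chain convergence summaries.

#' Root-mean-square copy-number error
#'
#' RMSE over all cells and bins between two integer copy-number matrices.
#'
#' @param true_profiles,inferred_profiles equally sized `m x B` matrices.
#' @return non-negative scalar.
#' @export
delta_rmse <- function(true_profiles, inferred_profiles) {
  stopifnot(all(dim(true_profiles) == dim(inferred_profiles)))
  sqrt(mean((as.numeric(true_profiles) - as.numeric(inferred_profiles))^2))
}

#' Annotate a tree with cell attachments for distance computations
#'
#' @param tree a valid [cna_tree()].
#' @param segments an `scn_segments` partition of the bins.
#' @param sigma per-cell attachment labels in `0..n`.
#' @return object of class `scn_annotated`.
#' @export
annotated_tree <- function(tree, segments, sigma) {
  stopifnot(inherits(tree, "cna_tree"), all(sigma >= 0), all(sigma <= tree$n))
  structure(list(tree = tree, segments = segments, sigma = as.integer(sigma)),
            class = "scn_annotated")
}

# per-edge path weight: total absolute per-bin state change of the node's
# event, i.e. sum over segments of |delta| * segment size
.edge_weights <- function(tree, segments) {
  if (tree$n == 0L) return(numeric(0))
  as.numeric(abs(tree$events) %*% segments$size)
}

# (n+1) x (n+1) matrix of path weights between all node pairs
.node_distances <- function(tree, segments) {
  n <- tree$n
  w <- .edge_weights(tree, segments)
  depthcost <- numeric(n + 1L)     # path weight from each node up to the root
  anc <- vector("list", n + 1L)    # ancestor label sequence, node first, root last
  anc[[1L]] <- 0L
  for (u in .topo_order(tree)) {
    p <- tree$parents[u]
    depthcost[u + 1L] <- depthcost[p + 1L] + w[u]
    anc[[u + 1L]] <- c(u, anc[[p + 1L]])
  }
  d <- matrix(0, n + 1L, n + 1L)
  for (i in 0:n) {
    for (j in 0:n) {
      if (j <= i) next
      common <- intersect(anc[[i + 1L]], anc[[j + 1L]])
      mrca <- common[1L]           # ancestor lists are ordered towards the root
      d[i + 1L, j + 1L] <- d[j + 1L, i + 1L] <-
        depthcost[i + 1L] + depthcost[j + 1L] - 2 * depthcost[mrca + 1L]
    }
  }
  d
}

#' Event-path distance between two cells on an annotated tree
#'
#' Counts, per bin, the absolute copy-number change accumulated along the
#' shortest path through the most recent common ancestor of the cells'
#' attachment nodes, summed over bins and normalized by the expected size of
#' a single event (`n_bins / n_segments`), so distances count "typical"
#' events.
#'
#' @param annot an [annotated_tree()].
#' @param i,j cell indices (1-based).
#' @return non-negative scalar.
#' @export
cell_pair_distance <- function(annot, i, j) {
  stopifnot(inherits(annot, "scn_annotated"))
  nd <- .node_distances(annot$tree, annot$segments)
  ns <- nrow(annot$segments)
  nb <- sum(annot$segments$size)
  (ns / nb) * nd[annot$sigma[i] + 1L, annot$sigma[j] + 1L]
}

#' Full cell-by-cell distance matrix of an annotated tree
#'
#' @param annot an [annotated_tree()].
#' @return symmetric `m x m` matrix of normalized event-path distances.
#' @export
cell_distance_matrix <- function(annot) {
  stopifnot(inherits(annot, "scn_annotated"))
  nd <- .node_distances(annot$tree, annot$segments)
  ns <- nrow(annot$segments)
  nb <- sum(annot$segments$size)
  (ns / nb) * nd[annot$sigma + 1L, annot$sigma + 1L, drop = FALSE]
}

#' Tree distance between two annotated trees
#'
#' Root-mean-square difference between the upper-triangular cell-pair
#' distance matrices of the two trees:
#' `tau = sqrt( 2/(m(m-1)) * sum_{i<j} (d_ij - d'_ij)^2 )`.
#' When the trees use different bin partitions, both distance matrices are
#' computed on their own segment maps over the common bin grid.
#'
#' Both matrices are normalized by the first (reference) tree's expected
#' event size so they are compared in the same units even when the inferred
#' segmentation differs from the true one.
#'
#' @param annot_true,annot_inferred [annotated_tree()] objects over the same
#'   cells.
#' @return non-negative scalar.
#' @export
tree_distance <- function(annot_true, annot_inferred) {
  unit <- nrow(annot_true$segments) / sum(annot_true$segments$size)
  raw <- function(annot) {
    nd <- .node_distances(annot$tree, annot$segments)
    nd[annot$sigma + 1L, annot$sigma + 1L, drop = FALSE]
  }
  d1 <- unit * raw(annot_true)
  d2 <- unit * raw(annot_inferred)
  m <- nrow(d1)
  if (nrow(d2) != m) stop("annotated trees cover different numbers of cells")
  ut <- upper.tri(d1)
  sqrt(sum((d1[ut] - d2[ut])^2) * 2 / (m * (m - 1)))
}

#' Convergence summary across chains
#'
#' Retains the best-scoring half of the chains and reports the mean pairwise
#' tree distance among their best trees and the mean log-score gap to the
#' overall best.
#'
#' @param scores numeric vector of per-chain best scores.
#' @param annots list of [annotated_tree()] objects, one per chain (best tree
#'   with its best attachments).
#' @return list with `mean_pairwise_tau`, `mean_score_gap`, `kept` (indices
#'   of the retained chains).
#' @export
convergence_summary <- function(scores, annots) {
  stopifnot(length(scores) == length(annots))
  keep <- order(scores, decreasing = TRUE)[seq_len(ceiling(length(scores) / 2))]
  taus <- c()
  if (length(keep) >= 2L) {
    for (a in seq_along(keep)) {
      for (b in seq_along(keep)) {
        if (b <= a) next
        taus <- c(taus, tree_distance(annots[[keep[a]]], annots[[keep[b]]]))
      }
    }
  } else taus <- 0
  list(mean_pairwise_tau = mean(taus),
       mean_score_gap = mean(max(scores[keep]) - scores[keep]),
       kept = keep)
}
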