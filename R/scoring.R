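# Tree-level scores: event-vector prior, tree-size penalty, and the marginal
# ("sum") and maximized ("max") posteriors over cell attachments.

#' Prior and penalty parameters
#'
#' The event-vector prior factorizes over nodes and mirrors the generative
#' process of the simulator: the number of segments touched by an event is
#' 1 + Poisson(`lambda_s`), each magnitude is 1 + Poisson(`lambda_c`), and the
#' sign is uniform. The tree-size penalty `exp(-kappa * n)` guards against the
#' combinatorial growth of larger trees in the marginal score.
#'
#' @param lambda_s Poisson offset for segments per event (default 0.1).
#' @param lambda_c Poisson offset for copies per segment (default 0.2).
#' @param kappa tree-size penalty rate (default 1).
#' @return list of validated parameters.
#' @export
prior_params <- function(lambda_s = 0.1, lambda_c = 0.2, kappa = 1) {
  stopifnot(lambda_s >= 0, lambda_c >= 0, kappa >= 0)
  list(lambda_s = lambda_s, lambda_c = lambda_c, kappa = kappa)
}

#' Log prior of the event vector
#'
#' The prior on each node's event is exactly the generative event
#' distribution of the simulator: sum over nodes of
#' `log Pois(k_i - 1; lambda_s) - log C(K, k_i) + sum_seg [log Pois(|d| - 1; lambda_c) + log 1/2]`
#' where `k_i` is the number of segments touched by node `i`'s event and the
#' binomial term reflects the uniform choice of which `k_i` of the `K`
#' segments are hit. The subset factor makes the prior a normalized
#' distribution over events; without it the posterior accumulates mass on
#' ever-larger trees simply because more distinct event vectors exist.
#'
#' @param tree a [cna_tree()].
#' @param params a [prior_params()].
#' @return log prior (0 for the empty tree).
#' @export
event_vector_log_prior <- function(tree, params = prior_params()) {
  stopifnot(inherits(tree, "cna_tree"))
  K <- ncol(tree$events)
  lp <- 0
  for (i in seq_len(tree$n)) {
    d <- tree$events[i, ]
    nz <- d[d != 0L]
    if (!length(nz)) return(-Inf)
    lp <- lp + stats::dpois(length(nz) - 1L, params$lambda_s, log = TRUE) -
      lchoose(K, length(nz)) +
      sum(stats::dpois(abs(nz) - 1L, params$lambda_c, log = TRUE) + log(0.5))
  }
  lp
}

#' Log tree-size penalty
#'
#' @param n number of event nodes.
#' @param params a [prior_params()].
#' @return `-kappa * n`.
#' @export
tree_log_penalty <- function(n, params = prior_params()) {
  stopifnot(n >= 0)
  -params$kappa * n
}

.attach_term <- function(table, weights, mode) {
  rel <- table$loglik
  per_cell <- if (mode == "max") {
    apply(rel, 1L, max)
  } else {
    apply(rel, 1L, function(r) {
      mx <- max(r)
      mx + log(sum(exp(r - mx)))
    })
  }
  sum(weights * (table$root_loglik + per_cell))
}

.score_breakdown <- function(tree, table, params, weights, mode) {
  stopifnot(inherits(table, "scn_attachment"))
  m <- nrow(table$loglik)
  if (ncol(table$loglik) != tree$n + 1L)
    stop("attachment table does not match the tree")
  if (is.null(weights)) weights <- rep(1, m)
  v <- validate_tree(tree)
  n <- tree$n
  M <- sum(weights)
  if (!v$valid) {
    return(structure(list(log_event_prior = -Inf, log_tree_penalty = -Inf,
                          log_attachment_term = -Inf, total = -Inf,
                          mode = mode, valid = FALSE, reason = v$reason),
                     class = "scn_score"))
  }
  lep <- event_vector_log_prior(tree, params)
  if (mode == "max") {
    pen <- 0                                     # no combinatorial correction needed
    attach <- -(n - 1) * log(n + 1) + .attach_term(table, weights, "max")
  } else {
    pen <- tree_log_penalty(n, params)
    attach <- -(n - 1 + M) * log(n + 1) + .attach_term(table, weights, "sum")
  }
  structure(list(log_event_prior = lep, log_tree_penalty = pen,
                 log_attachment_term = attach, total = lep + pen + attach,
                 mode = mode, valid = TRUE, reason = NA_character_),
            class = "scn_score")
}

#' Marginal ("sum") log posterior score of a tree
#'
#' Averages each cell over all `n + 1` attachment points:
#' `log P(V|T) - kappa n - (n - 1 + m) log(n + 1) + sum_j [root_j + logsumexp_s rel_js]`.
#' Trees violating the validity constraints score `-Inf`.
#'
#' @param tree a [cna_tree()].
#' @param table an [attachment_table()] computed for this tree.
#' @param params a [prior_params()].
#' @param weights optional per-cell weights (cluster sizes); default 1.
#' @return object of class `scn_score`: the breakdown
#'   (`log_event_prior`, `log_tree_penalty`, `log_attachment_term`, `total`).
#' @export
sum_log_score <- function(tree, table, params = prior_params(), weights = NULL) {
  .score_breakdown(tree, table, params, weights, "sum")
}

#' Maximized ("max") log score of a tree
#'
#' Places each cell at its best attachment:
#' `log P(V|T) - (n - 1) log(n + 1) + sum_j [root_j + max_s rel_js]`.
#' No tree-size penalty is applied: maximization removes the combinatorial
#' effect the penalty corrects for.
#'
#' @inheritParams sum_log_score
#' @return an `scn_score` object.
#' @export
max_log_score <- function(tree, table, params = prior_params(), weights = NULL) {
  .score_breakdown(tree, table, params, weights, "max")
}

#' @export
print.scn_score <- function(x, ...) {
  cat("tree score (", x$mode, " mode): total = ", format(x$total), "\n", sep = "")
  if (!x$valid) cat("  invalid tree: ", x$reason, "\n", sep = "")
  else
    cat("  event prior ", format(x$log_event_prior),
        ", penalty ", format(x$log_tree_penalty),
        ", attachment ", format(x$log_attachment_term), "\n", sep = "")
  invisible(x)
}

#' Best attachment of each cell
#'
#' Per-cell argmax over attachment nodes, root included; ties break toward the
#' lowest node label (root first).
#'
#' @param table an [attachment_table()].
#' @return integer vector of node labels in `0..n`, one per cell.
#' @export
best_attachments <- function(table) {
  stopifnot(inherits(table, "scn_attachment"))
  apply(table$loglik, 1L, which.max) - 1L
}
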