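# Metropolis-Hastings sampler over (tree, events, nu).
#
# Seven move types: six structural moves (prune & reattach, label swap,
# add/remove events, add/remove node, condense/split, genotype-preserving
# prune & reattach) plus a random walk on log(nu). Proposals producing
# invalid trees are rejected outright. Node-adding moves insert the new node
# at a uniformly chosen label so the chain is reversible on labelled trees.

#' MCMC move configuration
#'
#' All structural moves have weight 1 except the genotype-preserving prune and
#' reattach, which is down-weighted to 0.4 because it rescoring its whole
#' neighbourhood makes it comparatively expensive; the overdispersion walk is
#' an additional move of weight 1.
#'
#' @param prune_reattach,label_swap,event_change,add_remove_node,condense_split,genotype_preserving,nu_walk
#'   non-negative move weights.
#' @param nu_sd random-walk step in log-`nu` space (default 0.1).
#' @param nu_bounds allowed range for `nu`.
#' @param n_min,n_max bounds on the number of event nodes; proposals leaving
#'   the range are rejected.
#' @param max_abs_delta cap on per-segment event magnitude (proposals beyond
#'   it are rejected); `Inf` by default.
#' @return list of validated settings.
#' @export
move_config <- function(prune_reattach = 1, label_swap = 1, event_change = 1,
                        add_remove_node = 1, condense_split = 1,
                        genotype_preserving = 0.4, nu_walk = 1,
                        nu_sd = 0.1, nu_bounds = c(1e-2, 1e6),
                        n_min = 0L, n_max = 500L, max_abs_delta = Inf) {
  w <- c(prune_reattach, label_swap, event_change, add_remove_node,
         condense_split, genotype_preserving, nu_walk)
  stopifnot(all(w >= 0), any(w > 0), nu_sd >= 0, length(nu_bounds) == 2L,
            n_min >= 0, n_max >= n_min)
  list(weights = w, nu_sd = nu_sd, nu_bounds = nu_bounds,
       n_min = as.integer(n_min), n_max = as.integer(n_max),
       max_abs_delta = if (is.finite(max_abs_delta)) as.integer(max_abs_delta)
                       else .Machine$integer.max)
}

#' Run one MCMC chain over trees, events and overdispersion
#'
#' Samples states proportionally to `exp(score)` where the score is the
#' marginal (`"sum"`) or maximized (`"max"`) log posterior, tracking the best
#' state encountered. Deterministic given the R random seed.
#'
#' @param tree starting [cna_tree()] (must be valid).
#' @param D `m x K` segment count matrix.
#' @param sizes segment sizes in bins.
#' @param iterations chain length.
#' @param nu starting overdispersion concentration.
#' @param params a [likelihood_params()]; its `nu` is ignored in favour of the
#'   `nu` argument.
#' @param prior a [prior_params()].
#' @param moves a [move_config()].
#' @param score `"max"` or `"sum"`.
#' @param weights optional per-cell weights (cluster sizes).
#' @param track_states record per-state visit counts (for small spaces only);
#'   keys serialize the parent vector and dense event matrix.
#' @return object of class `scn_chain`: best/final states (as [cna_tree()]),
#'   scores, `nu` values, acceptance counts per move, and the improvement log.
#' @export
run_chain <- function(tree, D, sizes, iterations, nu = 1,
                      params = likelihood_params(), prior = prior_params(),
                      moves = move_config(), score = c("max", "sum"),
                      weights = NULL, track_states = FALSE) {
  score <- match.arg(score)
  stopifnot(inherits(tree, "cna_tree"), iterations >= 1)
  D <- as.matrix(D)
  if (is.null(weights)) weights <- rep(1, nrow(D))
  res <- run_chain_cpp(tree$parents, tree$events, tree$root_ploidy,
                       D, as.numeric(sizes), as.numeric(weights),
                       nu, params$eta, params$use_multinomial,
                       score == "max", as.integer(iterations),
                       moves$weights, moves$nu_sd,
                       prior$lambda_s, prior$lambda_c, prior$kappa,
                       moves$nu_bounds[1], moves$nu_bounds[2],
                       moves$n_min, moves$n_max, moves$max_abs_delta,
                       isTRUE(track_states))
  mk <- function(st) cna_tree(st$parents, .as_event_matrix(st$events, length(tree$root_ploidy)),
                              root_ploidy = tree$root_ploidy)
  move_names <- c("prune_reattach", "label_swap", "event_change",
                  "add_remove_node", "condense_split", "genotype_preserving",
                  "nu_walk")
  out <- list(best_tree = mk(res$best), best_nu = res$best_nu,
              best_score = res$best_score, best_iteration = res$best_iteration,
              final_tree = mk(res$final), final_nu = res$final_nu,
              final_score = res$final_score,
              proposed = stats::setNames(res$proposed, move_names),
              accepted = stats::setNames(res$accepted, move_names),
              improvements = data.frame(iteration = res$improvement_iter,
                                        score = res$improvement_score),
              iterations = iterations, score_mode = score)
  if (isTRUE(track_states)) out$visits <- res$visits
  structure(out, class = "scn_chain")
}

.as_event_matrix <- function(ev, K) {
  if (is.null(dim(ev)) || nrow(ev) == 0L) return(matrix(0L, nrow = 0L, ncol = K))
  ev
}

#' @export
print.scn_chain <- function(x, ...) {
  cat("MCMC chain (", x$iterations, " iterations, ", x$score_mode,
      " score)\n", sep = "")
  cat("  best score ", format(x$best_score), " at iteration ",
      x$best_iteration, "; best tree has ", x$best_tree$n, " node(s), nu = ",
      format(x$best_nu), "\n", sep = "")
  acc <- ifelse(x$proposed > 0, x$accepted / pmax(x$proposed, 1L), NA)
  cat("  acceptance: ",
      paste(names(x$proposed), sprintf("%.2f", acc), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# canonical visit-count key of a tree, matching the C++ serialization
.state_key <- function(tree) {
  paste0("T", paste0(",", tree$parents, collapse = ""), "|V",
         paste0(vapply(seq_len(tree$n),
                       function(i) paste0(";", paste0(",", tree$events[i, ],
                                                      collapse = "")),
                       character(1)),
                collapse = ""))
}
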