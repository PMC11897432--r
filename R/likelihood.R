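# Dirichlet-multinomial attachment likelihoods and their multinomial limit.
#
# The observation model: reads of cell j fall into segment k with probability
# proportional to the segment's copy-number state times its size in bins.
# Segment counts are Dirichlet-multinomial with concentration nu * Z_j, which
# converges to the multinomial as nu grows. Fully deleted segments keep a
# residual floor eta so mapping artefacts do not zero out the likelihood.

#' Likelihood parameters
#'
#' @param nu Dirichlet-multinomial concentration (inverse overdispersion),
#'   `> 0`.
#' @param eta residual copy-number floor substituted for state 0
#'   (default `1e-4`).
#' @param use_multinomial use the large-`nu` multinomial limit instead of the
#'   Dirichlet-multinomial.
#' @return list of validated parameters.
#' @export
likelihood_params <- function(nu = 1, eta = 1e-4, use_multinomial = FALSE) {
  stopifnot(nu > 0, eta > 0, eta < 1)
  list(nu = nu, eta = eta, use_multinomial = isTRUE(use_multinomial))
}

.floor_eta <- function(genotype_row, eta) pmax(genotype_row, eta)

#' Read probabilities per segment for a genotype
#'
#' `p_k = c_k s_k / Z` with `Z = sum_k c_k s_k`, after flooring zero states at
#' `eta`.
#'
#' @param genotype_row non-negative integer copy-number states, one per
#'   segment.
#' @param sizes segment sizes in bins.
#' @param eta zero-state floor.
#' @return numeric probability vector summing to one, with attribute `"Z"`
#'   holding the normalizer.
#' @export
segment_probabilities <- function(genotype_row, sizes, eta = 1e-4) {
  stopifnot(length(genotype_row) == length(sizes), all(sizes >= 1),
            all(genotype_row >= 0))
  mass <- .floor_eta(genotype_row, eta) * sizes
  Z <- sum(mass)
  structure(mass / Z, Z = Z)
}

#' Dirichlet-multinomial log-likelihood of one cell at one genotype
#'
#' Computes
#' `log G(nu Z) - log G(N + nu Z) + sum_k [log G(D_k + nu c_k s_k) - log G(nu c_k s_k)]`
#' with the eta-floored states `c_k` and `Z = sum c_k s_k`. The multinomial
#' coefficient is omitted: it is constant across attachments and trees and
#' cancels from every comparison the inference makes.
#'
#' @param D_row per-segment read counts for one cell.
#' @param genotype_row copy-number states at the attachment node.
#' @param sizes segment sizes in bins.
#' @param params a [likelihood_params()].
#' @return log-likelihood (numeric scalar).
#' @export
dm_cell_loglik <- function(D_row, genotype_row, sizes, params = likelihood_params()) {
  stopifnot(all(D_row >= 0))
  cf <- .floor_eta(genotype_row, params$eta)
  alpha <- params$nu * cf * sizes
  Z <- sum(cf * sizes)
  N <- sum(D_row)
  # lgamma(x) - lgamma(x + N) = lbeta(N, x) - lgamma(N); the beta form stays
  # accurate for the huge concentrations of the multinomial limit, where the
  # direct difference of lgamma values loses all precision
  out <- if (N > 0) lbeta(N, params$nu * Z) - lgamma(N) else 0
  pos <- D_row > 0
  out + sum(lgamma(D_row[pos]) - lbeta(D_row[pos], alpha[pos]))
}

#' Multinomial log-likelihood of one cell at one genotype
#'
#' The large-`nu` limit: `-N log Z + sum_k D_k log(c_k s_k)`.
#'
#' @inheritParams dm_cell_loglik
#' @param eta zero-state floor.
#' @return log-likelihood (numeric scalar).
#' @export
multinomial_cell_loglik <- function(D_row, genotype_row, sizes, eta = 1e-4) {
  stopifnot(all(D_row >= 0))
  cf <- .floor_eta(genotype_row, eta)
  Z <- sum(cf * sizes)
  -sum(D_row) * log(Z) + sum(D_row * log(cf * sizes))
}

#' Root log-likelihood of each cell
#'
#' The root contribution is shared by all trees on the same data and only
#' changes with `nu`, so it is computed once per `nu` and attachment scores
#' are stored relative to it. In the multinomial limit with constant ploidy
#' the ploidy cancels entirely and the score reduces to
#' `-N log(sum s_k) + sum_k D_k log s_k`.
#'
#' @param D `m x K` matrix (or single row) of segment counts.
#' @param sizes segment sizes in bins.
#' @param root_ploidy per-segment root states (scalar recycled).
#' @param params a [likelihood_params()].
#' @return numeric vector of per-cell log-likelihoods.
#' @export
root_loglik <- function(D, sizes, root_ploidy = 2L, params = likelihood_params()) {
  D <- rbind(D)
  K <- ncol(D)
  if (length(root_ploidy) == 1L) root_ploidy <- rep(root_ploidy, K)
  f <- if (params$use_multinomial) {
    function(row) multinomial_cell_loglik(row, root_ploidy, sizes, params$eta)
  } else {
    function(row) dm_cell_loglik(row, root_ploidy, sizes, params)
  }
  apply(D, 1L, f)
}

#' Attachment log-likelihood table
#'
#' For every cell and every attachment node, the log-likelihood relative to
#' attaching at the root. Computed by a root-to-leaf traversal that updates
#' only the product terms of the segments changed by each node's event (plus
#' the normalizer-dependent Gamma terms in the Dirichlet-multinomial case), so
#' the total cost is O(m * (n + total event size)) rather than O(m * n * K).
#'
#' @param tree a valid [cna_tree()].
#' @param D `m x K` matrix of per-segment counts.
#' @param sizes segment sizes in bins.
#' @param params a [likelihood_params()].
#' @return object of class `scn_attachment`: list with `loglik`
#'   (`m x (n + 1)` matrix, column 1 = root = all zeros) and `root_loglik`
#'   (absolute per-cell log-likelihood at the root).
#' @export
attachment_table <- function(tree, D, sizes, params = likelihood_params()) {
  stopifnot(inherits(tree, "cna_tree"))
  v <- validate_tree(tree)
  if (!v$valid) stop("invalid tree (", v$reason, ")")
  D <- as.matrix(D)
  if (ncol(D) != ncol(tree$events) && tree$n > 0L)
    stop("segment count mismatch between tree and data")
  res <- attachment_table_cpp(tree$parents, tree$events, tree$root_ploidy,
                              D, as.numeric(sizes), params$nu, params$eta,
                              params$use_multinomial)
  colnames(res$loglik) <- as.character(0:tree$n)
  structure(list(loglik = res$loglik, root_loglik = res$root_loglik),
            class = "scn_attachment")
}
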