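# Independent reference implementations used as oracles. These are written
# directly from the model definitions with plain loops and recursion, and
# deliberately share no code with the package internals.

# genotype of a single node by walking up the parent chain
oracle_genotype_node <- function(tree, u) {
  g <- as.numeric(tree$root_ploidy)
  while (u != 0L) {
    g <- g + tree$events[u, ]
    u <- tree$parents[u]
  }
  g
}

oracle_genotypes <- function(tree) {
  t(vapply(0:tree$n, function(u) oracle_genotype_node(tree, u),
           numeric(ncol(tree$events))))
}

# brute-force validity: enumerate every ancestor-descendant segment
# trajectory from the root to each node
oracle_validate <- function(tree) {
  gen <- oracle_genotypes(tree)
  if (any(gen < 0)) return("negative_state")
  for (u in seq_len(tree$n)) {
    # path root -> u as node sequence
    path <- u
    p <- tree$parents[u]
    while (p != 0L) {
      path <- c(p, path)
      p <- tree$parents[p]
    }
    states <- rbind(as.numeric(tree$root_ploidy), gen[path + 1L, , drop = FALSE])
    for (k in seq_len(ncol(states))) {
      traj <- states[, k]
      hit0 <- which(traj == 0)
      if (length(hit0) && any(diff(traj[hit0[1L]:length(traj)]) > 0))
        return("regain_after_zero")
    }
  }
  for (a in 0:(tree$n - 1L)) {
    for (b in (a + 1L):tree$n) {
      if (all(gen[a + 1L, ] == gen[b + 1L, ])) return("duplicate_genotype")
    }
  }
  "valid"
}

# direct Dirichlet-multinomial and multinomial log-likelihoods
oracle_dm <- function(D_row, geno, sizes, nu, eta) {
  cf <- ifelse(geno > 0, geno, eta)
  Z <- sum(cf * sizes)
  N <- sum(D_row)
  tot <- lgamma(nu * Z) - lgamma(N + nu * Z)
  for (k in seq_along(sizes))
    tot <- tot + lgamma(D_row[k] + nu * cf[k] * sizes[k]) -
      lgamma(nu * cf[k] * sizes[k])
  tot
}

oracle_multinomial <- function(D_row, geno, sizes, eta) {
  cf <- ifelse(geno > 0, geno, eta)
  Z <- sum(cf * sizes)
  tot <- -sum(D_row) * log(Z)
  for (k in seq_along(sizes)) tot <- tot + D_row[k] * log(cf[k] * sizes[k])
  tot
}

# attachment table by per-node recomputation over all (cell, node) pairs
oracle_attachment_table <- function(tree, D, sizes, nu, eta, multinomial = FALSE) {
  gen <- oracle_genotypes(tree)
  m <- nrow(D)
  f <- if (multinomial) {
    function(row, g) oracle_multinomial(row, g, sizes, eta)
  } else {
    function(row, g) oracle_dm(row, g, sizes, nu, eta)
  }
  out <- matrix(0, m, tree$n + 1L)
  for (j in seq_len(m)) {
    root <- f(D[j, ], gen[1L, ])
    for (u in 0:tree$n) out[j, u + 1L] <- f(D[j, ], gen[u + 1L, ]) - root
  }
  out
}

# marginal posterior score evaluated directly from its definition
oracle_sum_score <- function(tree, D, sizes, nu, eta, multinomial,
                             lambda_s, lambda_c, kappa) {
  if (oracle_validate(tree) != "valid") return(-Inf)
  K <- ncol(tree$events)
  lp <- 0
  for (i in seq_len(tree$n)) {
    nz <- tree$events[i, tree$events[i, ] != 0L]
    lp <- lp + dpois(length(nz) - 1L, lambda_s, log = TRUE) - lchoose(K, length(nz)) +
      sum(dpois(abs(nz) - 1L, lambda_c, log = TRUE) + log(0.5))
  }
  gen <- oracle_genotypes(tree)
  m <- nrow(D)
  n <- tree$n
  f <- if (multinomial) {
    function(row, g) oracle_multinomial(row, g, sizes, eta)
  } else {
    function(row, g) oracle_dm(row, g, sizes, nu, eta)
  }
  attach <- 0
  for (j in seq_len(m)) {
    ll <- vapply(0:n, function(u) f(D[j, ], gen[u + 1L, ]), numeric(1))
    mx <- max(ll)
    attach <- attach + mx + log(sum(exp(ll - mx)))
  }
  lp - kappa * n - (n - 1 + m) * log(n + 1) + attach
}

# random valid tree for oracle comparisons, built independently of the
# package simulator (uniform earlier-node parents, sparse random deltas)
oracle_random_tree <- function(n, K, root_ploidy = 2L, max_delta = 3L) {
  repeat {
    parents <- if (n > 0) vapply(seq_len(n), function(i) sample.int(i, 1L) - 1L,
                                 integer(1)) else integer(0)
    ev <- matrix(0L, n, K)
    for (i in seq_len(n)) {
      k <- sample.int(min(3L, K), 1L)
      segs <- sample.int(K, k)
      ev[i, segs] <- sample(c(-max_delta:-1, 1:max_delta), k, replace = TRUE)
    }
    tr <- cna_tree(parents, ev, root_ploidy = root_ploidy)
    if (oracle_validate(tr) == "valid") return(tr)
  }
}

# random not-necessarily-valid tree (for validity-agreement tests)
oracle_random_tree_any <- function(n, K, root_ploidy = 2L, max_delta = 3L) {
  parents <- if (n > 0) vapply(seq_len(n), function(i) sample.int(i, 1L) - 1L,
                               integer(1)) else integer(0)
  ev <- matrix(0L, n, K)
  for (i in seq_len(n)) {
    k <- sample.int(min(3L, K), 1L)
    segs <- sample.int(K, k)
    ev[i, segs] <- sample(c(-max_delta:-1, 0L, 1:max_delta), k, replace = TRUE)
  }
  cna_tree(parents, ev, root_ploidy = root_ploidy)
}

# total-variation distance between a named empirical distribution and a
# named reference distribution over the same key space
oracle_tv <- function(emp, ref) {
  full <- setNames(numeric(length(ref)), names(ref))
  stopifnot(all(names(emp) %in% names(ref)))
  full[names(emp)] <- emp
  0.5 * sum(abs(full / sum(full) - ref / sum(ref)))
}

# the worked-example tree: five nodes over five segments, diploid root
fig_tree <- function() {
  cna_tree(parents = c(0, 1, 2, 2, 1),
           events = list(c(S1 = 1, S2 = 1), c(S2 = 1, S3 = 1),
                         c(S1 = -1), c(S4 = -1), c(S1 = 1)),
           n_segments = 5)
}

# enumerate all valid labelled states with n in {n_lo..2}, K = 2 segments,
# |delta| <= max_d, diploid root
enumerate_small_space <- function(max_d = 2L, n_lo = 1L) {
  deltas <- seq.int(-max_d, max_d)
  events1 <- list()
  for (d1 in deltas) for (d2 in deltas) {
    if (d1 == 0 && d2 == 0) next
    events1[[length(events1) + 1L]] <- c(d1, d2)
  }
  states <- list()
  if (n_lo == 0L)
    states[[1L]] <- cna_tree(integer(0), matrix(0L, 0L, 2L), root_ploidy = 2L)
  for (e in events1) {
    tr <- cna_tree(0L, matrix(e, 1L, 2L), root_ploidy = 2L)
    if (validate_tree(tr)$valid) states[[length(states) + 1L]] <- tr
  }
  # all three labelled parent vectors on two nodes
  for (par2 in list(c(0L, 0L), c(0L, 1L), c(2L, 0L))) {
    for (e1 in events1) for (e2 in events1) {
      tr <- cna_tree(par2, rbind(e1, e2), root_ploidy = 2L)
      if (validate_tree(tr)$valid) states[[length(states) + 1L]] <- tr
    }
  }
  states
}
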