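#' Construct a copy-number event tree
#'
#' A CNA tree is a rooted tree whose non-root nodes each carry a copy-number
#' event: a set of net, signed per-segment copy-number changes. A cell attached
#' at a node has the genotype obtained by accumulating all events on the path
#' from the root, starting from the root ploidy.
#'
#' Nodes are labelled `1..n` with `0` denoting the root, so the tree structure
#' is a parent vector of length `n`. Events may be given either as a dense
#' `n x K` integer matrix of deltas (columns are segments), or as a list of
#' length `n` whose elements are named integer vectors such as
#' `c(S1 = 1, S2 = 1)` (names may also be plain column indices). Deltas on the
#' same segment within one node are net changes; zero entries are dropped.
#'
#' @param parents integer vector of length `n`; entry `i` is the parent label
#'   of node `i` (`0` is the root).
#' @param events dense `n x K` integer matrix of per-segment deltas, or a list
#'   of `n` named integer vectors.
#' @param n_segments number of segments `K`; required when `events` is a list
#'   and `root_ploidy` is scalar.
#' @param root_ploidy per-segment root copy number; a scalar is recycled to
#'   length `K` (default diploid). Need not be constant, e.g. sex chromosomes.
#' @return an object of class `cna_tree` with elements `n`, `parents`,
#'   `events` (dense matrix), `root_ploidy`.
#' @examples
#' tr <- cna_tree(
#'   parents = c(0, 1, 2, 2, 1),
#'   events = list(c(S1 = 1, S2 = 1), c(S2 = 1, S3 = 1),
#'                 c(S1 = -1), c(S4 = -1), c(S1 = 1)),
#'   n_segments = 5
#' )
#' compute_genotypes(tr)[6, ]  # genotype of node 5: (4, 3, 2, 2, 2)
#' @export
cna_tree <- function(parents, events, n_segments = NULL, root_ploidy = 2L) {
  parents <- as.integer(parents)
  n <- length(parents)
  if (is.list(events)) {
    if (length(events) != n) stop("'events' must have one element per node")
    if (is.null(n_segments)) {
      if (length(root_ploidy) > 1L) n_segments <- length(root_ploidy)
      else stop("'n_segments' required when events are given as a list")
    }
    K <- as.integer(n_segments)
    ev <- matrix(0L, nrow = n, ncol = K)
    for (i in seq_len(n)) {
      e <- events[[i]]
      if (length(e) == 0L) stop("node ", i, " has an empty event")
      idx <- .parse_segment_names(names(e), e, K)
      for (j in seq_along(idx)) ev[i, idx[j]] <- ev[i, idx[j]] + as.integer(e[j])
    }
  } else {
    if (!is.null(dim(events))) {
      ev <- as.matrix(events)
      storage.mode(ev) <- "integer"
      if (nrow(ev) != n) stop("'events' must have one row per node")
    } else {
      ev <- matrix(as.integer(events), nrow = n)
    }
    dimnames(ev) <- NULL
    K <- ncol(ev)
    if (!is.null(n_segments) && as.integer(n_segments) != K)
      stop("'n_segments' disagrees with ncol(events)")
  }
  if (length(root_ploidy) == 1L) root_ploidy <- rep(as.integer(root_ploidy), K)
  root_ploidy <- as.integer(root_ploidy)
  if (length(root_ploidy) != K) stop("'root_ploidy' must have one entry per segment")
  if (any(root_ploidy < 0L)) stop("'root_ploidy' must be non-negative")
  if (n > 0L && (any(parents < 0L) || any(parents > n)))
    stop("parent labels must lie in 0..n")
  tr <- structure(list(n = n, parents = parents, events = ev,
                       root_ploidy = root_ploidy),
                  class = "cna_tree")
  if (!.is_connected(tr)) stop("parent vector does not describe a rooted tree")
  tr
}

.parse_segment_names <- function(nm, e, K) {
  if (is.null(nm) || any(!nzchar(nm))) {
    if (length(e) != K) stop("unnamed event vectors must have length K")
    return(seq_len(K))
  }
  idx <- ifelse(grepl("^S[0-9]+$", nm), sub("^S", "", nm), nm)
  idx <- suppressWarnings(as.integer(idx))
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > K))
    stop("segment index out of range (segments are S1..S", K, ")")
  idx
}

.is_connected <- function(tree) {
  n <- tree$n
  if (n == 0L) return(TRUE)
  ch <- split(seq_len(n), factor(tree$parents, levels = 0:n))
  seen <- logical(n)
  stack <- ch[["0"]]
  while (length(stack)) {
    u <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (seen[u]) return(FALSE)
    seen[u] <- TRUE
    stack <- c(stack, ch[[as.character(u)]])
  }
  all(seen)
}

#' Node genotypes of a CNA tree
#'
#' Accumulates every node's events back to the root, returning the copy-number
#' state of each segment at each node. Row 1 is the root (node 0), row `i + 1`
#' is node `i`. Negative intermediate states are returned as-is; validity is
#' checked separately by [validate_tree()].
#'
#' @param tree a [cna_tree()].
#' @return `(n + 1) x K` integer matrix with rownames `"0" .. "n"`.
#' @export
compute_genotypes <- function(tree) {
  stopifnot(inherits(tree, "cna_tree"))
  n <- tree$n
  K <- ncol(tree$events)
  gen <- matrix(0L, nrow = n + 1L, ncol = K,
                dimnames = list(as.character(0:n), paste0("S", seq_len(K))))
  gen[1L, ] <- tree$root_ploidy
  if (n > 0L) {
    ord <- .topo_order(tree)
    for (u in ord) gen[u + 1L, ] <- gen[tree$parents[u] + 1L, ] + tree$events[u, ]
  }
  gen
}

.topo_order <- function(tree) {
  n <- tree$n
  ch <- split(seq_len(n), factor(tree$parents, levels = 0:n))
  out <- integer(0)
  stack <- ch[["0"]]
  while (length(stack)) {
    u <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, u)
    stack <- c(stack, ch[[as.character(u)]])
  }
  out
}

#' Check the biological validity of a CNA tree
#'
#' A tree is invalid when (in order of precedence) any node genotype has a
#' negative copy number (`negative_state`); a segment that reached copy number
#' zero at some node is increased by any event in that node's subtree
#' (`regain_after_zero`: a fully deleted segment cannot be regained); or two
#' distinct nodes, root included, share an identical genotype
#' (`duplicate_genotype`: the smaller tree fits equally well, so the redundant
#' one is forbidden).
#'
#' @param tree a [cna_tree()].
#' @return list with `valid` (logical) and `reason` (`NA` or one of
#'   `"negative_state"`, `"regain_after_zero"`, `"duplicate_genotype"`).
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "cna_tree"))
  gen <- compute_genotypes(tree)
  if (any(gen < 0L))
    return(list(valid = FALSE, reason = "negative_state"))
  n <- tree$n
  if (n > 0L) {
    ch <- split(seq_len(n), factor(tree$parents, levels = 0:n))
    # DFS carrying a per-segment "has hit zero" flag
    walk <- function(u, flag) {
      for (c in ch[[as.character(u)]]) {
        if (any(flag & tree$events[c, ] > 0L)) return(TRUE)
        f2 <- flag | gen[c + 1L, ] == 0L
        if (walk(c, f2)) return(TRUE)
      }
      FALSE
    }
    if (walk(0L, gen[1L, ] == 0L))
      return(list(valid = FALSE, reason = "regain_after_zero"))
  }
  if (anyDuplicated(gen) > 0L)
    return(list(valid = FALSE, reason = "duplicate_genotype"))
  list(valid = TRUE, reason = NA_character_)
}

#' Set of distinct genotypes generated by a tree
#'
#' @param tree a valid [cna_tree()].
#' @return matrix whose rows are the `n + 1` distinct genotype profiles.
#' @export
genotype_set <- function(tree) {
  gen <- compute_genotypes(tree)
  unique(gen)
}

#' @export
print.cna_tree <- function(x, ...) {
  cat("CNA event tree: ", x$n, " event node(s), ",
      ncol(x$events), " segment(s)\n", sep = "")
  if (x$n > 0L) {
    cat("  parents: (", paste(x$parents, collapse = ", "), ")\n", sep = "")
    for (i in seq_len(x$n)) {
      nz <- which(x$events[i, ] != 0L)
      lab <- paste0(ifelse(x$events[i, nz] > 0, "+", ""), x$events[i, nz],
                    "S", nz, collapse = " ")
      cat("  node ", i, ": ", lab, "\n", sep = "")
    }
  }
  cat("  root ploidy: (", paste(x$root_ploidy, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Serialize a CNA tree to JSON
#'
#' Events are written sparsely with 0-based segment indices; [tree_from_json()]
#' reverses the mapping, so trees round-trip exactly.
#'
#' @param tree a [cna_tree()].
#' @param path optional file to write to; otherwise the JSON string is returned.
#' @return JSON string (invisibly, when `path` is given).
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "cna_tree"))
  ev <- lapply(seq_len(tree$n), function(i) {
    nz <- which(tree$events[i, ] != 0L)
    list(segment = nz - 1L, delta = tree$events[i, nz])
  })
  obj <- list(n = tree$n, parents = tree$parents, events = ev,
              root_ploidy = tree$root_ploidy)
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a CNA tree from JSON
#'
#' @param x JSON string or path to a JSON file written by [tree_to_json()].
#' @return a [cna_tree()].
#' @export
tree_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyDataFrame = FALSE)
  K <- length(obj$root_ploidy)
  n <- as.integer(obj$n)
  ev <- matrix(0L, nrow = n, ncol = K)
  for (i in seq_len(n)) {
    e <- obj$events[[i]]
    ev[i, unlist(e$segment) + 1L] <- as.integer(unlist(e$delta))
  }
  cna_tree(parents = unlist(obj$parents), events = ev,
           root_ploidy = as.integer(obj$root_ploidy))
}

#' Export a CNA tree in DOT format
#'
#' Node labels list the events; optional attachment counts annotate how many
#' cells attach at each node.
#'
#' @param tree a [cna_tree()].
#' @param sigma optional per-cell attachment vector (values `0..n`) used to
#'   annotate nodes with cell counts.
#' @param path optional file to write to.
#' @return character vector of DOT lines (invisibly, when `path` is given).
#' @export
tree_to_dot <- function(tree, sigma = NULL, path = NULL) {
  stopifnot(inherits(tree, "cna_tree"))
  lab <- function(u) {
    if (u == 0L) return("root")
    nz <- which(tree$events[u, ] != 0L)
    paste0(ifelse(tree$events[u, nz] > 0, "+", ""), tree$events[u, nz],
           "S", nz, collapse = " ")
  }
  lines <- c("digraph cna_tree {", "  node [shape=box];")
  for (u in 0:tree$n) {
    l <- lab(u)
    if (!is.null(sigma)) l <- paste0(l, "\\n", sum(sigma == u), " cells")
    lines <- c(lines, sprintf("  n%d [label=\"%s\"];", u, l))
  }
  for (i in seq_len(tree$n))
    lines <- c(lines, sprintf("  n%d -> n%d;", tree$parents[i], i))
  lines <- c(lines, "}")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
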