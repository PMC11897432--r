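# The user-facing model fit: breakpoints -> segments -> staged MCMC search ->
# per-cell copy-number calls, wrapped in a classed object with the usual
# modelling methods.

#' Fit a copy-number event tree to single-cell read counts
#'
#' Runs the full inference pipeline on a cells-by-bins matrix of corrected
#' read counts: multi-cell breakpoint detection, collation of bins into
#' segments, and the staged Metropolis-Hastings search for the best-scoring
#' tree of copy-number events together with the attachment of every cell and
#' its per-bin integer copy-number profile.
#'
#' Counts may be real-valued (GC/mappability-corrected counts are generally
#' not integers); the Dirichlet-multinomial likelihood accepts non-negative
#' real counts directly.
#'
#' @param counts `m x B` matrix of corrected read counts (cells in rows), or
#'   anything coercible to one.
#' @param bins optional data frame of per-bin coordinates
#'   (`chrom`, `start`, `end`), as read by [read_bins()].
#' @param segments optional precomputed `scn_segments`; skips breakpoint
#'   detection.
#' @param root_ploidy root copy number, scalar or per-segment (use 4 to model
#'   a whole-genome duplication baseline).
#' @param score `"max"` (place each cell at its best attachment; the default)
#'   or `"sum"` (marginalize over attachments).
#' @param window breakpoint-detection window in bins.
#' @param threshold_sd robust threshold multiplier for breakpoint calling.
#' @param nu_bp detection dispersion of the breakpoint statistic.
#' @param seed random seed for the search (set via [set.seed()]).
#' @param config a [search_config()].
#' @param params a [likelihood_params()]; `params$nu` seeds the
#'   overdispersion walk.
#' @param prior a [prior_params()].
#' @param moves a [move_config()].
#' @return an object of class `scnatree` with components `tree`, `nu`,
#'   `sigma` (attachments), `cnv` (`m x B` integer copy-number calls),
#'   `segments`, `breakpoints`, `score`, `table`, `diagnostics`, plus the
#'   inputs needed by the methods.
#' @seealso [summary.scnatree()], [predict.scnatree()], [simulate.scnatree()]
#' @export
scnatree <- function(counts, bins = NULL, segments = NULL, root_ploidy = 2L,
                     score = c("max", "sum"), window = 10L, threshold_sd = 4,
                     nu_bp = 1, seed = NULL, config = search_config(),
                     params = likelihood_params(), prior = prior_params(),
                     moves = move_config()) {
  score <- match.arg(score)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("'counts' must be non-negative and finite")
  if (!is.null(seed)) set.seed(seed)
  B <- ncol(counts)
  if (!is.null(bins) && nrow(bins) != B)
    stop("'bins' must have one row per count column")

  bp <- NULL
  if (is.null(segments)) {
    bp <- detect_breakpoints(counts, window = window, nu_bp = nu_bp,
                             threshold_sd = threshold_sd)
    segments <- build_segments(bp, B)
  }
  agg <- aggregate_counts(counts, segments)

  res <- robust_infer(agg$D, agg$sizes, config = config, params = params,
                      prior = prior, moves = moves, score = score,
                      root_ploidy = root_ploidy)
  cnv <- call_copy_numbers(res$tree, res$sigma, segments)

  structure(list(tree = res$tree, nu = res$nu, sigma = res$sigma, cnv = cnv,
                 segments = segments, breakpoints = bp, bins = bins,
                 score = res$score, score_mode = score, table = res$table,
                 cluster_labels = res$cluster_labels,
                 cluster_tree = res$cluster_tree,
                 diagnostics = res$diagnostics,
                 D = agg$D, sizes = agg$sizes, totals = agg$totals,
                 eta = params$eta, use_multinomial = params$use_multinomial,
                 seed = seed, call = match.call()),
            class = "scnatree")
}

#' @export
print.scnatree <- function(x, ...) {
  cat("Copy-number event tree fit\n")
  cat("  ", nrow(x$cnv), " cells, ", ncol(x$cnv), " bins, ",
      nrow(x$segments), " segments\n", sep = "")
  cat("  tree: ", x$tree$n, " event node(s); score (", x$score_mode, ") = ",
      format(x$score), "; nu = ", format(x$nu), "\n", sep = "")
  invisible(x)
}

#' Summarize a fitted copy-number tree
#'
#' @param object an [scnatree()] fit.
#' @param ... unused.
#' @return a `summary.scnatree` object: clone table (genotype + attached cell
#'   count per node), breakpoint count, score breakdown, diagnostics.
#' @export
summary.scnatree <- function(object, ...) {
  gen <- compute_genotypes(object$tree)
  attached <- table(factor(object$sigma, levels = 0:object$tree$n))
  out <- list(n_cells = nrow(object$cnv), n_bins = ncol(object$cnv),
              n_segments = nrow(object$segments),
              n_breakpoints = if (is.null(object$breakpoints)) NA_integer_
                              else length(object$breakpoints$boundaries),
              tree = object$tree, genotypes = gen,
              attached = as.integer(attached),
              nu = object$nu, score = object$score,
              score_mode = object$score_mode,
              diagnostics = object$diagnostics)
  class(out) <- "summary.scnatree"
  out
}

#' @export
print.summary.scnatree <- function(x, ...) {
  cat("Copy-number event tree fit\n")
  cat("  data: ", x$n_cells, " cells x ", x$n_bins, " bins; ",
      x$n_segments, " segments", sep = "")
  if (!is.na(x$n_breakpoints)) cat(" (", x$n_breakpoints, " breakpoints)", sep = "")
  cat("\n  score (", x$score_mode, "): ", format(x$score),
      "; overdispersion nu = ", format(x$nu), "\n", sep = "")
  cat("  nodes (genotype | cells attached):\n")
  for (u in 0:x$tree$n) {
    cat("    ", if (u == 0L) "root" else paste0("node ", u), ": (",
        paste(x$genotypes[u + 1L, ], collapse = ","), ") | ",
        x$attached[u + 1L], "\n", sep = "")
  }
  invisible(x)
}

#' Node genotypes of a fitted tree
#'
#' @param object an [scnatree()] fit.
#' @param ... unused.
#' @return `(n + 1) x K` matrix of per-node, per-segment copy numbers.
#' @export
coef.scnatree <- function(object, ...) {
  compute_genotypes(object$tree)
}

#' Expected per-bin read counts under the fitted model
#'
#' @param object an [scnatree()] fit.
#' @param ... unused.
#' @return `m x B` matrix of expected counts (`N_j` times the per-bin read
#'   probabilities implied by each cell's called profile).
#' @export
fitted.scnatree <- function(object, ...) {
  cf <- pmax(object$cnv, object$eta)
  object$totals * cf / rowSums(cf)
}

#' Residuals of a fitted copy-number tree
#'
#' @param object an [scnatree()] fit.
#' Residuals are computed at segment level (observed segment counts versus
#' the expected allocation of each cell's read total), since that is the
#' resolution the likelihood models.
#'
#' @param type `"response"` (observed minus expected counts) or `"pearson"`
#'   (scaled by the Dirichlet-multinomial standard deviation).
#' @param ... unused.
#' @return `m x K` matrix of segment-level residuals.
#' @export
residuals.scnatree <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  # segment level: observed D versus expected allocation of N_j
  cf <- pmax(compute_genotypes(object$tree)[object$sigma + 1L, , drop = FALSE],
             object$eta)
  mass <- sweep(cf, 2L, object$sizes, "*")
  p <- mass / rowSums(mass)
  mu <- object$totals * p
  r <- object$D - mu
  if (type == "pearson") {
    Z <- rowSums(mass)
    infl <- if (object$use_multinomial) 1
            else (object$totals + object$nu * Z) / (1 + object$nu * Z)
    v <- object$totals * p * (1 - p) * infl
    r <- r / sqrt(pmax(v, .Machine$double.eps))
  }
  r
}

#' Predict copy-number profiles
#'
#' With `newdata`, new cells are aggregated over the fitted segmentation and
#' attached to the fitted tree at their maximum-likelihood node; without, the
#' fit's own calls are returned.
#'
#' @param object an [scnatree()] fit.
#' @param newdata optional `m' x B` count matrix of new cells.
#' @param type `"profile"` (per-bin copy numbers), `"segment"` (per-segment
#'   copy numbers), or `"attachment"` (node labels).
#' @param ... unused.
#' @return matrix or vector according to `type`.
#' @export
predict.scnatree <- function(object, newdata = NULL,
                             type = c("profile", "segment", "attachment"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    sigma <- object$sigma
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != ncol(object$cnv))
      stop("'newdata' must have the same bins as the fitted data")
    agg <- aggregate_counts(newdata, object$segments)
    tb <- attachment_table(object$tree, agg$D, object$sizes,
                           likelihood_params(nu = object$nu, eta = object$eta,
                                             use_multinomial = object$use_multinomial))
    sigma <- best_attachments(tb)
  }
  switch(type,
         attachment = sigma,
         segment = compute_genotypes(object$tree)[sigma + 1L, , drop = FALSE],
         profile = call_copy_numbers(object$tree, sigma, object$segments))
}

#' Simulate read counts from a fitted tree
#'
#' Draws new count matrices from the fitted generative model: each cell keeps
#' its attachment and read total, and counts are re-sampled from the
#' Dirichlet-multinomial around its called per-bin profile with the fitted
#' overdispersion.
#'
#' @param object an [scnatree()] fit.
#' @param nsim number of replicate matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `nsim` count matrices.
#' @export
simulate.scnatree <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  B <- ncol(object$cnv)
  lapply(seq_len(nsim), function(s) {
    out <- matrix(0L, nrow = nrow(object$cnv), ncol = B)
    for (j in seq_len(nrow(out))) {
      alpha <- object$nu * pmax(object$cnv[j, ], object$eta)
      g <- stats::rgamma(B, shape = alpha, rate = 1)
      if (sum(g) <= 0) g <- alpha
      out[j, ] <- as.integer(stats::rmultinom(1L, round(object$totals[j]),
                                              g / sum(g)))
    }
    out
  })
}

#' Log-likelihood of a fitted copy-number tree
#'
#' Sum over cells of the attachment log-likelihood at each cell's called
#' node (Dirichlet-multinomial, without the attachment-invariant multinomial
#' coefficient).
#'
#' @param object an [scnatree()] fit.
#' @param ... unused.
#' @return a `logLik` object; degrees of freedom count the nonzero event
#'   entries plus one for the overdispersion.
#' @export
logLik.scnatree <- function(object, ...) {
  rel <- object$table$loglik
  ll <- sum(object$table$root_loglik +
              rel[cbind(seq_len(nrow(rel)), object$sigma + 1L)])
  structure(ll, df = sum(object$tree$events != 0L) + 1L,
            nobs = nrow(rel), class = "logLik")
}

#' Plot a fitted copy-number tree
#'
#' `type = "tree"` draws the event tree with per-node event labels and
#' attached-cell counts; `"profiles"` shows the called copy-number matrix as
#' a heatmap with cells ordered by attachment; `"signal"` shows the combined
#' breakpoint signal with the called boundaries.
#'
#' @param x an [scnatree()] fit.
#' @param type plot flavour.
#' @param ... further graphical parameters (ignored).
#' @return `x`, invisibly.
#' @export
plot.scnatree <- function(x, type = c("tree", "profiles", "signal"), ...) {
  type <- match.arg(type)
  if (type == "signal") {
    if (is.null(x$breakpoints)) stop("fit was built from precomputed segments")
    sig <- x$breakpoints$full_signal
    graphics::plot(seq_along(sig), sig, type = "h", xlab = "bin boundary",
                   ylab = "combined signal", main = "breakpoint signal")
    graphics::abline(h = x$breakpoints$threshold, lty = 2)
    graphics::points(x$breakpoints$boundaries, x$breakpoints$signal,
                     col = "red", pch = 16)
    return(invisible(x))
  }
  if (type == "profiles") {
    ord <- order(x$sigma)
    graphics::image(t(x$cnv[ord, , drop = FALSE]),
                    col = grDevices::hcl.colors(12, "RdBu", rev = TRUE),
                    xlab = "genome bin", ylab = "cell (by attachment)",
                    main = "called copy numbers", axes = FALSE)
    graphics::box()
    return(invisible(x))
  }
  .plot_tree(x$tree, x$sigma)
  invisible(x)
}

.plot_tree <- function(tree, sigma = NULL) {
  n <- tree$n
  depth <- integer(n + 1L)
  for (u in .topo_order(tree)) depth[u + 1L] <- depth[tree$parents[u] + 1L] + 1L
  ch <- split(seq_len(n), factor(tree$parents, levels = 0:n))
  xpos <- numeric(n + 1L)
  leaf_x <- 0
  assign_x <- function(u) {
    kids <- ch[[as.character(u)]]
    if (!length(kids)) {
      leaf_x <<- leaf_x + 1
      xpos[u + 1L] <<- leaf_x
    } else {
      for (k in kids) assign_x(k)
      xpos[u + 1L] <<- mean(xpos[kids + 1L])
    }
  }
  assign_x(0L)
  y <- -depth
  graphics::plot(xpos, y, type = "n", axes = FALSE, xlab = "", ylab = "",
                 main = "copy-number event tree",
                 xlim = range(xpos) + c(-0.5, 0.5), ylim = range(y) + c(-0.5, 0.5))
  for (i in seq_len(n))
    graphics::segments(xpos[tree$parents[i] + 1L], y[tree$parents[i] + 1L],
                       xpos[i + 1L], y[i + 1L], col = "grey50")
  labs <- vapply(0:n, function(u) {
    l <- if (u == 0L) "root" else {
      nz <- which(tree$events[u, ] != 0L)
      paste0(ifelse(tree$events[u, nz] > 0, "+", ""), tree$events[u, nz],
             "S", nz, collapse = " ")
    }
    if (!is.null(sigma)) l <- paste0(l, "\n", sum(sigma == u), " cells")
    l
  }, character(1))
  graphics::points(xpos, y, pch = 21, bg = "white", cex = 3)
  graphics::text(xpos, y, labs, cex = 0.7)
}
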