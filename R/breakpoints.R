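# Multi-cell breakpoint detection: per-cell windowed likelihood-ratio of a
# step-change versus constant copy-number model, collated across cells, with
# robust thresholding; then bins are collated into segments.

# Negative-binomial profile log-likelihood of a window, as a function of the
# window sum S and bin count n only (size parameter r fixed; mean at its MLE
# S/n). All terms not depending on the fitted mean cancel in the ratio.
.nb_profile <- function(S, n, r) {
  out <- numeric(length(S))
  pos <- S > 0 & n > 0
  mu <- S[pos] / n[pos]
  out[pos] <- n[pos] * r * log(r / (r + mu)) + S[pos] * log(mu / (r + mu))
  out
}

#' Per-cell step-change statistic at every bin boundary
#'
#' For each boundary `b` (between bins `b` and `b + 1`), compares a two-mean
#' negative-binomial model on the flanking windows against a single-mean model
#' on their union. The statistic is a log-likelihood ratio, zero when the two
#' window means coincide, and is computed for all boundaries in O(B) via
#' prefix sums. Windows are truncated near the chromosome ends.
#'
#' @param counts_row numeric vector of corrected counts for one cell (length
#'   `B`).
#' @param window window half-width `w` in bins (each flank uses up to `w`
#'   bins).
#' @param nu_bp negative-binomial size (detection dispersion); default 1.
#' @return numeric vector of length `B - 1`; entry `b` is the statistic for a
#'   breakpoint between bin `b` and bin `b + 1`.
#' @export
per_cell_step_statistic <- function(counts_row, window = 10L, nu_bp = 1) {
  B <- length(counts_row)
  w <- as.integer(window)
  if (w < 2L) stop("'window' must be at least 2 bins")
  if (w > B / 2) stop("'window' larger than B/2")
  cs <- c(0, cumsum(as.numeric(counts_row)))
  b <- seq_len(B - 1L)                       # boundary after bin b
  lo <- pmax(b - w, 0L)                      # left window [lo, b)
  hi <- pmin(b + w, B)                       # right window [b, hi)
  SL <- cs[b + 1L] - cs[lo + 1L]
  SR <- cs[hi + 1L] - cs[b + 1L]
  nL <- b - lo
  nR <- hi - b
  .nb_profile(SL, nL, nu_bp) + .nb_profile(SR, nR, nu_bp) -
    .nb_profile(SL + SR, nL + nR, nu_bp)
}

#' Combined breakpoint signal across cells
#'
#' Rectifies each cell's step statistic at zero and sums over cells. Rows are
#' first scaled to a common mean so that depth differences between cells do
#' not dominate (corrected counts are proportional, not absolute). Total cost
#' is O(m * B).
#'
#' @param counts `m x B` matrix of corrected read counts (cells in rows).
#' @param window,nu_bp see [per_cell_step_statistic()].
#' @param normalize scale each cell to the grand mean before the statistic.
#' @return numeric vector of length `B - 1`.
#' @export
combined_signal <- function(counts, window = 10L, nu_bp = 1, normalize = TRUE) {
  counts <- as.matrix(counts)
  if (normalize) {
    gm <- mean(counts)
    rm <- rowMeans(counts)
    rm[rm == 0] <- 1
    counts <- counts * (gm / rm)
  }
  sig <- numeric(ncol(counts) - 1L)
  for (j in seq_len(nrow(counts)))
    sig <- sig + pmax(per_cell_step_statistic(counts[j, ], window, nu_bp), 0)
  sig
}

#' Call breakpoints from a combined signal
#'
#' Boundaries whose signal exceeds `median + threshold_sd * MAD` are selected
#' greedily in order of decreasing signal (ties broken toward the lower
#' index), skipping candidates within `min_separation` bins of an already
#' selected breakpoint.
#'
#' @param signal combined signal of length `B - 1`.
#' @param threshold_sd robust threshold multiplier (default 4).
#' @param min_separation exclusion radius in bins (default 10).
#' @return object of class `scn_breakpoints`: list with sorted `boundaries`
#'   (bin index `b` means a break between bin `b` and `b + 1`), their
#'   `signal`, and the `threshold` used.
#' @export
call_breakpoints <- function(signal, threshold_sd = 4, min_separation = 10L) {
  thr <- stats::median(signal) + threshold_sd * stats::mad(signal)
  cand <- which(signal > thr & signal > 0)
  sel <- integer(0)
  if (length(cand)) {
    ord <- cand[order(-signal[cand], cand)]
    for (b in ord) {
      if (!length(sel) || all(abs(sel - b) >= min_separation)) sel <- c(sel, b)
    }
    sel <- sort(sel)
  }
  structure(list(boundaries = sel, signal = signal[sel], threshold = thr),
            class = "scn_breakpoints")
}

#' Detect breakpoints in a cells-by-bins count matrix
#'
#' Convenience wrapper combining [combined_signal()] and [call_breakpoints()].
#'
#' @inheritParams combined_signal
#' @inheritParams call_breakpoints
#' @return an `scn_breakpoints` object that additionally carries the full
#'   per-boundary signal as `full_signal`.
#' @export
detect_breakpoints <- function(counts, window = 10L, nu_bp = 1,
                               threshold_sd = 4, min_separation = window) {
  sig <- combined_signal(counts, window = window, nu_bp = nu_bp)
  bp <- call_breakpoints(sig, threshold_sd = threshold_sd,
                         min_separation = min_separation)
  bp$full_signal <- sig
  bp
}

#' Collate bins between consecutive breakpoints into segments
#'
#' @param breakpoints an `scn_breakpoints` object or integer vector of
#'   boundaries (`b` = break between bins `b` and `b + 1`, values in
#'   `1..B-1`).
#' @param n_bins total number of bins `B`.
#' @return object of class `scn_segments`: data frame with 0-based half-open
#'   bin intervals `start`, `end` and `size = end - start`; `K` breakpoints
#'   give `K + 1` segments covering all bins exactly once.
#' @export
build_segments <- function(breakpoints, n_bins) {
  if (inherits(breakpoints, "scn_breakpoints")) breakpoints <- breakpoints$boundaries
  b <- sort(unique(as.integer(breakpoints)))
  if (length(b) && (min(b) < 1L || max(b) > n_bins - 1L))
    stop("boundaries must lie in 1..B-1")
  starts <- c(0L, b)
  ends <- c(b, as.integer(n_bins))
  structure(data.frame(start = starts, end = ends, size = ends - starts),
            class = c("scn_segments", "data.frame"))
}

#' Sum bin counts within segments
#'
#' @param counts `m x B` count matrix.
#' @param segments an `scn_segments` object covering all `B` bins.
#' @return list with `D` (`m x K` matrix of per-segment summed counts),
#'   `sizes` (bins per segment), and `totals` (per-cell read totals).
#' @export
aggregate_counts <- function(counts, segments) {
  counts <- as.matrix(counts)
  B <- ncol(counts)
  if (sum(segments$size) != B) stop("segments do not cover all bins")
  idx <- rep(seq_len(nrow(segments)), segments$size)
  D <- t(rowsum(t(counts), group = idx, reorder = TRUE))
  dimnames(D) <- list(rownames(counts), paste0("S", seq_len(nrow(segments))))
  list(D = D, sizes = as.numeric(segments$size), totals = rowSums(D))
}

#' Mask outlier bins
#'
#' Flags bins whose total count across cells exceeds `factor` times the median
#' bin total; a generic utility for removing collapsed-repeat artefacts before
#' breakpoint detection.
#'
#' @param counts `m x B` count matrix.
#' @param factor multiple of the median bin total above which a bin is masked.
#' @return logical vector of length `B`; `TRUE` marks a masked bin.
#' @export
outlier_bin_mask <- function(counts, factor = 3) {
  tot <- colSums(as.matrix(counts))
  tot > factor * stats::median(tot)
}
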