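# File input/output: delimited count matrices, BED bin annotation, and the
# result bundle written by a full inference run.

#' Read a cells-by-bins count matrix
#'
#' Accepts TSV or CSV (by extension; `.gz` transparently), with an optional
#' header row and an optional leading non-numeric cell-id column. Values must
#' be non-negative and finite; corrected counts need not be integers.
#'
#' @param path file path.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return numeric matrix, cells in rows, with any ids as rownames.
#' @export
read_counts <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first[-1L]))))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- NULL
  if (ncol(df) > 1L && !is.numeric(df[[1L]])) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("non-numeric values in count matrix: ", path)
  x <- as.matrix(df)
  dimnames(x) <- list(ids, NULL)
  if (any(!is.finite(x))) stop("missing or non-finite counts in ", path)
  if (any(x < 0)) stop("negative counts in ", path)
  x
}

#' Write a count matrix
#'
#' @param counts matrix, cells in rows.
#' @param path output path (TSV; `.gz` compresses).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(counts, con, sep = "\t", quote = FALSE,
                     row.names = !is.null(rownames(counts)), col.names = FALSE)
  invisible(path)
}

#' Read per-bin coordinates from a BED file
#'
#' Standard 3+ column BED: 0-based, half-open intervals, one per bin, sorted
#' and non-overlapping within each chromosome.
#'
#' @param path BED file path.
#' @param one_based treat the input as 1-based inclusive and convert.
#' @return data frame with `chrom`, `start`, `end`.
#' @export
read_bins <- function(path, one_based = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.numeric(df[[2L]]),
                    end = as.numeric(df[[3L]]))
  if (one_based) out$start <- out$start - 1
  if (any(out$end <= out$start)) stop("empty or inverted bin intervals")
  for (ch in unique(out$chrom)) {
    b <- out[out$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE) || any(b$start[-1L] < b$end[-nrow(b)]))
      stop("bins are unsorted or overlapping on ", ch)
  }
  out
}

#' Write the result bundle of a fitted tree
#'
#' Writes `tree.json`, `tree.dot`, `cnvs.tsv` (cells x bins),
#' `attachments.tsv`, and `diagnostics.json` into a directory. Re-running the
#' same fit writes identical files.
#'
#' @param fit an [scnatree()] fit.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(fit, dir) {
  stopifnot(inherits(fit, "scnatree"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree_to_json(fit$tree, file.path(dir, "tree.json"))
  tree_to_dot(fit$tree, fit$sigma, file.path(dir, "tree.dot"))
  utils::write.table(fit$cnv, file.path(dir, "cnvs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(cell = seq_along(fit$sigma), node = fit$sigma),
                     file.path(dir, "attachments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  diag <- list(score = fit$score, score_mode = fit$score_mode, nu = fit$nu,
               n_nodes = fit$tree$n, n_segments = nrow(fit$segments),
               seed = fit$seed, diagnostics = fit$diagnostics)
  jsonlite::write_json(diag, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  seg <- as.data.frame(fit$segments)
  utils::write.table(seg, file.path(dir, "segments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
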