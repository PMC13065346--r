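#' Counts per million miRNA reads
#'
#' Each count is divided by its sample's total miRNA count and scaled to
#' one million; no pseudocount is added, so every non-degenerate column of
#' the result sums to 1e6. CPM is the abundance scale used for top-k
#' ranking; differential expression and tau use median-of-ratios
#' normalization instead (see [size_factors]).
#'
#' @param x an [ev_counts] object or a count matrix (features x samples).
#' @return numeric matrix of CPM values with the input's dimnames.
#' @export
cpm <- function(x) {
  m <- if (inherits(x, "ev_counts")) x$counts else x
  totals <- colSums(m)
  if (any(totals == 0)) {
    bad <- colnames(m)[totals == 0][1L]
    stop_degenerate("sample has zero total counts: ", bad)
  }
  sweep(m, 2L, totals, `/`) * 1e6
}

#' Median-of-ratios size factors and normalized counts
#'
#' Implements the median-of-ratios convention: a pseudo-reference sample is
#' formed as the per-feature geometric mean over samples, restricted to
#' features with non-zero counts in every sample; each sample's size factor
#' is the median of its count-to-reference ratios over those features. Size
#' factors are rescaled so their geometric mean is exactly 1, which fixes
#' the otherwise arbitrary scale of the normalized counts
#' (count / size factor). The log matrix is log2(normalized + 1), a
#' transparent stand-in for shrinkage-based variance-stabilizing
#' transforms.
#'
#' @param x an [ev_counts] object or count matrix.
#' @return A list of class `normalization`: `size_factors` (named, geometric
#'   mean 1), `normalized` (matrix), `log2` (matrix), `reference_features`
#'   (IDs used for the pseudo-reference).
#' @export
size_factors <- function(x) {
  m <- if (inherits(x, "ev_counts")) x$counts else x
  ref_idx <- rowSums(m == 0) == 0
  if (!any(ref_idx)) {
    stop_degenerate("no feature is non-zero in every sample; ",
                    "median-of-ratios undefined (consider CPM instead)")
  }
  logref <- rowMeans(log(m[ref_idx, , drop = FALSE]))
  logratios <- log(m[ref_idx, , drop = FALSE]) - logref
  s <- exp(apply(logratios, 2L, median))
  s <- s / exp(mean(log(s)))
  normalized <- sweep(m, 2L, s, `/`)
  structure(list(size_factors = s,
                 normalized = normalized,
                 log2 = log2(normalized + 1),
                 reference_features = rownames(m)[ref_idx]),
            class = "normalization")
}

#' @export
print.normalization <- function(x, ...) {
  cat("median-of-ratios normalization\n")
  print(round(x$size_factors, 4))
  invisible(x)
}

#' Principal component analysis of a log count matrix
#'
#' Samples are the observations; features are centered but not scaled
#' (unit-scaling would flatten the abundance structure that the log
#' transform already stabilizes). Features constant across all samples are
#' dropped before decomposition. Variance-explained fractions are
#' non-negative, non-increasing and sum to 1 over the returned components.
#'
#' @param logmatrix numeric matrix, features x samples (e.g. the `log2`
#'   element of [size_factors]).
#' @param groups optional group labels attached to the score table.
#' @return list of class `mir_pca`: `scores` (samples x components),
#'   `var_explained` (fractions), `sdev`.
#' @export
mir_pca <- function(logmatrix, groups = NULL) {
  if (ncol(logmatrix) < 2L) {
    stop_degenerate("PCA needs at least 2 samples")
  }
  keep <- apply(logmatrix, 1L, function(r) diff(range(r)) > 0)
  if (!any(keep)) stop_degenerate("all features are constant across samples")
  p <- prcomp(t(logmatrix[keep, , drop = FALSE]), center = TRUE,
              scale. = FALSE)
  varfrac <- p$sdev^2 / sum(p$sdev^2)
  scores <- p$x
  structure(list(scores = scores,
                 var_explained = varfrac,
                 sdev = p$sdev,
                 groups = groups),
            class = "mir_pca")
}

#' @export
print.mir_pca <- function(x, ...) {
  k <- min(3L, length(x$var_explained))
  cat("PCA of log-normalized counts; variance explained: ",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$var_explained[1:k]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
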