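#' Tissue-specificity index tau
#'
#' tau = sum_i (1 - x_i / x_max) / (N - 1) over N group means: 0 for a
#' perfectly uniform expression profile, 1 for expression confined to a
#' single group. Undefined (NA) when all means are zero; such features are
#' never called enriched.
#'
#' @param x numeric vector of non-negative per-group means (length >= 2),
#'   or a matrix with one profile per row.
#' @return tau value(s) in \[0, 1\], NA where the profile is all-zero.
#' @examples
#' compute_tau(c(10, 5, 0, 5))  # 2/3
#' @export
compute_tau <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) < 2L) stop_config("tau needs at least 2 groups")
    if (any(x < 0, na.rm = TRUE)) stop_config("group means must be >= 0")
    mx <- apply(x, 1L, max)
    tau <- rowSums(1 - x / mx) / (ncol(x) - 1L)
    tau[mx == 0] <- NA_real_
    return(tau)
  }
  if (length(x) < 2L) stop_config("tau needs at least 2 groups")
  if (any(x < 0)) stop_config("group means must be >= 0")
  if (max(x) == 0) return(NA_real_)
  sum(1 - x / max(x)) / (length(x) - 1L)
}

#' Per-feature group means of normalized counts with tau
#'
#' Group means are taken on the median-of-ratios normalized scale (not
#' CPM): tau describes specificity of the expression level that the
#' differential-expression model sees, while abundance ranking uses CPM.
#'
#' @param normalized matrix of normalized counts (features x samples).
#' @param groups factor of group labels per sample.
#' @return data frame of class `tau_table`: `feature`, one `mean_<group>`
#'   column per group, `x_max`, `tau`.
#' @export
tau_table <- function(normalized, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop_config("tau needs at least 2 groups")
  means <- vapply(levels(groups), function(g) {
    rowMeans(normalized[, groups == g, drop = FALSE])
  }, numeric(nrow(normalized)))
  tau <- compute_tau(means)
  out <- data.frame(feature = rownames(normalized), means, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[1L + seq_len(ncol(means))] <- paste0("mean_", colnames(means))
  out$x_max <- apply(means, 1L, max)
  out$tau <- tau
  class(out) <- c("tau_table", "data.frame")
  out
}

#' Three-criteria integrative filter for subtype-specific key miRNAs
#'
#' For every (feature, subtype) combination, evaluates:
#' \describe{
#'   \item{abundant}{the feature is in the subtype's top-k by mean CPM.}
#'   \item{upregulated}{significantly up (FDR < alpha, log2FC > 0 in favor
#'     of the subtype) versus at least one other subtype.}
#'   \item{enriched}{tau > tau_thresh, OR linear fold change > fc_thresh in
#'     favor of the subtype in at least `m` pairwise comparisons (by
#'     default only comparisons passing FDR < alpha count, so noise-driven
#'     fold changes from near-zero means cannot qualify; set
#'     `require_significance = FALSE` for the permissive reading).}
#' }
#' A feature is a key miRNA for a subtype when all three hold. The
#' consensus-upregulated flag additionally requires significant
#' upregulation against every other subtype.
#'
#' @param ranking an `abundance_ranking` from [rank_abundance].
#' @param de a `de_result` list from [fit_pairwise] covering all pairs.
#' @param tau a `tau_table` computed on the same normalized counts as `de`.
#' @param alpha FDR significance threshold (default 0.05).
#' @param tau_thresh tau enrichment threshold (default 0.7).
#' @param fc_thresh linear fold-change enrichment threshold (default 5).
#' @param m minimum number of qualifying comparisons for the fold-change
#'   arm of the enrichment criterion (default 2).
#' @param require_significance whether fold-change evidence must also pass
#'   FDR < alpha (default TRUE).
#' @return data frame of class `key_signature`: `feature`, `subtype`,
#'   `abundant`, `upregulated`, `enriched`, `tau`, `n_fc_pairs`, `key`,
#'   `consensus_upregulated`. Only (feature, subtype) rows where at least
#'   one flag is TRUE are retained.
#' @export
classify_key <- function(ranking, de, tau, alpha = 0.05, tau_thresh = 0.7,
                         fc_thresh = 5, m = 2L,
                         require_significance = TRUE) {
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1)) {
    stop_config("alpha must lie in (0, 1)")
  }
  if (fc_thresh <= 1) stop_config("fc_thresh must exceed 1")
  if (m < 1) stop_config("m must be >= 1")
  subtypes <- names(ranking$top)
  others <- function(g) setdiff(subtypes, g)
  tau_of <- setNames(tau$tau, tau$feature)
  lfc_thresh <- log2(fc_thresh)

  rows <- list()
  for (g in subtypes) {
    abundant_set <- ranking$top[[g]]$feature
    up_sets <- lapply(others(g), function(o) upregulated_in(de, g, o, alpha))
    up_any <- unique(unlist(up_sets))
    up_all <- Reduce(intersect, up_sets)
    fc_sets <- lapply(others(g), function(o) {
      upregulated_in(de, g, o,
                     alpha = if (require_significance) alpha else 1,
                     lfc_min = lfc_thresh)
    })
    fc_count <- table(unlist(fc_sets))

    feats <- unique(c(abundant_set, up_any, names(fc_count),
                      tau$feature[!is.na(tau_of) & tau_of > tau_thresh]))
    if (!length(feats)) next
    n_fc <- as.integer(fc_count[feats]); n_fc[is.na(n_fc)] <- 0L
    t_g <- tau_of[feats]
    enriched <- (!is.na(t_g) & t_g > tau_thresh) | n_fc >= m
    rows[[g]] <- data.frame(
      feature = feats, subtype = g,
      abundant = feats %in% abundant_set,
      upregulated = feats %in% up_any,
      enriched = enriched,
      tau = unname(t_g),
      n_fc_pairs = n_fc,
      consensus_upregulated = feats %in% up_all,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(feature = character(0), subtype = character(0),
                      abundant = logical(0), upregulated = logical(0),
                      enriched = logical(0), tau = numeric(0),
                      n_fc_pairs = integer(0),
                      consensus_upregulated = logical(0))
  }
  out$key <- out$abundant & out$upregulated & out$enriched
  keep <- out$abundant | out$upregulated | out$enriched
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("key_signature", "data.frame")
  out
}

#' Features significantly upregulated against every other subtype
#'
#' @param de a `de_result` list from [fit_pairwise].
#' @param subtype the group of interest.
#' @param alpha FDR threshold.
#' @return character vector of consensus-upregulated feature IDs.
#' @export
consensus_upregulated <- function(de, subtype, alpha = 0.05) {
  groups <- unique(unlist(strsplit(names(de), "_vs_", fixed = TRUE)))
  if (!subtype %in% groups) stop_format("no DE tables involve ", subtype)
  sets <- lapply(setdiff(groups, subtype), function(o) {
    upregulated_in(de, subtype, o, alpha)
  })
  sort(Reduce(intersect, sets))
}
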