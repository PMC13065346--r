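#' Partition detected miRNAs by the subset of groups expressing them
#'
#' Assigns every detected feature to the exact subset of groups in which
#' the detection rule holds — the cells of the multi-group Venn diagram
#' (15 non-empty cells for four groups). Features failing the rule in
#' every group are excluded from the union.
#'
#' Built-in rules:
#' \describe{
#'   \item{`any_replicate_nonzero`}{detected in a group if any replicate
#'     has a non-zero raw count (default; the most permissive reading of
#'     "detected in sequencing").}
#'   \item{`all_replicates_nonzero`}{every replicate non-zero.}
#'   \item{`min_total`}{group total count >= `min_total`.}
#' }
#'
#' @param x an [ev_counts] object.
#' @param rule detection rule name.
#' @param min_total threshold for the `min_total` rule.
#' @return list of class `detection_partition`:
#'   \describe{
#'     \item{cells}{named list, one element per occupied subset (label
#'       `"CM+Mac"` etc., groups in factor-level order), each a character
#'       vector of feature IDs.}
#'     \item{membership}{logical matrix features x groups.}
#'     \item{group_totals}{features detected per group (any cell).}
#'     \item{exclusive}{features detected in exactly that one group.}
#'     \item{union_size}{number of features detected anywhere.}
#'     \item{rule}{rule descriptor.}
#'   }
#' @export
detect_partition <- function(x, rule = c("any_replicate_nonzero",
                                         "all_replicates_nonzero",
                                         "min_total"),
                             min_total = 10) {
  rule <- tryCatch(match.arg(rule),
                   error = function(e) stop_config("unknown detection rule: ",
                                                   rule[1L]))
  g <- levels(x$groups)
  if (length(g) < 1L) stop_config("need at least one group")
  membership <- vapply(g, function(gr) {
    sub <- x$counts[, x$groups == gr, drop = FALSE]
    switch(rule,
           any_replicate_nonzero = rowSums(sub > 0) > 0,
           all_replicates_nonzero = rowSums(sub > 0) == ncol(sub),
           min_total = rowSums(sub) >= min_total)
  }, logical(nrow(x$counts)))
  rownames(membership) <- rownames(x$counts)

  detected <- rowSums(membership) > 0
  mem <- membership[detected, , drop = FALSE]
  labels <- apply(mem, 1L, function(r) paste(g[r], collapse = "+"))
  cells <- split(rownames(mem), labels)
  # order cells by subset size then group order for stable reporting
  ord <- order(vapply(strsplit(names(cells), "+", fixed = TRUE), length, 1L),
               match(sub("\\+.*", "", names(cells)), g))
  cells <- cells[ord]

  structure(list(
    cells = cells,
    membership = membership,
    group_totals = colSums(mem),
    exclusive = colSums(mem[rowSums(mem) == 1L, , drop = FALSE]),
    union_size = nrow(mem),
    rule = if (rule == "min_total") sprintf("min_total>=%g", min_total)
           else rule),
    class = "detection_partition")
}

#' @export
print.detection_partition <- function(x, ...) {
  cat(sprintf("detection partition (rule: %s): %d detected miRNAs\n",
              x$rule, x$union_size))
  df <- data.frame(detected = x$group_totals, exclusive = x$exclusive)
  print(df)
  shared <- sum(rowSums(x$membership) == ncol(x$membership))
  cat(sprintf("detected in all %d groups: %d\n", ncol(x$membership), shared))
  invisible(x)
}

#' Rank per-group miRNA abundance and flag shared/unique top features
#'
#' Ranks features within each group by mean CPM across that group's
#' replicates (ties broken by lexicographic feature ID so rankings are
#' reproducible) and reports the top `k` with mean and SD. A feature is
#' `common_abundant` if it makes the top `k` of every group and
#' `uniquely_abundant` if it makes the top `k` of exactly one.
#'
#' @param cpm_matrix CPM matrix from [cpm].
#' @param groups factor of group labels, one per column of `cpm_matrix`.
#' @param k list length per group (default 20).
#' @return list of class `abundance_ranking`: `top` (named list of per-group
#'   data frames: feature, mean_cpm, sd_cpm, rank), `flags` (data frame:
#'   feature, n_groups_topk, common_abundant, uniquely_abundant), `k`.
#' @export
rank_abundance <- function(cpm_matrix, groups, k = 20L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop_config("k must be a positive integer")
  }
  k <- as.integer(k)
  groups <- as.factor(groups)
  if (length(groups) != ncol(cpm_matrix)) {
    stop_config("groups must have one label per sample column")
  }
  g <- levels(groups)
  top <- lapply(g, function(gr) {
    sub <- cpm_matrix[, groups == gr, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1L, sd)
    ord <- order(-mu, rownames(cpm_matrix))
    idx <- ord[seq_len(min(k, length(ord)))]
    data.frame(feature = rownames(cpm_matrix)[idx],
               mean_cpm = mu[idx], sd_cpm = sdv[idx],
               rank = seq_along(idx),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(top) <- g

  in_top <- vapply(top, function(t) rownames(cpm_matrix) %in% t$feature,
                   logical(nrow(cpm_matrix)))
  n_top <- rowSums(in_top)
  keep <- n_top > 0
  flags <- data.frame(feature = rownames(cpm_matrix)[keep],
                      n_groups_topk = n_top[keep],
                      common_abundant = n_top[keep] == length(g),
                      uniquely_abundant = n_top[keep] == 1L,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(top = top, flags = flags, k = k,
                 in_top = in_top[keep, , drop = FALSE]),
            class = "abundance_ranking")
}

#' @export
print.abundance_ranking <- function(x, ...) {
  cat(sprintf("top-%d abundance ranking over %d groups\n", x$k,
              length(x$top)))
  for (g in names(x$top)) {
    t3 <- head(x$top[[g]], 3L)
    cat(sprintf("  %s: %s ...\n", g,
                paste(sprintf("%s (%.0f CPM)", t3$feature, t3$mean_cpm),
                      collapse = ", ")))
  }
  cat(sprintf("  common to all top lists: %d; unique to one: %d\n",
              sum(x$flags$common_abundant), sum(x$flags$uniquely_abundant)))
  invisible(x)
}
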