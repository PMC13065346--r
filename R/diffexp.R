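#' Per-feature negative-binomial dispersion estimates
#'
#' Dispersion estimation shares information across features in three
#' steps, pooling all groups so that genuine group effects do not inflate
#' the estimate:
#'
#' 1. A method-of-moments starting value per feature,
#'    alpha_mom = (pooled within-group variance - mu * mean(1/s)) / mu^2,
#'    the moment solution of Var(K/s) = mu/s + alpha * mu^2.
#' 2. A mean-dispersion trend: a gamma GLM of alpha_mom on log mean (log
#'    link), refitted once after trimming gross outliers. The gamma family
#'    targets the conditional mean of the dispersion; median- or log-scale
#'    centering would systematically underestimate it and inflate Wald
#'    statistics.
#' 3. A maximum a-posteriori estimate per feature: the Cox-Reid-adjusted
#'    negative-binomial profile log-likelihood (group means profiled out)
#'    plus a normal prior on log alpha centered at the trend, maximized on
#'    a log-dispersion grid with quadratic refinement. The prior variance
#'    is estimated from the spread of log(alpha_mom) around the trend in
#'    excess of the expected chi-square sampling noise (floored at 0.25).
#'
#' The likelihood/prior combination is what controls the far tail of the
#' Wald null distribution: a feature whose moment estimate collapses by
#' chance carries almost no likelihood evidence against a larger
#' dispersion, so the prior pulls it back to the trend instead of
#' manufacturing a tiny p-value. Estimates are floored at `floor`;
#' all-zero features receive the floor.
#'
#' @param counts raw count matrix (features x samples).
#' @param groups factor of group labels per sample.
#' @param size_factors_vec per-sample size factors; defaults to 1.
#' @param floor minimum dispersion.
#' @return list of class `dispersion_estimate`: `alpha` (final MAP,
#'   floored), `mom`, `trend`, `mean` (per-feature mean normalized count),
#'   `prior_var`.
#' @export
estimate_dispersions <- function(counts, groups,
                                 size_factors_vec = NULL, floor = 1e-8) {
  groups <- as.factor(groups)
  n <- nrow(counts)
  m <- ncol(counts)
  s <- size_factors_vec %||% rep(1, m)
  normalized <- sweep(counts, 2L, s, `/`)
  mu <- rowMeans(normalized)

  ss <- numeric(n)
  df_tot <- 0L
  for (g in levels(groups)) {
    sub <- normalized[, groups == g, drop = FALSE]
    ng <- ncol(sub)
    if (ng < 2L) next
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df_tot <- df_tot + (ng - 1L)
  }
  if (df_tot == 0L) stop_degenerate("every group has a single replicate")
  v_within <- ss / df_tot

  mom <- ifelse(mu > 0, (v_within - mu * mean(1 / s)) / mu^2, NA_real_)

  fit_ok <- is.finite(mom) & mom > floor & mu > 0
  trend <- rep(NA_real_, n)
  if (sum(fit_ok) >= 10L) {
    fit_trend <- function(idx) {
      fit <- tryCatch(
        stats::glm(mom[idx] ~ log(mu[idx]),
                   family = stats::Gamma(link = "log")),
        error = function(e) NULL)
      if (is.null(fit) || !all(is.finite(coef(fit)))) return(NULL)
      coef(fit)
    }
    cf <- fit_trend(which(fit_ok))
    if (!is.null(cf)) {  # trim gross outliers, refit once
      pred <- exp(cf[1] + cf[2] * log(mu))
      ratio <- mom / pred
      keep <- which(fit_ok & ratio < 15 & ratio > 1e-4)
      if (length(keep) >= 10L) {
        cf2 <- fit_trend(keep)
        if (!is.null(cf2)) cf <- cf2
      }
      trend[mu > 0] <- exp(cf[1] + cf[2] * log(mu[mu > 0]))
    }
  }
  if (all(is.na(trend))) {  # degenerate fallback: flat center
    ctr <- if (any(fit_ok)) mean(mom[fit_ok]) else 0.1
    trend[mu > 0] <- ctr
  }

  # prior width: spread of log mom around the trend beyond sampling noise
  res <- log(mom[fit_ok]) - log(trend[fit_ok])
  samp_var <- trigamma(max(df_tot, 2) / 2)
  prior_var <- max(0.25,
                   if (length(res) >= 10L) {
                     (stats::mad(res))^2 - samp_var
                   } else 0.25)

  alpha <- cr_map_dispersion(counts, groups, s, trend, prior_var, floor)
  structure(list(alpha = alpha, mom = mom, trend = trend, mean = mu,
                 prior_var = prior_var),
            class = "dispersion_estimate")
}

# Maximize the Cox-Reid-adjusted NB profile log-likelihood plus a normal
# prior on log(alpha) centered at log(trend), on a log-alpha grid with one
# quadratic interpolation step. Group means are profiled out by the
# ratio-of-sums estimate mu_g = sum(K)/sum(s), which is alpha-independent.
cr_map_dispersion <- function(counts, groups, s, trend, prior_var, floor) {
  n <- nrow(counts)
  gidx <- split(seq_along(s), groups)
  fitted <- matrix(0, n, ncol(counts))
  for (g in gidx) {
    mu_g <- rowSums(counts[, g, drop = FALSE]) / sum(s[g])
    fitted[, g] <- outer(mu_g, s[g])
  }
  active <- rowSums(counts) > 0
  if (!any(active)) return(rep(floor, n))
  K <- counts[active, , drop = FALSE]
  MU <- pmax(fitted[active, , drop = FALSE], 1e-10)
  ltr <- log(pmax(trend[active], 1e-6))
  gmat <- vapply(gidx, function(g) {
    v <- numeric(ncol(K)); v[g] <- 1; v
  }, numeric(ncol(K)))

  grid <- seq(log(1e-4), log(40), length.out = 49L)
  obj <- matrix(NA_real_, nrow(K), length(grid))
  for (k in seq_along(grid)) {
    a <- exp(grid[k])
    ll <- rowSums(stats::dnbinom(K, mu = MU, size = 1 / a, log = TRUE))
    w <- MU / (1 + a * MU)
    cr <- -0.5 * rowSums(log(w %*% gmat + 1e-10))
    obj[, k] <- ll + cr - (grid[k] - ltr)^2 / (2 * prior_var)
  }
  best <- max.col(obj, ties.method = "first")
  # quadratic refinement around the grid maximum
  h <- grid[2] - grid[1]
  inner <- best > 1L & best < length(grid)
  la <- grid[best]
  if (any(inner)) {
    i <- which(inner)
    idx <- cbind(i, best[inner])
    y0 <- obj[cbind(i, best[inner] - 1L)]
    y1 <- obj[idx]
    y2 <- obj[cbind(i, best[inner] + 1L)]
    denom <- y0 - 2 * y1 + y2
    shift <- ifelse(denom < 0, 0.5 * h * (y0 - y2) / denom, 0)
    la[inner] <- grid[best[inner]] + pmax(pmin(shift, h), -h)
  }
  alpha <- rep(floor, n)
  alpha[active] <- pmax(exp(la), floor)
  alpha
}

#' All-pairwise negative-binomial Wald differential expression
#'
#' For every unordered pair of groups and every feature, compares NB means
#' fitted on the size-factor-normalized scale. The log2 fold change is
#' log2((mean_A + eps) / (mean_B + eps)) with a pseudo-mass of eps = 0.5
#' counts guarding zero means; its standard error comes from the NB
#' observed information for a log-mean parameter,
#' I_g = sum_j s_j m_g / (1 + alpha s_j m_g), giving
#' SE = sqrt(1/I_A + 1/I_B) / ln 2. The Wald statistic is referred to the
#' standard normal, two-sided, and Benjamini-Hochberg adjustment is applied
#' within each pairwise table separately. There is no outlier replacement,
#' no independent filtering and no fold-change shrinkage; size factors and
#' dispersions are estimated once on the full matrix, all groups together.
#'
#' @param x an [ev_counts] object (>= 2 replicates per group).
#' @param normalization result of [size_factors] on `x`; computed if NULL.
#' @param dispersions result of [estimate_dispersions]; computed if NULL.
#' @param eps pseudo-mass (in normalized counts) added to group means.
#' @return named list of class `de_result` with one data frame per pair
#'   (`"A_vs_B"`, A before B in group-level order; log2FC is A relative to
#'   B): columns `feature`, `baseMean`, `log2FC`, `SE`, `stat`, `pvalue`,
#'   `FDR`. Features with zero counts in both groups of a pair get
#'   log2FC = 0 and p = 1.
#' @export
fit_pairwise <- function(x, normalization = NULL, dispersions = NULL,
                         eps = 0.5) {
  groups <- x$groups
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    stop_config("every group needs >= 2 replicates; offending: ",
                paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  normalization <- normalization %||% size_factors(x)
  s <- normalization$size_factors
  norm <- normalization$normalized
  dispersions <- dispersions %||%
    estimate_dispersions(x$counts, groups, size_factors_vec = s)
  alpha <- dispersions$alpha

  g <- levels(groups)
  base_mean <- rowMeans(norm)
  means <- vapply(g, function(gr) rowMeans(norm[, groups == gr, drop = FALSE]),
                  numeric(nrow(norm)))
  # observed information per group, using eps-guarded means
  info <- vapply(g, function(gr) {
    sg <- s[groups == gr]
    m <- means[, gr] + eps
    rowSums(vapply(sg, function(sj) sj * m / (1 + alpha * sj * m),
                   numeric(length(m))))
  }, numeric(nrow(norm)))

  pairs <- utils::combn(g, 2L)
  out <- vector("list", ncol(pairs))
  names(out) <- apply(pairs, 2L, paste, collapse = "_vs_")
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    lfc <- log2((means[, a] + eps) / (means[, b] + eps))
    se <- sqrt(1 / info[, a] + 1 / info[, b]) / log(2)
    stat <- lfc / se
    p <- 2 * pnorm(-abs(stat))
    dead <- means[, a] == 0 & means[, b] == 0
    lfc[dead] <- 0; stat[dead] <- 0; p[dead] <- 1
    out[[k]] <- data.frame(feature = rownames(norm),
                           baseMean = base_mean,
                           log2FC = lfc, SE = se, stat = stat,
                           pvalue = p, FDR = adjust_fdr(p),
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(out, class = c("de_result", "list"))
}

#' @export
print.de_result <- function(x, alpha = 0.05, ...) {
  cat("pairwise NB Wald differential expression\n")
  for (nm in names(x)) {
    t <- x[[nm]]
    cat(sprintf("  %s: %d up, %d down at FDR < %g\n", nm,
                sum(t$FDR < alpha & t$log2FC > 0),
                sum(t$FDR < alpha & t$log2FC < 0), alpha))
  }
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order, monotone-enforced and
#'   capped at 1.
#' @export
adjust_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop_config("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * pvalues[o]))[ro]
}

#' Extract significantly upregulated features for one side of a pair
#'
#' @param de a `de_result` list from [fit_pairwise].
#' @param group the subtype whose upregulated features are wanted.
#' @param other the comparison subtype.
#' @param alpha FDR threshold.
#' @param lfc_min minimum log2 fold change in favor of `group`.
#' @return character vector of feature IDs.
#' @export
upregulated_in <- function(de, group, other, alpha = 0.05, lfc_min = 0) {
  key_ab <- paste0(group, "_vs_", other)
  key_ba <- paste0(other, "_vs_", group)
  if (key_ab %in% names(de)) {
    t <- de[[key_ab]]
    t$feature[t$FDR < alpha & t$log2FC > lfc_min]
  } else if (key_ba %in% names(de)) {
    t <- de[[key_ba]]
    t$feature[t$FDR < alpha & -t$log2FC > lfc_min]
  } else {
    stop_format("no DE table for pair ", group, " / ", other)
  }
}
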