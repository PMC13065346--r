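#' Assess distributional assumptions for grouped measurements
#'
#' Computes, per group, Shapiro-Wilk normality p-values on the raw and
#' (for strictly positive data) natural-log scale, plus a spread test:
#' the Brown-Forsythe test (Levene's test with median centering) for
#' multi-group designs, the F test of variance ratio for two-group designs
#' (on both scales where defined). Predicates are derived at level `alpha`:
#' normality/lognormality pass only if every group's Shapiro-Wilk p is
#' >= alpha on the respective scale; groups with fewer than 3 observations
#' make the Shapiro-Wilk test inapplicable and are flagged
#' (`insufficient_n`), in which case normality is treated as failed.
#'
#' @param table data frame with columns `group` and `value` (a `sample`
#'   column is allowed and ignored here).
#' @param alpha predicate significance level.
#' @return list of class `assumption_report` with per-group p-values,
#'   spread-test p-values (`spread_p_raw`, `spread_p_log`) and predicates
#'   `normality_pass`, `lognormality_pass`, `equal_sd`, `equal_sd_log`,
#'   `insufficient_n`, plus `design` (`"two_group"` or `"multi_group"`).
#' @export
assess_assumptions <- function(table, alpha = 0.05) {
  check_measurement_table(table)
  groups <- split(table$value, factor(table$group))
  g <- length(groups)
  design <- if (g == 2L) "two_group" else "multi_group"
  insufficient <- vapply(groups, function(v) length(v) < 3L, logical(1))
  all_positive <- all(table$value > 0)

  sw <- function(v) {
    if (length(v) < 3L || length(unique(v)) == 1L) return(NA_real_)
    tryCatch(shapiro.test(v)$p.value, error = function(e) NA_real_)
  }
  shapiro_raw <- vapply(groups, sw, numeric(1))
  shapiro_log <- if (all_positive) {
    vapply(groups, function(v) sw(log(v)), numeric(1))
  } else {
    setNames(rep(NA_real_, g), names(groups))
  }

  spread_raw <- spread_test(table$value, table$group, design)
  spread_log <- if (all_positive) {
    spread_test(log(table$value), table$group, design)
  } else NA_real_

  pass <- function(p) !any(insufficient) && all(!is.na(p)) && all(p >= alpha)
  structure(list(
    design = design,
    alpha = alpha,
    shapiro_raw = shapiro_raw,
    shapiro_log = shapiro_log,
    spread_p_raw = spread_raw,
    spread_p_log = spread_log,
    insufficient_n = insufficient,
    normality_pass = pass(shapiro_raw),
    lognormality_pass = all_positive && pass(shapiro_log),
    equal_sd = !is.na(spread_raw) && spread_raw >= alpha,
    equal_sd_log = !is.na(spread_log) && spread_log >= alpha),
    class = "assumption_report")
}

check_measurement_table <- function(table) {
  if (!is.data.frame(table) || !all(c("group", "value") %in% names(table))) {
    stop_format("measurement table needs columns 'group' and 'value'")
  }
  if (any(!is.finite(table$value))) stop_format("values must be finite")
  sizes <- table(table$group)
  if (length(sizes) < 2L) stop_format("need at least 2 groups")
  if (any(sizes < 2L)) stop_format("every group needs >= 2 observations")
  invisible(TRUE)
}

# Two groups: F test of variance ratio; more: Brown-Forsythe (Levene,
# median-centered). Returns NA for degenerate inputs.
spread_test <- function(values, group, design) {
  group <- factor(group)
  if (design == "two_group") {
    v <- split(values, group)
    if (var(v[[1]]) == 0 || var(v[[2]]) == 0) return(NA_real_)
    return(var.test(v[[1]], v[[2]])$p.value)
  }
  z <- abs(values - ave(values, group, FUN = median))
  if (all(z == 0)) return(NA_real_)
  fit <- aov(z ~ group)
  summary(fit)[[1]][["Pr(>F)"]][1]
}

#' Select the statistical route implied by an assumption report
#'
#' Deterministic mapping from assumption predicates to a named test route:
#'
#' * multi-group: normality and equal SDs -> `anova_tukey`; normality but
#'   unequal SDs -> `welch_bf_dunnettT3` (Brown-Forsythe and Welch ANOVA
#'   with Dunnett T3 comparisons); normality failed -> `kruskal_dunn`.
#' * two-group, `scale_hint = "lognormal_candidate"` (multiplicative data
#'   such as vessel-network metrics): lognormality and equal SDs on the
#'   log scale -> `lognormal_t`; lognormality but unequal SDs ->
#'   `lognormal_welch`; lognormality failed -> `mann_whitney`.
#' * two-group, `scale_hint = "dimensionless_index"` or `"raw"`: normality
#'   and equal SDs -> `unpaired_t`; normality but unequal SDs ->
#'   `welch_t`; normality failed -> `mann_whitney`.
#'
#' @param report an `assumption_report` from [assess_assumptions].
#' @param design `"multi_group"` or `"two_group"`; defaults to the
#'   report's.
#' @param scale_hint `"raw"`, `"lognormal_candidate"` or
#'   `"dimensionless_index"` (two-group designs only).
#' @return route label (character scalar).
#' @export
select_route <- function(report,
                         design = report$design,
                         scale_hint = c("raw", "lognormal_candidate",
                                        "dimensionless_index")) {
  scale_hint <- match.arg(scale_hint)
  if (!design %in% c("multi_group", "two_group")) {
    stop_config("unknown design: ", design)
  }
  if (!is.null(report$design) && report$design != design) {
    stop_config("assumption report was computed for a ", report$design,
                " design")
  }
  if (design == "multi_group") {
    if (report$normality_pass) {
      if (report$equal_sd) "anova_tukey" else "welch_bf_dunnettT3"
    } else {
      "kruskal_dunn"
    }
  } else if (scale_hint == "lognormal_candidate") {
    if (report$lognormality_pass) {
      if (report$equal_sd_log) "lognormal_t" else "lognormal_welch"
    } else {
      "mann_whitney"
    }
  } else {
    if (report$normality_pass) {
      if (report$equal_sd) "unpaired_t" else "welch_t"
    } else {
      "mann_whitney"
    }
  }
}

#' Run a grouped comparison along a named route
#'
#' Executes the omnibus test and (for multi-group routes) the post-hoc
#' procedure of the selected route, returning adjusted pairwise p-values
#' with significance stars at 0.05 / 0.01 / 0.001. Log routes apply the
#' corresponding t-test variant to natural-log-transformed values.
#' Dunnett's T3 comparisons are computed as Welch t statistics with a
#' Sidak (studentized-maximum-modulus, independence form) adjustment;
#' Dunn's comparisons use rank sums with tie correction and Bonferroni
#' adjustment.
#'
#' @param table data frame with columns `group` and `value`.
#' @param route route label from [select_route].
#' @return list of class `route_result`: `route`, `omnibus_p` (and
#'   `omnibus_p_bf` for the Welch route: the Brown-Forsythe adjusted-df
#'   ANOVA), `posthoc` (data frame: group1, group2, estimate, p_adj,
#'   stars) covering all pairs for multi-group routes, one row for
#'   two-group routes.
#' @export
run_comparison <- function(table, route) {
  check_measurement_table(table)
  routes <- c("anova_tukey", "welch_bf_dunnettT3", "kruskal_dunn",
              "unpaired_t", "welch_t", "lognormal_t", "lognormal_welch",
              "mann_whitney")
  if (!route %in% routes) stop_config("unknown route: ", route)
  grp <- factor(table$group)
  values <- table$value
  if (grepl("^lognormal", route)) {
    if (any(values <= 0)) {
      bad <- which(values <= 0)[1L]
      stop_format("log route requires positive values; observation ", bad,
                  " is ", values[bad])
    }
    values <- log(values)
  }
  parametric <- route %in% c("anova_tukey", "welch_bf_dunnettT3",
                             "unpaired_t", "welch_t", "lognormal_t",
                             "lognormal_welch")
  if (parametric && any(tapply(values, grp, var) == 0)) {
    stop_degenerate("a group has zero variance; parametric route '",
                    route, "' is degenerate")
  }
  two <- nlevels(grp) == 2L
  if (route %in% c("unpaired_t", "welch_t", "lognormal_t",
                   "lognormal_welch", "mann_whitney") && !two) {
    stop_config("route '", route, "' requires exactly 2 groups")
  }

  res <- switch(route,
    anova_tukey = {
      fit <- aov(values ~ grp)
      tuk <- TukeyHSD(fit)$grp
      list(omnibus_p = summary(fit)[[1]][["Pr(>F)"]][1],
           posthoc = data.frame(
             pair = rownames(tuk),
             estimate = tuk[, "diff"],
             p_adj = tuk[, "p adj"],
             row.names = NULL))
    },
    welch_bf_dunnettT3 = {
      welch <- oneway.test(values ~ grp, var.equal = FALSE)
      ph <- pairwise_welch_sidak(values, grp)
      list(omnibus_p = welch$p.value,
           omnibus_p_bf = brown_forsythe_anova(values, grp),
           posthoc = ph)
    },
    kruskal_dunn = {
      kw <- kruskal.test(values, grp)
      list(omnibus_p = kw$p.value, posthoc = dunn_posthoc(values, grp))
    },
    unpaired_t = two_sample(values, grp, var.equal = TRUE),
    welch_t = two_sample(values, grp, var.equal = FALSE),
    lognormal_t = two_sample(values, grp, var.equal = TRUE),
    lognormal_welch = two_sample(values, grp, var.equal = FALSE),
    mann_whitney = {
      v <- split(values, grp)
      w <- suppressWarnings(wilcox.test(v[[1]], v[[2]]))
      list(omnibus_p = w$p.value,
           posthoc = data.frame(
             pair = paste(levels(grp)[2:1], collapse = "-"),
             estimate = median(v[[1]]) - median(v[[2]]),
             p_adj = w$p.value))
    })

  ph <- res$posthoc
  pairbits <- strsplit(as.character(ph$pair), "-", fixed = TRUE)
  ph$group1 <- vapply(pairbits, `[`, "", 1L)
  ph$group2 <- vapply(pairbits, `[`, "", 2L)
  ph$stars <- stars_for(ph$p_adj)
  ph <- ph[, c("group1", "group2", "estimate", "p_adj", "stars")]
  structure(list(route = route,
                 omnibus_p = res$omnibus_p,
                 omnibus_p_bf = res$omnibus_p_bf,
                 posthoc = ph),
            class = "route_result")
}

#' @export
print.route_result <- function(x, ...) {
  cat(sprintf("route: %s; omnibus p = %.4g\n", x$route, x$omnibus_p))
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

stars_for <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns")))
}

two_sample <- function(values, grp, var.equal) {
  v <- split(values, grp)
  tt <- t.test(v[[1]], v[[2]], var.equal = var.equal)
  list(omnibus_p = tt$p.value,
       posthoc = data.frame(
         pair = paste(levels(grp)[2:1], collapse = "-"),
         estimate = mean(v[[1]]) - mean(v[[2]]),
         p_adj = tt$p.value))
}

# Brown-Forsythe ANOVA (adjusted-df F*), distinct from the Levene-type
# spread test of the same name.
brown_forsythe_anova <- function(values, grp) {
  v <- split(values, grp)
  n <- lengths(v); N <- sum(n); xb <- vapply(v, mean, 0)
  s2 <- vapply(v, var, 0)
  num <- sum(n * (xb - mean(values))^2)
  den_terms <- (1 - n / N) * s2
  fstat <- num / sum(den_terms)
  c_i <- den_terms / sum(den_terms)
  df2 <- 1 / sum(c_i^2 / (n - 1))
  pf(fstat, length(v) - 1, df2, lower.tail = FALSE)
}

pairwise_welch_sidak <- function(values, grp, ...) {
  v <- split(values, grp)
  combos <- utils::combn(names(v), 2L)
  m <- ncol(combos)
  out <- lapply(seq_len(m), function(k) {
    a <- combos[1, k]; b <- combos[2, k]
    tt <- t.test(v[[b]], v[[a]], var.equal = FALSE)
    data.frame(pair = paste0(b, "-", a),
               estimate = mean(v[[b]]) - mean(v[[a]]),
               p_adj = min(1, 1 - (1 - tt$p.value)^m))
  })
  do.call(rbind, out)
}

dunn_posthoc <- function(values, grp) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v <- split(r, grp)
  n <- lengths(v)
  rb <- vapply(v, mean, 0)
  combos <- utils::combn(names(v), 2L)
  m <- ncol(combos)
  out <- lapply(seq_len(m), function(k) {
    a <- combos[1, k]; b <- combos[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (rb[[b]] - rb[[a]]) / se
    data.frame(pair = paste0(b, "-", a),
               estimate = rb[[b]] - rb[[a]],
               p_adj = min(1, 2 * pnorm(-abs(z)) * m))
  })
  do.call(rbind, out)
}

#' One-call assumption-routed comparison
#'
#' Convenience wrapper: [assess_assumptions], [select_route],
#' [run_comparison] in sequence, returning the full decision trail.
#'
#' @inheritParams assess_assumptions
#' @inheritParams select_route
#' @return list with `assumptions`, `route`, `result`.
#' @export
group_stats <- function(table, scale_hint = "raw", alpha = 0.05) {
  rep <- assess_assumptions(table, alpha = alpha)
  route <- select_route(rep, scale_hint = scale_hint)
  list(assumptions = rep, route = route,
       result = run_comparison(table, route))
}
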