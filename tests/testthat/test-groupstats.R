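gauss_table <- function(seed = 1, n = 10, means = c(0, 0), sds = c(1, 1),
                        labels = c("ctrl", "ev")) {
  set.seed(seed)
  data.frame(group = rep(labels, each = n),
             value = unlist(lapply(seq_along(means),
                                   function(i) rnorm(n, means[i], sds[i]))))
}

test_that("assumption predicates match direct computation on a fixture", {
  tab <- gauss_table(seed = 101, n = 10)
  rep <- assess_assumptions(tab)
  v <- split(tab$value, tab$group)
  expect_equal(rep$shapiro_raw[["ctrl"]], shapiro.test(v$ctrl)$p.value)
  expect_equal(rep$shapiro_raw[["ev"]], shapiro.test(v$ev)$p.value)
  expect_equal(rep$spread_p_raw, var.test(v[[1]], v[[2]])$p.value)
  expect_identical(rep$normality_pass, all(vapply(v, function(x)
    shapiro.test(x)$p.value, 0) >= 0.05))
  expect_identical(rep$equal_sd, var.test(v[[1]], v[[2]])$p.value >= 0.05)
})

test_that("small groups trip the insufficient-n flag and fail normality", {
  tab <- data.frame(group = c("a", "a", "b", "b", "b"),
                    value = c(1.2, 1.4, 2.1, 2.2, 2.0))
  rep <- assess_assumptions(tab)
  expect_true(rep$insufficient_n[["a"]])
  expect_false(rep$normality_pass)
  expect_identical(select_route(rep, scale_hint = "dimensionless_index"),
                   "mann_whitney")
})

test_that("identical groups have equal spread", {
  tab <- data.frame(group = rep(c("a", "b"), each = 4),
                    value = rep(c(1.3, 2.7, 3.1, 0.9), 2))
  rep <- assess_assumptions(tab)
  expect_true(rep$equal_sd)
})

test_that("route selection is total and deterministic over all predicates", {
  mk <- function(normal, lognormal, equal_sd, equal_sd_log,
                 design = "multi_group") {
    structure(list(design = design, normality_pass = normal,
                   lognormality_pass = lognormal, equal_sd = equal_sd,
                   equal_sd_log = equal_sd_log),
              class = "assumption_report")
  }
  for (normal in c(TRUE, FALSE)) {
    for (lognormal in c(TRUE, FALSE)) {
      for (eq in c(TRUE, FALSE)) {
        for (eql in c(TRUE, FALSE)) {
          multi <- select_route(mk(normal, lognormal, eq, eql))
          expect_identical(multi,
                           if (normal && eq) "anova_tukey"
                           else if (normal) "welch_bf_dunnettT3"
                           else "kruskal_dunn")
          two_log <- select_route(mk(normal, lognormal, eq, eql,
                                     "two_group"),
                                  scale_hint = "lognormal_candidate")
          expect_identical(two_log,
                           if (lognormal && eql) "lognormal_t"
                           else if (lognormal) "lognormal_welch"
                           else "mann_whitney")
          two_raw <- select_route(mk(normal, lognormal, eq, eql,
                                     "two_group"),
                                  scale_hint = "dimensionless_index")
          expect_identical(two_raw,
                           if (normal && eq) "unpaired_t"
                           else if (normal) "welch_t"
                           else "mann_whitney")
        }
      }
    }
  }
  expect_error(select_route(mk(TRUE, TRUE, TRUE, TRUE), design = "nested"),
               class = "mirland_config_error")
})

test_that("anova_tukey matches hand-computed F and ptukey oracle", {
  set.seed(55)
  tab <- data.frame(group = rep(c("a", "b", "c", "d"), each = 6),
                    value = rnorm(24, rep(c(0, 0.5, 1, 0), each = 6)))
  res <- run_comparison(tab, "anova_tukey")
  expect_identical(nrow(res$posthoc), 6L)

  # omnibus F by the textbook formula
  v <- split(tab$value, tab$group)
  n <- lengths(v); N <- sum(n); k <- length(v)
  ssb <- sum(n * (vapply(v, mean, 0) - mean(tab$value))^2)
  ssw <- sum(unlist(lapply(v, function(x) (x - mean(x))^2)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(res$omnibus_p, pf(f, k - 1, N - k, lower.tail = FALSE),
               tolerance = 1e-9)

  # Tukey adjusted p for one pair from the studentized range distribution
  mse <- ssw / (N - k)
  q <- abs(mean(v$b) - mean(v$a)) / sqrt(mse / 2 * (1 / 6 + 1 / 6))
  p_tukey <- ptukey(q, k, N - k, lower.tail = FALSE)
  row <- res$posthoc[res$posthoc$group1 == "b" & res$posthoc$group2 == "a", ]
  expect_equal(row$p_adj, p_tukey, tolerance = 1e-6)
})

test_that("lognormal routes are t-tests on the log scale", {
  set.seed(77)
  z <- data.frame(group = rep(c("a", "b"), each = 8),
                  value = rnorm(16, rep(c(1, 2), each = 8), 0.3))
  tab <- transform(z, value = exp(value))
  res <- run_comparison(tab, "lognormal_t")
  oracle <- t.test(log(value) ~ group, data = tab, var.equal = TRUE)
  expect_equal(res$omnibus_p, oracle$p.value, tolerance = 1e-12)
  res_w <- run_comparison(tab, "lognormal_welch")
  oracle_w <- t.test(log(value) ~ group, data = tab)
  expect_equal(res_w$omnibus_p, oracle_w$p.value, tolerance = 1e-12)

  tab$value[1] <- -1
  expect_error(run_comparison(tab, "lognormal_t"), "positive",
               class = "mirland_format_error")
})

test_that("kruskal_dunn and welch routes produce complete post-hoc tables", {
  set.seed(88)
  tab <- data.frame(group = rep(c("a", "b", "c"), each = 5),
                    value = c(rexp(5), rexp(5, 0.3), rexp(5, 2)))
  kd <- run_comparison(tab, "kruskal_dunn")
  expect_equal(kd$omnibus_p, kruskal.test(tab$value, factor(tab$group))$p.value)
  expect_identical(nrow(kd$posthoc), 3L)
  expect_true(all(kd$posthoc$p_adj >= 0 & kd$posthoc$p_adj <= 1))

  wf <- run_comparison(tab, "welch_bf_dunnettT3")
  expect_identical(nrow(wf$posthoc), 3L)
  expect_equal(wf$omnibus_p,
               oneway.test(value ~ group, tab, var.equal = FALSE)$p.value)
  expect_true(is.numeric(wf$omnibus_p_bf))

  degenerate <- data.frame(group = rep(c("a", "b"), each = 3),
                           value = c(1, 1, 1, 2, 3, 4))
  expect_error(run_comparison(degenerate, "unpaired_t"),
               class = "mirland_degenerate_error")
})

test_that("parametric routes hold their nominal size under the null", {
  set.seed(202)
  rej <- vapply(1:400, function(i) {
    tab <- data.frame(group = rep(c("a", "b", "c"), each = 6),
                      value = rnorm(18))
    run_comparison(tab, "anova_tukey")$omnibus_p < 0.05
  }, logical(1))
  bounds <- qbinom(c(0.005, 0.995), 400, 0.05) / 400
  expect_gte(mean(rej), bounds[1])
  expect_lte(mean(rej), bounds[2])
})

test_that("group_stats wires assumptions to a sensible route end to end", {
  tab <- gauss_table(seed = 303, n = 12)
  out <- group_stats(tab, scale_hint = "dimensionless_index")
  expect_identical(out$route,
                   select_route(out$assumptions,
                                scale_hint = "dimensionless_index"))
  expect_identical(nrow(out$result$posthoc), 1L)
})
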