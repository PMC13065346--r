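test_that("tau closed forms evaluate exactly", {
  expect_equal(compute_tau(c(3, 3, 3, 3)), 0)
  expect_equal(compute_tau(c(7, 0, 0, 0)), 1)
  expect_equal(compute_tau(c(10, 5, 0, 5)), 2 / 3)
  expect_true(is.na(compute_tau(c(0, 0, 0, 0))))
  expect_error(compute_tau(5), class = "mirland_config_error")
  expect_error(compute_tau(c(-1, 2)), class = "mirland_config_error")
})

test_that("tau is scale-invariant and rewards concentration", {
  set.seed(20)
  profiles <- matrix(rexp(500 * 4), 500, 4)
  tau <- compute_tau(profiles)
  expect_true(all(tau >= 0 & tau <= 1))
  scaled <- compute_tau(profiles * 1e3)
  expect_equal(tau, scaled, tolerance = 1e-14)
  # moving mass from a non-maximal group to the maximal group raises tau
  for (i in 1:50) {
    p <- profiles[i, ]
    j_max <- which.max(p)
    j_min <- which.min(replace(p, j_max, Inf))
    delta <- p[j_min] / 2
    p2 <- p; p2[j_min] <- p2[j_min] - delta; p2[j_max] <- p2[j_max] + delta
    expect_gte(compute_tau(p2), compute_tau(p))
  }
})

test_that("tau_table computes per-group means on the normalized scale", {
  cfg <- sim_config(n_features = 100, seed = 19L)
  x <- simulate_counts(cfg)$counts
  norm <- size_factors(x)
  tt <- tau_table(norm$normalized, sample_groups(x))
  f <- tt$feature[10]
  gr <- sample_groups(x)
  expect_equal(tt$mean_Mac[10],
               mean(norm$normalized[f, gr == "Mac"]))
  expect_true(all(tt$tau >= 0 & tt$tau <= 1, na.rm = TRUE))
})

test_that("classify_key applies the three-criteria conjunction", {
  groups <- c("CM", "CF", "HCMVEC", "Mac")
  feats <- c("hsa-miR-key-5p", "hsa-miR-tauonly-5p", "hsa-miR-fc2-5p")
  # DE truth: key feature strongly up in Mac vs all; fc2 has FC > 5 in
  # exactly two Mac comparisons; tauonly never significant
  lfc <- list(); fdr <- list()
  for (o in c("CM", "CF", "HCMVEC")) {
    nm <- paste0(o, "_vs_Mac")
    lfc[[nm]] <- c(-3, 0, if (o == "HCMVEC") 0 else -2.5)
    fdr[[nm]] <- c(0.001, 1, if (o == "HCMVEC") 1 else 0.001)
  }
  de <- fake_de_tables(feats, lfc, fdr, groups)

  cpm_m <- matrix(10, 3, 13, dimnames = list(feats, paste0("s", 1:13)))
  gfac <- factor(rep(groups, c(3, 3, 3, 4)), levels = groups)
  cpm_m[1, gfac == "Mac"] <- 5000   # abundant in Mac
  cpm_m[3, gfac == "Mac"] <- 3000
  rk <- rank_abundance(cpm_m, gfac, k = 2)

  tau <- data.frame(feature = feats, tau = c(0.85, 0.95, 0.5))
  sig <- classify_key(rk, de, tau)

  key_row <- sig[sig$feature == feats[1] & sig$subtype == "Mac", ]
  expect_true(key_row$abundant && key_row$upregulated && key_row$enriched)
  expect_true(key_row$key)
  expect_true(key_row$consensus_upregulated)

  # tau 0.95 but not abundant in any top list -> never key
  tau_row <- sig[sig$feature == feats[2] & sig$subtype == "Mac", ]
  expect_true(tau_row$enriched)
  expect_false(tau_row$abundant)
  expect_false(tau_row$key)

  # tau 0.5 with FC > 5 upward in exactly 2 significant comparisons
  fc_row <- sig[sig$feature == feats[3] & sig$subtype == "Mac", ]
  expect_identical(fc_row$n_fc_pairs, 2L)
  expect_true(fc_row$enriched)
  expect_false(fc_row$consensus_upregulated)

  expect_error(classify_key(rk, de, tau, alpha = 1.5),
               class = "mirland_config_error")
  expect_error(classify_key(rk, de, tau, fc_thresh = 0.9),
               class = "mirland_config_error")
})

test_that("consensus sets equal brute-force intersection of per-pair up-sets", {
  cfg <- sim_config(n_features = 400, de_fraction = 0.15, seed = 23L)
  sim <- simulate_counts(cfg)
  de <- fit_pairwise(sim$counts)
  for (g in group_names(sim$counts)) {
    oth <- setdiff(group_names(sim$counts), g)
    sets <- lapply(oth, function(o) upregulated_in(de, g, o, 0.05))
    expect_identical(consensus_upregulated(de, g),
                     sort(Reduce(intersect, sets)))
    # consensus implies upregulated in at least one pair
    expect_true(all(consensus_upregulated(de, g) %in% unlist(sets)))
  }
  # up in only 2 of 3 comparisons is excluded
  feats <- c("hsa-miR-x-5p")
  lfc <- list(Mac_vs_CM = 3, Mac_vs_CF = 3, Mac_vs_HCMVEC = 0)
  fdr <- list(Mac_vs_CM = 0.01, Mac_vs_CF = 0.01, Mac_vs_HCMVEC = 1)
  de2 <- fake_de_tables(feats, lfc, fdr, c("Mac", "CM", "CF", "HCMVEC"))
  expect_identical(consensus_upregulated(de2, "Mac"), character(0))
})

test_that("a planted abundant exclusive marker is recovered as key", {
  hits <- vapply(1:5, function(s) {
    cfg <- sim_config(n_features = 500, seed = s)
    sim <- simulate_counts(cfg)
    x <- plant_key_feature(sim$counts, "Mac")
    norm <- size_factors(x)
    de <- fit_pairwise(x, normalization = norm)
    tt <- tau_table(norm$normalized, sample_groups(x))
    rk <- rank_abundance(cpm(x), sample_groups(x))
    sig <- classify_key(rk, de, tt)
    any(sig$feature == "hsa-miR-9999-5p" & sig$subtype == "Mac" & sig$key)
  }, logical(1))
  expect_true(all(hits))
})
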