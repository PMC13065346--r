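test_that("identical group columns give log2FC = 0 and all-zero rows p = 1", {
  block <- matrix(rpois(20 * 2, 50), 20, 2)
  m <- cbind(block, block)
  m[5, ] <- 0  # dead feature
  rownames(m) <- paste0("hsa-miR-", 1:20, "-5p")
  colnames(m) <- c("A_1", "A_2", "B_1", "B_2")
  x <- ev_counts(m, c(A_1 = "A", A_2 = "A", B_1 = "B", B_2 = "B"))
  de <- fit_pairwise(x)
  expect_identical(names(de), "A_vs_B")
  expect_equal(de$A_vs_B$log2FC, rep(0, 20))
  expect_equal(de$A_vs_B$pvalue[5], 1)
  expect_equal(de$A_vs_B$log2FC[5], 0)
})

test_that("pair antisymmetry: reversing group order negates log2FC, keeps p", {
  cfg <- sim_config(n_features = 150, group_names = c("CM", "Mac"),
                    group_sizes = c(3L, 4L), seed = 6L)
  x <- simulate_counts(cfg)$counts
  de_ab <- fit_pairwise(x)
  m <- count_matrix(x)
  gr <- as.character(sample_groups(x))
  x_rev <- ev_counts(m, setNames(factor(gr, levels = c("Mac", "CM")),
                                 colnames(m)))
  de_ba <- fit_pairwise(x_rev)
  expect_equal(de_ab$CM_vs_Mac$log2FC, -de_ba$Mac_vs_CM$log2FC)
  expect_equal(de_ab$CM_vs_Mac$pvalue, de_ba$Mac_vs_CM$pvalue)
  expect_equal(de_ab$CM_vs_Mac$FDR, de_ba$Mac_vs_CM$FDR)
})

test_that("scaling a sample column is absorbed by size factors", {
  cfg <- sim_config(n_features = 300, structural_zero_fraction = 0,
                    seed = 12L)
  x <- simulate_counts(cfg)$counts
  de1 <- fit_pairwise(x)
  m <- count_matrix(x)
  m[, 2] <- m[, 2] * 4L
  x2 <- ev_counts(m, sample_groups(x))
  de2 <- fit_pairwise(x2)
  # invariant up to the eps pseudo-mass interacting with the geometric
  # rescaling of size factors
  expect_equal(de2$CM_vs_CF$log2FC, de1$CM_vs_CF$log2FC, tolerance = 0.02)
  expect_equal(de2$CM_vs_CF$stat, de1$CM_vs_CF$stat, tolerance = 0.02)
})

test_that("with the dispersion floor forced, Wald stats match a Poisson oracle", {
  set.seed(99)
  m <- matrix(rpois(30 * 6, 1000), 30, 6,
              dimnames = list(paste0("hsa-miR-", 1:30, "-5p"),
                              c(paste0("A_", 1:3), paste0("B_", 1:3))))
  x <- ev_counts(m, setNames(rep(c("A", "B"), each = 3), colnames(m)))
  norm <- size_factors(x)
  disp <- estimate_dispersions(count_matrix(x), sample_groups(x),
                               size_factors_vec = norm$size_factors)
  disp$alpha <- rep(1e-8, 30)  # Poisson limit
  de <- fit_pairwise(x, normalization = norm, dispersions = disp, eps = 0)
  # oracle: Wald on log means of Poisson sums (size factors ~ 1 here)
  sA <- norm$size_factors[1:3]; sB <- norm$size_factors[4:6]
  muA <- rowSums(m[, 1:3]) / sum(sA); muB <- rowSums(m[, 4:6]) / sum(sB)
  z_oracle <- (log(muA) - log(muB)) /
    sqrt(1 / (muA * sum(sA)) + 1 / (muB * sum(sB)))
  expect_equal(de$A_vs_B$stat, unname(z_oracle), tolerance = 0.05)
})

test_that("injected effects are recovered without systematic bias", {
  cfg <- sim_config(n_features = 800, de_fraction = 0.1, effect_log2fc = 2,
                    seed = 17L)
  sim <- simulate_counts(cfg)
  de <- fit_pairwise(sim$counts)
  tr <- sim$truth[!is.na(sim$truth$affected_group), ]
  errs <- unlist(lapply(seq_len(nrow(tr)), function(i) {
    g <- tr$affected_group[i]
    sapply(setdiff(group_names(sim$counts), g), function(o) {
      k1 <- paste0(g, "_vs_", o); k2 <- paste0(o, "_vs_", g)
      est <- if (k1 %in% names(de)) {
        de[[k1]]$log2FC[de[[k1]]$feature == tr$feature[i]]
      } else {
        -de[[k2]]$log2FC[de[[k2]]$feature == tr$feature[i]]
      }
      est - tr$true_log2fc[i]
    })
  }))
  expect_lt(abs(mean(errs)), 0.2)
})

test_that("designs with singleton groups are rejected", {
  m <- matrix(rpois(10 * 3, 30), 10, 3,
              dimnames = list(paste0("hsa-miR-", 1:10, "-5p"),
                              c("A_1", "A_2", "B_1")))
  x <- ev_counts(m, c(A_1 = "A", A_2 = "A", B_1 = "B"))
  expect_error(fit_pairwise(x), "replicates", class = "mirland_config_error")
})

test_that("BH step-up matches hand evaluation and stays within bounds", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.37), 0.37)
  set.seed(4)
  for (i in 1:5) {
    p <- runif(sample(2:50, 1))
    adj <- adjust_fdr(p)
    expect_true(all(adj >= p & adj <= 1))
    expect_equal(adj, p.adjust(p, method = "BH"))
  }
  expect_error(adjust_fdr(c(0.5, 1.2)), class = "mirland_config_error")
})
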