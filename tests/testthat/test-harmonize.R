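make_raw <- function(features, counts, samples, annotation = NULL) {
  m <- matrix(counts, nrow = length(features), byrow = TRUE,
              dimnames = list(features, samples))
  miRland:::raw_counts(m, annotation)
}

anno <- data.frame(
  feature = c("hsa-miR-9", "hsa-miR-9-5p", "hsa-miR-9-3p",
              "hsa-miR-7", "hsa-miR-7-5p"),
  chrom = c("chr1:500", "chr1:500", "chr1:500", "chr5:900", "chr5:900"),
  stringsAsFactors = FALSE)

meta4 <- function() {
  fixture_metadata(c("p1", "p2", "r1", "r2"), c("CM", "CM", "Mac", "Mac"))
}

test_that("a sole expressed arm resolves an arm-less feature, counts intact", {
  primary <- make_raw(c("hsa-miR-9", "hsa-miR-21-5p"),
                      c(4, 7, 1, 2), c("p1", "p2"))
  reference <- make_raw(c("hsa-miR-9-5p", "hsa-miR-21-5p"),
                        c(10, 11, 3, 4), c("r1", "r2"))
  h <- harmonize_counts(primary, reference, meta4(), annotation = anno)
  m <- count_matrix(h$counts)
  expect_true("hsa-miR-9-5p" %in% rownames(m))
  expect_false("hsa-miR-9" %in% rownames(m))
  expect_equal(unname(m["hsa-miR-9-5p", c("p1", "p2")]), c(4, 7))
  expect_identical(h$log$renamed$old, "hsa-miR-9")
  expect_match(h$log$renamed$evidence, "sole_expressed_arm")
})

test_that("features missing from one file are zero-filled, not dropped", {
  primary <- make_raw("hsa-miR-21-5p", c(1, 2), c("p1", "p2"))
  reference <- make_raw(c("hsa-miR-21-5p", "hsa-miR-126-3p"),
                        c(3, 4, 9, 8), c("r1", "r2"))
  h <- harmonize_counts(primary, reference, meta4())
  m <- count_matrix(h$counts)
  expect_equal(unname(m["hsa-miR-126-3p", c("p1", "p2")]), c(0, 0))
  expect_equal(unname(m["hsa-miR-126-3p", c("r1", "r2")]), c(9, 8))
  expect_true("hsa-miR-126-3p" %in% h$log$zero_filled_primary)
})

test_that("ambiguous or conflicting arm evidence excludes the feature", {
  # both arms expressed in the reference
  primary <- make_raw("hsa-miR-9", c(4, 7), c("p1", "p2"))
  reference <- make_raw(c("hsa-miR-9-5p", "hsa-miR-9-3p"),
                        c(10, 11, 5, 6), c("r1", "r2"))
  h <- harmonize_counts(primary, reference, meta4(), annotation = anno)
  expect_false(any(grepl("^hsa-miR-9", rownames(count_matrix(h$counts))[
    !grepl("p$", rownames(count_matrix(h$counts)))])))
  expect_identical(h$log$unresolved$reason, "both_arms_expressed_in_reference")

  # chromosome conflict
  anno2 <- anno
  anno2$chrom[anno2$feature == "hsa-miR-9-5p"] <- "chr9:1"
  reference2 <- make_raw("hsa-miR-9-5p", c(10, 11), c("r1", "r2"))
  h2 <- harmonize_counts(primary, reference2, meta4(), annotation = anno2)
  expect_identical(h2$log$unresolved$reason, "chromosome_conflict")
  expect_false("hsa-miR-9" %in% rownames(count_matrix(h2$counts)))
  expect_false("hsa-miR-9-5p" %in% h2$log$renamed$new)

  # no expressed arm at all
  reference3 <- make_raw("hsa-miR-9-5p", c(0, 0), c("r1", "r2"))
  h3 <- harmonize_counts(primary, reference3, meta4(), annotation = anno)
  expect_identical(h3$log$unresolved$reason, "no_expressed_arm_in_reference")
})

test_that("harmonization conserves count mass and is idempotent", {
  cfg <- sim_config(n_features = 300, seed = 21L)
  sim <- simulate_counts(cfg)
  d <- emit_dialects(sim$counts, sim$annotation, strip_arm_fraction = 0.25,
                     drop_fraction = 0.1, seed = 4L)
  meta <- fixture_metadata(names(sample_groups(sim$counts)),
                           as.character(sample_groups(sim$counts)))
  h <- harmonize_counts(d$primary, d$reference, meta, sim$annotation)
  m <- count_matrix(h$counts)

  # mass conservation: every merged feature's totals equal its source totals
  kept_primary <- intersect(rownames(m), rownames(d$primary$counts))
  expect_equal(rowSums(m[kept_primary, colnames(d$primary$counts)]),
               rowSums(d$primary$counts[kept_primary, ]))
  renamed <- h$log$renamed
  if (nrow(renamed)) {
    expect_equal(
      unname(rowSums(m[renamed$new, colnames(d$primary$counts),
                       drop = FALSE])),
      unname(rowSums(d$primary$counts[renamed$old, , drop = FALSE])))
  }

  # idempotence: re-harmonizing the harmonized halves is a no-op
  p2 <- miRland:::raw_counts(m[, colnames(d$primary$counts)])
  r2 <- miRland:::raw_counts(m[, colnames(d$reference$counts)])
  h2 <- harmonize_counts(p2, r2, meta, sim$annotation)
  expect_identical(sort(rownames(count_matrix(h2$counts))),
                   sort(rownames(m)))
  expect_equal(count_matrix(h2$counts)[rownames(m), colnames(m)], m)
  expect_identical(nrow(h2$log$renamed), 0L)
})

test_that("unresolved features are never double-counted against an arm", {
  # the arm itself is present in the primary file: renaming must not merge
  primary <- make_raw(c("hsa-miR-9", "hsa-miR-9-5p"),
                      c(4, 7, 100, 200), c("p1", "p2"))
  reference <- make_raw("hsa-miR-9-5p", c(10, 11), c("r1", "r2"))
  h <- harmonize_counts(primary, reference, meta4(), annotation = anno)
  m <- count_matrix(h$counts)
  expect_equal(unname(m["hsa-miR-9-5p", c("p1", "p2")]), c(100, 200))
  expect_identical(h$log$unresolved$reason,
                   "rename_collides_with_existing_feature")
})
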