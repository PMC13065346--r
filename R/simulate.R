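#' Simulation configuration for the four-group EV count generator
#'
#' The defaults emulate the sequencing design of a four-subtype cardiac EV
#' study: cardiomyocyte (CM), cardiac fibroblast (CF), cardiac
#' microvascular endothelial cell (HCMVEC) and primitive macrophage (Mac)
#' EV preparations with n = 3, 3, 3, 4 biological replicates. Counts are
#' negative binomial with feature-specific baselines and dispersions
#' (variance = mu + alpha * mu^2), heterogeneous library sizes, an optional
#' fraction of single-group log2 fold-change effects, and structural zeros
#' that silence a feature in a random subset of groups so that detection
#' sets differ between subtypes.
#'
#' @param n_features number of miRNA features to simulate.
#' @param group_names ordered group (EV subtype) labels.
#' @param group_sizes replicate count per group.
#' @param baseline_logmean_range interval (natural-log scale) from which
#'   feature baseline means are drawn uniformly.
#' @param dispersion_range interval from which NB dispersions alpha are
#'   drawn uniformly.
#' @param de_fraction proportion of features given a group-specific effect.
#' @param effect_log2fc absolute log2 fold change of injected effects; the
#'   sign is drawn per feature.
#' @param structural_zero_fraction proportion of (non-effect) features
#'   zeroed out in a random strict subset of groups.
#' @param libsize_range interval of per-sample library-size scaling factors.
#' @param both_arm_fraction proportion of miRNA hairpins contributing both
#'   a -5p and a -3p arm to the feature set (the rest contribute one arm).
#' @param seed integer seed; one global stream drives the whole fixture.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_features = 2000L,
                       group_names = c("CM", "CF", "HCMVEC", "Mac"),
                       group_sizes = c(3L, 3L, 3L, 4L),
                       baseline_logmean_range = c(log(5), log(5000)),
                       dispersion_range = c(0.05, 0.6),
                       de_fraction = 0.1,
                       effect_log2fc = 2,
                       structural_zero_fraction = 0.1,
                       libsize_range = c(0.5, 1.5),
                       both_arm_fraction = 0.1,
                       seed = 1L) {
  if (length(n_features) != 1L || !is.finite(n_features) || n_features < 1) {
    stop_config("n_features must be a positive integer")
  }
  if (length(group_names) != length(group_sizes)) {
    stop_config("group_sizes must have one entry per group name")
  }
  if (any(group_sizes < 1)) stop_config("group_sizes must be positive")
  ranges <- list(baseline_logmean_range = baseline_logmean_range,
                 dispersion_range = dispersion_range,
                 libsize_range = libsize_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2]) {
      stop_config(nm, " must be a finite interval with lower <= upper")
    }
  }
  if (any(dispersion_range < 0)) stop_config("dispersion_range must be >= 0")
  if (any(libsize_range <= 0)) stop_config("libsize_range must be positive")
  for (fr in c(de_fraction = de_fraction,
               structural_zero_fraction = structural_zero_fraction,
               both_arm_fraction = both_arm_fraction)) {
    if (!is.finite(fr) || fr < 0 || fr > 1) {
      stop_config("fractions must lie in [0, 1]")
    }
  }
  structure(list(n_features = as.integer(n_features),
                 group_names = as.character(group_names),
                 group_sizes = as.integer(group_sizes),
                 baseline_logmean_range = baseline_logmean_range,
                 dispersion_range = dispersion_range,
                 de_fraction = de_fraction,
                 effect_log2fc = effect_log2fc,
                 structural_zero_fraction = structural_zero_fraction,
                 libsize_range = libsize_range,
                 both_arm_fraction = both_arm_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# miRBase-style feature names built from sequentially numbered hairpins;
# a hairpin contributes either one arm or both, so that arm-suffix
# stripping in emit_dialects can create genuinely ambiguous names.
simulate_feature_names <- function(n, both_arm_fraction) {
  feats <- character(0)
  hairpin <- character(0)
  h <- 0L
  while (length(feats) < n) {
    h <- h + 1L
    base <- sprintf("hsa-miR-%d", h)
    arms <- if (runif(1) < both_arm_fraction) c("-5p", "-3p")
            else sample(c("-5p", "-3p"), 1L)
    feats <- c(feats, paste0(base, arms))
    hairpin <- c(hairpin, rep(base, length(arms)))
  }
  list(features = feats[seq_len(n)], hairpin = hairpin[seq_len(n)])
}

#' Simulate a negative-binomial EV miRNA count matrix with known truth
#'
#' Counts for feature i in sample j are drawn from
#' NB(mean = libsize_j * exp(baseline_i + log(2) * lfc_ij),
#' variance = mu + alpha_i * mu^2). Effect features receive their signed
#' log2 fold change in exactly one group (all other groups form the
#' baseline); structural-zero features are set to exactly zero in a random
#' strict subset of groups. The same seed always reproduces the same
#' fixture bit for bit.
#'
#' @param config a [sim_config] object.
#' @return A list with components:
#'   \describe{
#'     \item{counts}{an [ev_counts] matrix (features x samples).}
#'     \item{truth}{data frame listing only features with an injected
#'       effect and/or structural zeros: `feature`, `affected_group`,
#'       `true_log2fc`, `zero_groups` (semicolon-separated).}
#'     \item{annotation}{data frame (`feature`, `chrom`) with one row per
#'       arm-level feature and one per hairpin; arms of a hairpin share a
#'       locus.}
#'     \item{params}{per-feature `baseline`, `dispersion`, `hairpin` and
#'       per-sample `libsize` used for the draw (for oracle checks).}
#'   }
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_config("'config' must be a sim_config object")
  }
  set.seed(config$seed)
  n <- config$n_features
  g <- length(config$group_names)
  n_samples <- sum(config$group_sizes)
  groups <- factor(rep(config$group_names, config$group_sizes),
                   levels = config$group_names)
  samples <- unlist(lapply(seq_len(g), function(i) {
    sprintf("%s_%d", config$group_names[i], seq_len(config$group_sizes[i]))
  }))

  nm <- simulate_feature_names(n, config$both_arm_fraction)
  baseline <- runif(n, config$baseline_logmean_range[1],
                    config$baseline_logmean_range[2])
  alpha <- runif(n, config$dispersion_range[1], config$dispersion_range[2])
  libsize <- runif(n_samples, config$libsize_range[1],
                   config$libsize_range[2])

  n_de <- floor(config$de_fraction * n)
  de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
  de_group <- if (n_de > 0) sample(config$group_names, n_de, replace = TRUE)
              else character(0)
  de_lfc <- if (n_de > 0) {
    sample(c(-1, 1), n_de, replace = TRUE) * config$effect_log2fc
  } else numeric(0)

  n_sz <- floor(config$structural_zero_fraction * n)
  sz_pool <- setdiff(seq_len(n), de_idx)  # keep effect truth unambiguous
  n_sz <- min(n_sz, length(sz_pool))
  sz_idx <- if (n_sz > 0) sample(sz_pool, n_sz) else integer(0)
  sz_groups <- lapply(seq_len(n_sz), function(i) {
    k <- sample.int(g - 1L, 1L)
    sample(config$group_names, k)
  })

  lfc <- matrix(0, n, g, dimnames = list(nm$features, config$group_names))
  if (n_de > 0) lfc[cbind(de_idx, match(de_group, config$group_names))] <- de_lfc

  mu <- exp(baseline + log(2) * lfc[, as.integer(groups), drop = FALSE])
  mu <- sweep(mu, 2L, libsize, `*`)
  counts <- matrix(rnbinom(n * n_samples, mu = mu, size = 1 / pmax(alpha, 1e-12)),
                   n, n_samples, dimnames = list(nm$features, samples))
  if (any(alpha == 0)) {  # alpha = 0 degenerates to Poisson
    pois <- which(alpha == 0)
    counts[pois, ] <- stats::rpois(length(pois) * n_samples, mu[pois, ])
  }
  if (n_sz > 0) {
    for (i in seq_len(n_sz)) {
      counts[sz_idx[i], groups %in% sz_groups[[i]]] <- 0
    }
  }

  truth_idx <- sort(union(de_idx, sz_idx))
  truth <- data.frame(
    feature = nm$features[truth_idx],
    affected_group = rep(NA_character_, length(truth_idx)),
    true_log2fc = rep(0, length(truth_idx)),
    zero_groups = rep("", length(truth_idx)),
    stringsAsFactors = FALSE)
  if (n_de > 0) {
    pos <- match(de_idx, truth_idx)
    truth$affected_group[pos] <- de_group
    truth$true_log2fc[pos] <- de_lfc
  }
  if (n_sz > 0) {
    pos <- match(sz_idx, truth_idx)
    truth$zero_groups[pos] <- vapply(sz_groups, paste, "", collapse = ";")
  }

  hairpins <- unique(nm$hairpin)
  hp_chrom <- sprintf("chr%d:%d",
                      sample(1:22, length(hairpins), replace = TRUE),
                      sample.int(1e8, length(hairpins)))
  annotation <- rbind(
    data.frame(feature = nm$features,
               chrom = hp_chrom[match(nm$hairpin, hairpins)],
               stringsAsFactors = FALSE),
    data.frame(feature = hairpins, chrom = hp_chrom,
               stringsAsFactors = FALSE))
  annotation <- annotation[!duplicated(annotation$feature), ]

  list(counts = ev_counts(counts, setNames(as.character(groups), samples)),
       truth = truth,
       annotation = annotation,
       params = list(baseline = setNames(baseline, nm$features),
                     dispersion = setNames(alpha, nm$features),
                     hairpin = setNames(nm$hairpin, nm$features),
                     libsize = setNames(libsize, samples)))
}

#' Plant a highly abundant, group-exclusive marker feature
#'
#' Adds (or overwrites) one feature that is expressed only in `group`, at a
#' baseline high enough to enter the group's top-k abundance list. Used for
#' power analyses of the key-miRNA filter: the planted feature is abundant,
#' consistently upregulated versus every other subtype, and maximally
#' enriched (tau = 1 in expectation).
#'
#' @param x an [ev_counts] object.
#' @param group the subtype that expresses the marker.
#' @param name feature ID for the marker.
#' @param baseline_log natural-log mean count in the expressing group.
#' @param dispersion NB dispersion of the marker counts.
#' @return The modified [ev_counts] object.
#' @export
plant_key_feature <- function(x, group, name = "hsa-miR-9999-5p",
                              baseline_log = log(20000), dispersion = 0.1) {
  if (!group %in% levels(x$groups)) stop_config("unknown group: ", group)
  m <- x$counts
  row <- numeric(ncol(m))
  in_group <- x$groups == group
  row[in_group] <- rnbinom(sum(in_group), mu = exp(baseline_log),
                           size = 1 / dispersion)
  if (name %in% rownames(m)) {
    m[name, ] <- row
  } else {
    m <- rbind(m, matrix(row, 1, dimnames = list(name, colnames(m))))
  }
  ev_counts(m, x$groups)
}

#' Emit the two alignment-pipeline count-file dialects
#'
#' Splits a simulated matrix into the two file dialects that
#' [harmonize_counts] is designed to reconcile, emulating a study in which
#' one batch of samples was aligned by a pipeline that sometimes omits the
#' -3p/-5p arm suffix and misses some features, while a second pipeline
#' reports full miRBase IDs. The primary dialect carries the samples of
#' every group except the last; the reference dialect carries the last
#' group's samples. Renaming preserves per-feature counts exactly.
#'
#' @param counts an [ev_counts] object.
#' @param annotation annotation data frame as returned by
#'   [simulate_counts] (feature, chrom).
#' @param strip_arm_fraction proportion of suffixed primary features whose
#'   arm suffix is removed (at most one arm per hairpin is stripped so IDs
#'   stay unique).
#' @param drop_fraction proportion of primary features dropped outright.
#' @param seed integer seed for the strip/drop draws.
#' @return list with `primary` and `reference` (`raw_counts` objects),
#'   `annotation`, and `manifest`: a data frame with one row per original
#'   feature (`feature`, `emitted_name` in the primary dialect or NA if
#'   dropped, `stripped`, `dropped`).
#' @export
emit_dialects <- function(counts, annotation = NULL,
                          strip_arm_fraction = 0.2, drop_fraction = 0.05,
                          seed = 1L) {
  for (fr in c(strip_arm_fraction, drop_fraction)) {
    if (!is.finite(fr) || fr < 0 || fr > 1) {
      stop_config("fractions must lie in [0, 1]")
    }
  }
  g <- levels(counts$groups)
  if (length(g) < 2L) stop_config("need at least two groups to split dialects")
  set.seed(seed)
  ref_group <- g[length(g)]
  primary_m <- counts$counts[, counts$groups != ref_group, drop = FALSE]
  reference_m <- counts$counts[, counts$groups == ref_group, drop = FALSE]

  feats <- rownames(counts$counts)
  n <- length(feats)
  dropped <- rep(FALSE, n)
  n_drop <- floor(drop_fraction * n)
  if (n_drop > 0) dropped[sample.int(n, n_drop)] <- TRUE

  # strip eligibility: suffixed, not dropped, and no other arm of the same
  # hairpin already selected (duplicate armless IDs would be unparseable)
  stripped <- rep(FALSE, n)
  eligible <- which(has_arm_suffix(feats) & !dropped)
  n_strip <- floor(strip_arm_fraction * length(eligible))
  if (n_strip > 0) {
    cand <- sample(eligible)
    taken_hairpin <- character(0)
    for (i in cand) {
      hp <- strip_arm_suffix(feats[i])
      if (hp %in% taken_hairpin || hp %in% feats) next
      stripped[i] <- TRUE
      taken_hairpin <- c(taken_hairpin, hp)
      if (sum(stripped) >= n_strip) break
    }
  }

  emitted <- ifelse(dropped, NA_character_,
                    ifelse(stripped, strip_arm_suffix(feats), feats))
  keep <- !dropped
  primary_out <- primary_m[keep, , drop = FALSE]
  rownames(primary_out) <- emitted[keep]

  manifest <- data.frame(feature = feats, emitted_name = emitted,
                         stripped = stripped, dropped = dropped,
                         stringsAsFactors = FALSE)
  list(primary = raw_counts(primary_out, annotation),
       reference = raw_counts(reference_m, annotation),
       annotation = annotation,
       manifest = manifest)
}

#' Write a simulated fixture to disk
#'
#' Writes the count matrix, sample metadata, truth table and annotation as
#' tab-separated files, and the configuration as JSON, under `dir`.
#'
#' @param sim result of [simulate_counts].
#' @param config the [sim_config] used.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             config = file.path(dir, "sim_config.json"))
  write_counts(sim$counts, paths["counts"])
  write.table(data.frame(sample = names(sim$counts$groups),
                         group = as.character(sim$counts$groups)),
              paths["metadata"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$annotation, paths["annotation"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(unclass(config), paths["config"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
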