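#' Pipeline configuration
#'
#' Validates and assembles the configuration driving [run_pipeline]. Input
#' paths must exist at construction time (fail-fast); thresholds are
#' checked against their documented ranges. A configuration round-trips
#' through JSON unchanged (see [read_pipeline_config]).
#'
#' @param counts path to a tab-separated count file (single-pipeline
#'   input), or NULL when `primary`/`reference` are given.
#' @param metadata path to the sample metadata table (sample, group).
#' @param out_dir output directory for all stage artifacts.
#' @param primary,reference optional paths to the two pipeline dialect
#'   files; when both are given the harmonization stage runs first.
#' @param annotation optional path to a feature/chrom annotation table.
#' @param detection_rule detection rule for [detect_partition].
#' @param k top-k list length for abundance ranking.
#' @param alpha FDR significance threshold.
#' @param tau_thresh tau enrichment threshold.
#' @param fc_thresh linear fold-change enrichment threshold.
#' @param m minimum qualifying comparisons for fold-change enrichment.
#' @param seed integer seed recorded in the provenance block (the analysis
#'   stages themselves are deterministic).
#' @param stages character vector of stages to run, a subset of
#'   `c("normalize", "detection", "pca", "diffexp", "signature")`;
#'   dependencies are enforced (`signature` needs `diffexp` and
#'   `detection`; `pca` needs `normalize`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, metadata, out_dir,
                            primary = NULL, reference = NULL,
                            annotation = NULL,
                            detection_rule = "any_replicate_nonzero",
                            k = 20L, alpha = 0.05, tau_thresh = 0.7,
                            fc_thresh = 5, m = 2L, seed = 1L,
                            stages = c("normalize", "detection", "pca",
                                       "diffexp", "signature")) {
  two_file <- !is.null(primary) && !is.null(reference)
  if (!two_file && is.null(counts)) {
    stop_config("provide either 'counts' or both 'primary' and 'reference'")
  }
  for (p in c(counts, metadata, primary, reference, annotation)) {
    if (!file.exists(p)) stop_config("input file not found: ", p)
  }
  if (!(alpha > 0 && alpha < 1)) stop_config("alpha must lie in (0, 1)")
  if (!(tau_thresh >= 0 && tau_thresh <= 1)) {
    stop_config("tau_thresh must lie in [0, 1]")
  }
  if (fc_thresh <= 1) stop_config("fc_thresh must exceed 1")
  if (k < 1 || m < 1) stop_config("k and m must be >= 1")
  known <- c("normalize", "detection", "pca", "diffexp", "signature")
  if (!all(stages %in% known)) {
    stop_config("unknown stages: ",
                paste(setdiff(stages, known), collapse = ", "))
  }
  if ("pca" %in% stages && !"normalize" %in% stages) {
    stop_config("stage 'pca' requires stage 'normalize'")
  }
  if ("signature" %in% stages &&
      !all(c("diffexp", "detection", "normalize") %in% stages)) {
    stop_config("stage 'signature' requires normalize, detection and diffexp")
  }
  if ("diffexp" %in% stages && !"normalize" %in% stages) {
    stop_config("stage 'diffexp' requires stage 'normalize'")
  }
  structure(list(counts = counts, metadata = metadata, out_dir = out_dir,
                 primary = primary, reference = reference,
                 annotation = annotation,
                 detection_rule = detection_rule, k = as.integer(k),
                 alpha = alpha, tau_thresh = tau_thresh,
                 fc_thresh = fc_thresh, m = as.integer(m),
                 seed = as.integer(seed), stages = stages),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @param path JSON path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a validated `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the landscape pipeline end to end
#'
#' Executes the enabled stages in dependency order — harmonize (when two
#' dialect files are configured), normalize (CPM + median-of-ratios),
#' detection partition, PCA, all-pairwise differential expression, tau and
#' key-miRNA signature — writing every stage table under
#' `config$out_dir` and a machine-readable report JSON last. The report
#' contains only numbers re-derivable from the emitted stage tables plus a
#' provenance block (configuration, seed, package and R versions).
#' Identical configuration and seed produce an identical report body.
#'
#' @param config a [pipeline_config].
#' @return the report, invisibly (list of class `landscape_report`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_config("'config' must be a pipeline_config")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  report <- list()
  out <- function(...) file.path(config$out_dir, ...)

  if (!is.null(config$primary) && !is.null(config$reference)) {
    message("stage: harmonize")
    h <- harmonize_counts(read_raw_counts(config$primary),
                          read_raw_counts(config$reference),
                          metadata = config$metadata,
                          annotation = if (!is.null(config$annotation)) {
                            read.delim(config$annotation,
                                       stringsAsFactors = FALSE)
                          })
    write_counts(h$counts, out("harmonized_counts.tsv"))
    write_harmonization_log(h, out("harmonization_log.json"))
    x <- h$counts
    report$harmonization <- list(
      merged_features = nrow(x$counts),
      renamed = nrow(h$log$renamed),
      unresolved = nrow(h$log$unresolved))
  } else {
    x <- read_counts(config$counts, config$metadata)
  }

  norm <- NULL; cpm_m <- NULL
  if ("normalize" %in% config$stages) {
    message("stage: normalize")
    cpm_m <- cpm(x)
    norm <- size_factors(x)
    write_matrix_tsv(cpm_m, out("cpm.tsv"))
    write_matrix_tsv(norm$normalized, out("normalized_counts.tsv"))
    write.table(data.frame(sample = names(norm$size_factors),
                           size_factor = norm$size_factors),
                out("size_factors.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$normalization <- list(
      size_factors = as.list(round(norm$size_factors, 6)),
      reference_set_size = length(norm$reference_features))
  }

  if ("detection" %in% config$stages) {
    message("stage: detection")
    part <- detect_partition(x, rule = config$detection_rule)
    jsonlite::write_json(
      list(rule = part$rule, union_size = part$union_size,
           group_totals = as.list(part$group_totals),
           exclusive = as.list(part$exclusive),
           cells = lapply(part$cells, identity)),
      out("detection_partition.json"), auto_unbox = TRUE, digits = NA)
    ranking <- rank_abundance(cpm_m %||% cpm(x), x$groups, k = config$k)
    for (g in names(ranking$top)) {
      write.table(ranking$top[[g]], out(sprintf("top%d_%s.tsv", config$k, g)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(ranking$flags, out("abundance_flags.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$detection <- list(
      rule = part$rule, union_size = part$union_size,
      group_totals = as.list(part$group_totals),
      exclusive = as.list(part$exclusive),
      shared_all = sum(rowSums(part$membership) == ncol(part$membership)),
      common_abundant = sum(ranking$flags$common_abundant),
      uniquely_abundant = sum(ranking$flags$uniquely_abundant))
  }

  if ("pca" %in% config$stages) {
    message("stage: pca")
    p <- mir_pca(norm$log2, groups = x$groups)
    scores <- data.frame(sample = rownames(p$scores),
                         group = as.character(x$groups[rownames(p$scores)]),
                         p$scores, check.names = FALSE)
    write.table(scores, out("pca_scores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$pca <- list(var_explained = round(p$var_explained, 6))
  }

  de <- NULL
  if ("diffexp" %in% config$stages) {
    message("stage: diffexp")
    de <- fit_pairwise(x, normalization = norm)
    for (nm in names(de)) {
      write.table(de[[nm]], out(sprintf("de_%s.tsv", nm)), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    report$diffexp <- lapply(de, function(t) {
      list(up = sum(t$FDR < config$alpha & t$log2FC > 0),
           down = sum(t$FDR < config$alpha & t$log2FC < 0))
    })
  }

  if ("signature" %in% config$stages) {
    message("stage: signature")
    tt <- tau_table(norm$normalized, x$groups)
    write.table(tt, out("tau.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    ranking <- rank_abundance(cpm_m, x$groups, k = config$k)
    sig <- classify_key(ranking, de, tt, alpha = config$alpha,
                        tau_thresh = config$tau_thresh,
                        fc_thresh = config$fc_thresh, m = config$m)
    write.table(sig, out("key_signature.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    consensus <- lapply(setNames(nm = levels(x$groups)), function(g) {
      consensus_upregulated(de, g, alpha = config$alpha)
    })
    jsonlite::write_json(consensus, out("consensus_upregulated.json"),
                         auto_unbox = FALSE, digits = NA)
    tau_ok <- tt$tau[!is.na(tt$tau)]
    report$signature <- list(
      key = lapply(split(sig$feature[sig$key], sig$subtype[sig$key]),
                   sort),
      n_key = as.list(table(sig$subtype[sig$key])),
      consensus_upregulated = lapply(consensus, length),
      tau_summary = list(median = median(tau_ok),
                         over_threshold = sum(tau_ok > config$tau_thresh)))
  }

  report$provenance <- list(
    config = unclass(config),
    seed = config$seed,
    package_version = as.character(packageVersion("miRland")),
    r_version = R.version.string)
  class(report) <- c("landscape_report", "list")
  jsonlite::write_json(unclass(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(miRNA = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
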