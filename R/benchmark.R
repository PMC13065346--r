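#' Published detection-set reference for the four-subtype cardiac EV study
#'
#' Printed summary values from the study whose design this package models
#' (GEO Series GSE311002): per-subtype totals of detected miRNAs, counts
#' exclusive to one subtype, the union over all subtypes, the 4-way
#' intersection, and the per-subtype consensus-upregulated counts. These
#' are comparison references for [detection_benchmark]; the exact detection
#' rule behind the published Venn is unstated, so agreement is reported
#' rule by rule rather than asserted.
#'
#' @return nested list: `detected`, `exclusive` (named per subtype),
#'   `union`, `shared_all`, `consensus_upregulated`, `upregulated_any`,
#'   `de_union`, and `accession`.
#' @export
cardiac_ev_reference <- function() {
  list(
    detected = c(CM = 674, CF = 99, HCMVEC = 217, Mac = 181),
    exclusive = c(CM = 421, CF = 2, HCMVEC = 20, Mac = 30),
    union = 730,
    shared_all = 56,
    consensus_upregulated = c(CM = 37, CF = 2, HCMVEC = 2, Mac = 12),
    upregulated_any = c(CM = 81, CF = 31, HCMVEC = 37, Mac = 46),
    de_union = 124,
    accession = "GSE311002")
}

#' Compare a count matrix's detection summary to the published reference
#'
#' Runs [detect_partition] under each built-in detection rule and tabulates
#' per-subtype detected totals, exclusive counts, union and all-group
#' intersection against [cardiac_ev_reference] (or any reference of the
#' same shape).
#'
#' @param x an [ev_counts] object whose groups are named CM, CF, HCMVEC,
#'   Mac (order free).
#' @param reference reference list; defaults to [cardiac_ev_reference].
#' @param min_total threshold used for the `min_total` rule.
#' @return data frame with one row per (rule, statistic): columns `rule`,
#'   `statistic`, `observed`, `reference`, `match`.
#' @export
detection_benchmark <- function(x, reference = cardiac_ev_reference(),
                                min_total = 10) {
  rules <- c("any_replicate_nonzero", "all_replicates_nonzero", "min_total")
  rows <- lapply(rules, function(r) {
    part <- detect_partition(x, rule = r, min_total = min_total)
    g <- names(reference$detected)
    obs <- c(setNames(as.numeric(part$group_totals[g]),
                      paste0("detected_", g)),
             setNames(as.numeric(part$exclusive[g]), paste0("exclusive_", g)),
             union = part$union_size,
             shared_all = sum(rowSums(part$membership) ==
                                ncol(part$membership)))
    ref <- c(setNames(as.numeric(reference$detected[g]),
                      paste0("detected_", g)),
             setNames(as.numeric(reference$exclusive[g]),
                      paste0("exclusive_", g)),
             union = reference$union,
             shared_all = reference$shared_all)
    data.frame(rule = part$rule, statistic = names(obs),
               observed = unname(obs), reference = unname(ref),
               match = unname(obs == ref),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fetch processed count matrices for a GEO series (network required)
#'
#' Downloads the supplementary files of a GEO Series accession into `dest`.
#' This helper exists for benchmarking against deposited study data and is
#' deliberately excluded from the test suite: it requires internet access
#' and GEO availability.
#'
#' @param accession GEO Series accession (e.g. `"GSE311002"`).
#' @param dest destination directory.
#' @param timeout download timeout in seconds.
#' @return destination directory, invisibly.
#' @export
fetch_geo_counts <- function(accession, dest, timeout = 300) {
  dir.create(dest, showWarnings = FALSE, recursive = TRUE)
  stub <- paste0(substr(accession, 1, nchar(accession) - 3), "nnn")
  url <- sprintf(
    "https://ftp.ncbi.nlm.nih.gov/geo/series/%s/%s/suppl/%s_RAW.tar",
    stub, accession, accession)
  out <- file.path(dest, paste0(accession, "_RAW.tar"))
  old <- options(timeout = timeout); on.exit(options(old))
  status <- utils::download.file(url, out, mode = "wb", quiet = TRUE)
  if (status != 0) stop_format("download failed for ", accession)
  utils::untar(out, exdir = dest)
  invisible(dest)
}
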