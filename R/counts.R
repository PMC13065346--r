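#' miRNA count matrix with sample-to-group mapping
#'
#' `ev_counts` is the basic substrate of every analysis stage: an integer
#' feature-by-sample count matrix together with a group label for each
#' sample. Feature IDs follow the miRBase convention
#' (e.g. `"hsa-miR-21-5p"`); the `"hsa-"` prefix is case-normalized to
#' lower case at construction, the remainder of the ID is case-sensitive.
#'
#' @param counts numeric matrix of non-negative integer counts with unique
#'   feature IDs as row names and unique sample IDs as column names.
#' @param groups character or factor of group labels, one per sample. If
#'   named, names must match the sample IDs; otherwise positional.
#' @return An object of class `ev_counts`: a list with elements `counts`
#'   (integer-valued matrix) and `groups` (factor named by sample, levels in
#'   order of first appearance unless `groups` is already a factor).
#' @examples
#' m <- matrix(c(5L, 0L, 9L, 3L), 2, 2,
#'             dimnames = list(c("hsa-miR-21-5p", "hsa-let-7a-5p"),
#'                             c("s1", "s2")))
#' x <- ev_counts(m, c(s1 = "CM", s2 = "Mac"))
#' group_names(x)
#' @export
ev_counts <- function(counts, groups) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_format("'counts' must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_format("'counts' must have feature row names and sample column names")
  }
  rownames(counts) <- normalize_mir_ids(rownames(counts))
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stop_format("duplicate feature ID: ", dup)
  }
  if (anyDuplicated(colnames(counts))) {
    stop_format("duplicate sample IDs in count matrix")
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop_format("counts must be finite non-negative integers")
  }
  counts <- round(counts)
  storage.mode(counts) <- "double"

  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(counts), names(groups))
    if (length(missing)) {
      stop_format("samples missing from metadata: ",
                  paste(missing, collapse = ", "))
    }
    groups <- groups[colnames(counts)]
  } else if (length(groups) != ncol(counts)) {
    stop_format("'groups' must have one label per sample")
  }
  if (anyNA(groups)) stop_format("group labels contain NA")
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  names(groups) <- colnames(counts)

  structure(list(counts = counts, groups = groups), class = "ev_counts")
}

#' @export
print.ev_counts <- function(x, ...) {
  cat(sprintf("ev_counts: %d miRNAs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$groups)
  cat("groups: ",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.ev_counts <- function(x) dim(x$counts)

#' @rdname ev_counts
#' @param x an `ev_counts` object.
#' @export
group_names <- function(x) levels(x$groups)

#' @rdname ev_counts
#' @export
sample_groups <- function(x) x$groups

#' @rdname ev_counts
#' @export
count_matrix <- function(x) x$counts

#' Subset an ev_counts object
#'
#' @param x an `ev_counts` object.
#' @param i feature index (ID, position, or logical).
#' @param j sample index.
#' @param ... ignored.
#' @export
`[.ev_counts` <- function(x, i, j, ...) {
  m <- x$counts
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  ev_counts(m[i, j, drop = FALSE], droplevels(x$groups[j]))
}

# Enforce a lower-case species prefix ("hsa-") while leaving the rest of
# the ID untouched; miRBase IDs are otherwise case-sensitive.
normalize_mir_ids <- function(ids) {
  ids <- trimws(ids)
  sub("^(?i)hsa-", "hsa-", ids, perl = TRUE)
}

has_arm_suffix <- function(ids) grepl("-(3p|5p)$", ids)

strip_arm_suffix <- function(ids) sub("-(3p|5p)$", "", ids)

#' Read a tab-separated miRNA count file with sample metadata
#'
#' The expected layout is the one exported by the harmonization and
#' simulation stages: a header row of sample IDs, first column header
#' `"miRNA"`, one row per feature, integer counts. The metadata table maps
#' each sample to its group (EV subtype) label.
#'
#' @param path path to the tab-separated count file.
#' @param metadata either a path to a two-column tab-separated table with
#'   columns `sample` and `group`, or a data frame with those columns.
#' @return An [ev_counts] object; feature order is preserved from the file.
#' @export
read_counts <- function(path, metadata) {
  raw <- read_raw_counts(path)
  meta <- read_sample_metadata(metadata)
  groups <- setNames(as.character(meta$group), meta$sample)
  ev_counts(raw$counts, groups)
}

read_sample_metadata <- function(metadata) {
  if (is.character(metadata) && length(metadata) == 1L) {
    if (!file.exists(metadata)) {
      stop_format("metadata file not found: ", metadata)
    }
    metadata <- read.delim(metadata, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  }
  if (!is.data.frame(metadata) ||
      !all(c("sample", "group") %in% names(metadata))) {
    stop_format("metadata must have columns 'sample' and 'group'")
  }
  if (anyDuplicated(metadata$sample)) {
    stop_format("duplicate sample IDs in metadata")
  }
  metadata
}

#' Write an ev_counts object as a tab-separated count file
#'
#' @param x an [ev_counts] object or a `raw_counts` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  m <- if (inherits(x, "ev_counts")) x$counts else x$counts
  df <- data.frame(miRNA = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a raw (dialect-agnostic) count file
#'
#' Unlike [read_counts] this performs no group assignment and tolerates
#' arm-suffix-less feature IDs; it is the entry point for files destined for
#' [harmonize_counts]. Validation still rejects empty files, duplicate
#' feature IDs and non-integer or negative counts.
#'
#' @param path path to a tab-separated count file (first column `miRNA`,
#'   remaining columns one per sample).
#' @param annotation optional data frame or path with columns `feature` and
#'   `chrom` giving a chromosome location per feature (hairpin-level rows,
#'   named without the arm suffix, are also honored).
#' @return A `raw_counts` object: list with `counts` (matrix) and
#'   `annotation` (data frame or NULL).
#' @export
read_raw_counts <- function(path, annotation = NULL) {
  if (!file.exists(path)) stop_format("count file not found: ", path)
  if (file.size(path) == 0L) stop_format("empty count file: ", path)
  df <- tryCatch(
    read.delim(path, sep = "\t", stringsAsFactors = FALSE,
               check.names = FALSE),
    error = function(e) stop_format("cannot parse count file ", path, ": ",
                                    conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop_format("count file has no data rows or no sample columns: ", path)
  }
  feats <- normalize_mir_ids(as.character(df[[1L]]))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_format("non-numeric counts in ", path)
  rownames(m) <- feats
  raw_counts(m, annotation)
}

raw_counts <- function(counts, annotation = NULL) {
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stop_format("duplicate feature ID: ", dup)
  }
  if (anyDuplicated(colnames(counts))) {
    stop_format("duplicate sample IDs")
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop_format("counts must be finite non-negative integers")
  }
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- read.delim(annotation, sep = "\t",
                             stringsAsFactors = FALSE)
  }
  if (!is.null(annotation) &&
      !all(c("feature", "chrom") %in% names(annotation))) {
    stop_format("annotation must have columns 'feature' and 'chrom'")
  }
  structure(list(counts = round(counts), annotation = annotation),
            class = "raw_counts")
}

#' @export
print.raw_counts <- function(x, ...) {
  cat(sprintf("raw_counts: %d features x %d samples (%d without arm suffix)\n",
              nrow(x$counts), ncol(x$counts),
              sum(!has_arm_suffix(rownames(x$counts)))))
  invisible(x)
}
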