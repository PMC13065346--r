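#' Harmonize count files from two alignment pipelines
#'
#' Merges a primary count file (which may contain feature IDs lacking their
#' -3p/-5p arm suffix and may miss features entirely) with a reference
#' count file carrying full miRBase IDs, following two rules:
#'
#' 1. A feature absent from one file but expressed (non-zero) in the other
#'    is added to the missing file as a zero-count entry, so the merged
#'    matrix is rectangular over the union of features.
#' 2. An arm-suffix-less feature `X` in the primary file is renamed to
#'    `X-5p` or `X-3p` if and only if exactly one of the two arms is
#'    expressed (non-zero total) in the reference file and the chromosome
#'    locations of `X` and that arm agree (when annotation is available for
#'    both). Otherwise the feature is excluded from the merged matrix and
#'    logged as unresolved, preventing double counting against a resolved
#'    arm.
#'
#' Harmonization never changes a numeric count: it only renames, unions
#' and zero-fills, so the total count mass of retained features is
#' conserved, and harmonizing an already-harmonized pair is a no-op.
#'
#' @param primary a `raw_counts` object (see [read_raw_counts]); the file
#'   whose arm-less IDs are to be resolved.
#' @param reference a `raw_counts` object with full feature IDs.
#' @param metadata sample metadata (path or data frame with columns
#'   `sample`, `group`) covering the samples of both files.
#' @param annotation optional data frame (`feature`, `chrom`); defaults to
#'   annotations attached to either input file.
#' @return A list of class `harmonization`:
#'   \describe{
#'     \item{counts}{merged [ev_counts] over primary then reference samples.}
#'     \item{log}{list with `zero_filled_primary`, `zero_filled_reference`,
#'       `renamed` (data frame: old, new, evidence), `unresolved`
#'       (data frame: feature, reason).}
#'   }
#' @export
harmonize_counts <- function(primary, reference, metadata,
                             annotation = NULL) {
  if (!inherits(primary, "raw_counts") || !inherits(reference, "raw_counts")) {
    stop_format("'primary' and 'reference' must be raw_counts objects")
  }
  annotation <- annotation %||% primary$annotation %||% reference$annotation
  chrom_of <- make_chrom_lookup(annotation)

  pm <- primary$counts
  rm_ <- reference$counts
  if (length(intersect(colnames(pm), colnames(rm_)))) {
    stop_format("primary and reference files share sample IDs")
  }

  ref_expressed <- rownames(rm_)[rowSums(rm_) > 0]

  renamed <- data.frame(old = character(0), new = character(0),
                        evidence = character(0), stringsAsFactors = FALSE)
  unresolved <- data.frame(feature = character(0), reason = character(0),
                           stringsAsFactors = FALSE)

  pfeats <- rownames(pm)
  armless <- which(!has_arm_suffix(pfeats))
  new_names <- pfeats
  drop <- rep(FALSE, length(pfeats))
  for (i in armless) {
    f <- pfeats[i]
    arms <- paste0(f, c("-5p", "-3p"))
    expressed <- arms[arms %in% ref_expressed]
    if (length(expressed) == 0L) {
      drop[i] <- TRUE
      unresolved <- rbind(unresolved, data.frame(
        feature = f, reason = "no_expressed_arm_in_reference"))
      next
    }
    if (length(expressed) > 1L) {
      drop[i] <- TRUE
      unresolved <- rbind(unresolved, data.frame(
        feature = f, reason = "both_arms_expressed_in_reference"))
      next
    }
    target <- expressed
    chr_f <- chrom_of(f)
    chr_t <- chrom_of(target)
    if (!is.na(chr_f) && !is.na(chr_t) && chr_f != chr_t) {
      drop[i] <- TRUE
      unresolved <- rbind(unresolved, data.frame(
        feature = f, reason = "chromosome_conflict"))
      next
    }
    if (target %in% pfeats) {
      drop[i] <- TRUE
      unresolved <- rbind(unresolved, data.frame(
        feature = f, reason = "rename_collides_with_existing_feature"))
      next
    }
    evidence <- if (!is.na(chr_f) && !is.na(chr_t)) {
      "sole_expressed_arm+chromosome_match"
    } else {
      "sole_expressed_arm"
    }
    new_names[i] <- target
    renamed <- rbind(renamed, data.frame(old = f, new = target,
                                         evidence = evidence))
  }

  pm2 <- pm[!drop, , drop = FALSE]
  rownames(pm2) <- new_names[!drop]

  all_feats <- union(rownames(pm2), rownames(rm_))
  zero_filled_primary <- setdiff(rownames(rm_), rownames(pm2))
  zero_filled_reference <- setdiff(rownames(pm2), rownames(rm_))

  merged <- matrix(0, length(all_feats), ncol(pm2) + ncol(rm_),
                   dimnames = list(all_feats, c(colnames(pm2), colnames(rm_))))
  merged[rownames(pm2), colnames(pm2)] <- pm2
  merged[rownames(rm_), colnames(rm_)] <- rm_

  meta <- read_sample_metadata(metadata)
  groups <- setNames(as.character(meta$group), meta$sample)
  counts <- ev_counts(merged, groups)

  structure(list(
    counts = counts,
    log = list(zero_filled_primary = zero_filled_primary,
               zero_filled_reference = zero_filled_reference,
               renamed = renamed,
               unresolved = unresolved)),
    class = "harmonization")
}

#' @export
print.harmonization <- function(x, ...) {
  cat(sprintf(paste0("harmonization: %d merged features; %d renamed, ",
                     "%d unresolved/excluded\n"),
              nrow(x$counts$counts), nrow(x$log$renamed),
              nrow(x$log$unresolved)))
  invisible(x)
}

make_chrom_lookup <- function(annotation) {
  if (is.null(annotation)) return(function(f) NA_character_)
  tab <- setNames(as.character(annotation$chrom),
                  normalize_mir_ids(annotation$feature))
  function(f) {
    if (f %in% names(tab)) return(tab[[f]])
    hp <- strip_arm_suffix(f)
    if (hp %in% names(tab)) return(tab[[hp]])
    NA_character_
  }
}

#' Write the harmonization log as JSON
#'
#' @param h a `harmonization` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_harmonization_log <- function(h, path) {
  jsonlite::write_json(h$log, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
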