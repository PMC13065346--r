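# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

toy_counts <- function() {
  m <- matrix(c(10, 12, 100, 110, 0, 0,
                90, 80, 300, 280, 5, 4,
                7, 9, 0, 0, 40, 44),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("hsa-miR-21-5p", "hsa-let-7a-5p",
                                "hsa-miR-126-3p"),
                              c("CM_1", "CM_2", "Mac_1", "Mac_2",
                                "CF_1", "CF_2")))
  ev_counts(m, c(CM_1 = "CM", CM_2 = "CM", Mac_1 = "Mac", Mac_2 = "Mac",
                 CF_1 = "CF", CF_2 = "CF"))
}

write_fixture_counts <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

fixture_metadata <- function(samples, groups,
                             path = tempfile(fileext = ".tsv")) {
  write.table(data.frame(sample = samples, group = groups), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Hand-built DE tables for signature tests: a list shaped like
# fit_pairwise() output over groups CM, CF, HCMVEC, Mac.
fake_de_tables <- function(features, lfc, fdr,
                           groups = c("CM", "CF", "HCMVEC", "Mac")) {
  pairs <- combn(groups, 2)
  out <- list()
  for (k in seq_len(ncol(pairs))) {
    nm <- paste0(pairs[1, k], "_vs_", pairs[2, k])
    l <- lfc[[nm]] %||% rep(0, length(features))
    f <- fdr[[nm]] %||% rep(1, length(features))
    out[[nm]] <- data.frame(feature = features, baseMean = 100,
                            log2FC = l, SE = 1, stat = l,
                            pvalue = f, FDR = f,
                            stringsAsFactors = FALSE)
  }
  class(out) <- c("de_result", "list")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
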