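#' OTU count tables
#'
#' A count table is an integer matrix of read counts with samples as rows and
#' OTUs as columns, carrying sample IDs as row names and OTU IDs as column
#' names. `count_table()` validates and classes a matrix; most package
#' functions accept either a classed table or a bare named matrix.
#'
#' Invariants enforced at construction: unique sample and OTU IDs,
#' non-negative counts, and a positive total for every sample (empty samples
#' are meaningless downstream, where dissimilarities are undefined for them).
#'
#' @param counts numeric matrix, samples x OTUs, with dimnames.
#' @return an integer matrix of class `count_table`.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 1L, 3L, 4L), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("otu1", "otu2", "otu3")))
#' count_table(m)
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) stopf("`counts` must be a matrix (samples x OTUs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("`counts` must carry sample IDs (rownames) and OTU IDs (colnames)")
  if (anyDuplicated(rownames(counts))) stopf("duplicate sample IDs")
  if (anyDuplicated(colnames(counts))) stopf("duplicate OTU IDs")
  if (anyNA(counts) || any(counts < 0)) stopf("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    warnf("non-integer counts supplied; rounding")
  storage.mode(counts) <- "integer"
  rs <- rowSums(counts)
  if (any(rs == 0))
    stopf("samples with zero total reads: %s",
          paste(rownames(counts)[rs == 0], collapse = ", "))
  class(counts) <- c("count_table", class(counts))
  counts
}

#' @export
print.count_table <- function(x, ...) {
  m <- unclass(x)
  cat(sprintf("count_table: %d samples x %d OTUs, %s reads (depth %d-%d)\n",
              nrow(m), ncol(m), format(sum(as.numeric(m)), big.mark = ","),
              min(rowSums(m)), max(rowSums(m))))
  invisible(x)
}

# coerce to a validated plain integer matrix; used by every consumer so the
# public functions accept bare matrices too.
#' @noRd
as_count_matrix <- function(table) {
  if (inherits(table, "count_table")) return(unclass(table))
  m <- count_table(as.matrix(table))
  unclass(m)
}

#' Sample metadata table
#'
#' Validates a data frame of per-sample metadata: `sample_id`,
#' `individual_id`, `region` (one of `"oral"`, `"faecal"`), and optionally
#' `sex` (`"M"`, `"F"`, `"unknown"`), `body_mass` (g) and `tarsus` (mm).
#' Each individual may contribute at most one sample per region.
#'
#' @param meta data frame.
#' @return the validated data frame (character columns, region as character).
#' @export
sample_metadata <- function(meta) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "individual_id", "region")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stopf("metadata lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stopf("duplicate sample IDs in metadata")
  bad <- setdiff(unique(meta$region), c("oral", "faecal"))
  if (length(bad)) stopf("unknown region labels: %s", paste(bad, collapse = ", "))
  dup <- duplicated(meta[, c("individual_id", "region")])
  if (any(dup))
    stopf("individual(s) with more than one sample in a region: %s",
          paste(unique(meta$individual_id[dup]), collapse = ", "))
  if ("sex" %in% names(meta)) {
    badsex <- setdiff(unique(meta$sex), c("M", "F", "unknown", NA))
    if (length(badsex)) stopf("unknown sex labels: %s", paste(badsex, collapse = ", "))
  }
  for (col in c("body_mass", "tarsus")) {
    if (col %in% names(meta) && any(!is.na(meta[[col]]) & meta[[col]] <= 0))
      stopf("`%s` must be positive where present", col)
  }
  meta
}

#' @noRd
align_meta <- function(meta, sample_ids) {
  idx <- match(sample_ids, meta$sample_id)
  if (anyNA(idx))
    stopf("samples missing from metadata: %s",
          paste(sample_ids[is.na(idx)], collapse = ", "))
  meta[idx, , drop = FALSE]
}

#' Taxonomy table helper
#'
#' @param tax data frame with `otu_id` plus the six rank columns
#'   `kingdom`, `phylum`, `class`, `order`, `family`, `genus`; empty string
#'   means unassigned.
#' @return validated data frame.
#' @export
taxonomy_table <- function(tax) {
  tax <- as.data.frame(tax, stringsAsFactors = FALSE)
  need <- c("otu_id", "kingdom", "phylum", "class", "order", "family", "genus")
  miss <- setdiff(need, names(tax))
  if (length(miss)) stopf("taxonomy lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(tax$otu_id)) stopf("duplicate OTU IDs in taxonomy")
  for (r in need[-1]) tax[[r]][is.na(tax[[r]])] <- ""
  tax
}
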