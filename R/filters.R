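#' Remove chloroplast and phylum-unassigned OTUs
#'
#' Amplicon surveys of animal hosts routinely recover chloroplast 16S reads
#' (diet material) and OTUs that cannot be placed in any bacterial phylum
#' (likely artefacts); both are excluded before analysis. An OTU is flagged
#' when its class or order label equals `"Chloroplast"` or `"Streptophyta"`
#' (case-insensitively; reference taxonomies differ in which rank carries the
#' chloroplast label) or when its phylum is empty/unassigned. Samples whose
#' total drops to zero are removed with a warning, because downstream
#' dissimilarities are undefined for empty samples.
#'
#' @param table a [count_table()] (samples x OTUs).
#' @param tax taxonomy data frame (see [taxonomy_table()]); every OTU of
#'   `table` must have a row.
#' @return filtered `count_table`; attributes `removed_otus` (character) and
#'   `removed_read_fraction` (flagged reads / total reads) report the loss.
#' @export
filter_nonbacterial <- function(table, tax) {
  m <- as_count_matrix(table)
  tax <- taxonomy_table(tax)
  idx <- match(colnames(m), tax$otu_id)
  if (anyNA(idx))
    stopf("no taxonomy for OTU(s): %s",
          paste(colnames(m)[is.na(idx)], collapse = ", "))
  tx <- tax[idx, , drop = FALSE]
  plastid <- c("chloroplast", "streptophyta")
  flagged <- tolower(tx$class) %in% plastid |
    tolower(tx$order) %in% plastid |
    tx$phylum == "" | tolower(tx$phylum) %in% c("unassigned", "unclassified")
  removed_frac <- sum(as.numeric(m[, flagged, drop = FALSE])) / sum(as.numeric(m))
  keep <- m[, !flagged, drop = FALSE]
  rs <- rowSums(keep)
  if (any(rs == 0)) {
    warnf("dropping sample(s) emptied by contaminant filtering: %s",
          paste(rownames(keep)[rs == 0], collapse = ", "))
    keep <- keep[rs > 0, , drop = FALSE]
  }
  out <- count_table(keep)
  attr(out, "removed_otus") <- colnames(m)[flagged]
  attr(out, "removed_read_fraction") <- removed_frac
  out
}

#' Keep OTUs detected in at least `min_samples` samples
#'
#' @param table a [count_table()].
#' @param min_samples minimum number of samples with a nonzero count.
#' @return filtered `count_table` with attribute `retained_read_fraction`.
#' @export
prevalence_filter <- function(table, min_samples = 5L) {
  m <- as_count_matrix(table)
  min_samples <- check_scalar_int(min_samples, "min_samples")
  if (min_samples > nrow(m))
    stopf("min_samples (%d) exceeds the number of samples (%d)",
          min_samples, nrow(m))
  keep <- colSums(m > 0) >= min_samples
  out <- count_table(m[, keep, drop = FALSE])
  attr(out, "retained_read_fraction") <-
    sum(as.numeric(m[, keep, drop = FALSE])) / sum(as.numeric(m))
  out
}

#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads, removing the depth bias that inflates diversity in deeply
#' sequenced samples. A single draw is used, deterministic given `seed`.
#'
#' @param table a [count_table()].
#' @param depth target depth; defaults to the minimum sample total.
#' @param seed integer seed.
#' @return rarefied `count_table` (all row sums equal `depth`; OTUs are kept
#'   as columns even if their total drops to zero).
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  m <- as_count_matrix(table)
  rs <- rowSums(m)
  if (is.null(depth)) depth <- min(rs)
  depth <- check_scalar_int(depth, "depth")
  if (any(rs < depth))
    stopf("depth %d exceeds the total of sample(s): %s", depth,
          paste(rownames(m)[rs < depth], collapse = ", "))
  out <- with_seed(seed, {
    t(apply(m, 1L, function(row) {
      if (sum(row) == depth) return(row)
      otu_of_read <- rep.int(seq_along(row), row)
      tabulate(otu_of_read[sample.int(length(otu_of_read), depth)],
               nbins = length(row))
    }))
  })
  colnames(out) <- colnames(m)
  rownames(out) <- rownames(m)
  count_table(out)
}

#' Summarise OTU sharing between the two GIT regions
#'
#' Counts OTUs detected in both regions, only in oral samples, and only in
#' faecal samples, with fractions of the detected-OTU total.
#'
#' @param table a [count_table()].
#' @param meta sample metadata (see [sample_metadata()]).
#' @return data frame with rows `both`, `oral_only`, `faecal_only`.
#' @export
shared_otu_summary <- function(table, meta) {
  m <- as_count_matrix(table)
  meta <- align_meta(sample_metadata(meta), rownames(m))
  if (length(unique(meta$region)) < 2L)
    stopf("both regions must be present")
  pres <- function(r) colSums(m[meta$region == r, , drop = FALSE] > 0) > 0
  oral <- pres("oral"); faecal <- pres("faecal")
  n <- c(both = sum(oral & faecal), oral_only = sum(oral & !faecal),
         faecal_only = sum(!oral & faecal))
  data.frame(category = names(n), n_otus = as.integer(n),
             fraction = as.numeric(n) / sum(n), row.names = NULL)
}

#' Per-sample read proportions aggregated at a taxonomic rank
#'
#' @param table a [count_table()].
#' @param tax taxonomy data frame.
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @return matrix samples x rank labels; empty labels are pooled as
#'   `"Unassigned"`; each row sums to 1.
#' @export
taxon_rank_proportions <- function(table, tax,
                                   rank = c("phylum", "class", "order",
                                            "family", "genus")) {
  rank <- match.arg(rank)
  m <- as_count_matrix(table)
  tax <- taxonomy_table(tax)
  idx <- match(colnames(m), tax$otu_id)
  if (anyNA(idx))
    stopf("no taxonomy for OTU(s): %s",
          paste(colnames(m)[is.na(idx)], collapse = ", "))
  lab <- tax[[rank]][idx]
  lab[lab == ""] <- "Unassigned"
  agg <- t(rowsum(t(m), lab))
  sweep(agg, 1L, rowSums(agg), "/")
}
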