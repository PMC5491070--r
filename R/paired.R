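#' Individuals sampled in both GIT regions
#'
#' @param meta sample metadata.
#' @return data frame of class `paired_set`: `individual_id`,
#'   `oral_sample_id`, `faecal_sample_id`; errors when no individual has
#'   both samples (all downstream paired analyses are then undefined).
#' @export
paired_subset <- function(meta) {
  meta <- sample_metadata(meta)
  oral <- meta[meta$region == "oral", c("individual_id", "sample_id")]
  faec <- meta[meta$region == "faecal", c("individual_id", "sample_id")]
  both <- merge(oral, faec, by = "individual_id",
                suffixes = c("_oral", "_faecal"))
  if (nrow(both) == 0L) stopf("no individual has samples in both regions")
  out <- data.frame(individual_id = both$individual_id,
                    oral_sample_id = both$sample_id_oral,
                    faecal_sample_id = both$sample_id_faecal,
                    stringsAsFactors = FALSE)
  out <- out[order(out$individual_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("paired_set", class(out))
  out
}

#' Pearson correlation of paired alpha diversity across regions
#'
#' @param alpha output of [alpha_diversity()].
#' @param pairs a [paired_subset()] result.
#' @param metric diversity metric column.
#' @return list: `r`, `p` (two-sided), `n`.
#' @export
paired_alpha_pearson <- function(alpha, pairs,
                                 metric = c("observed", "shannon", "chao1")) {
  metric <- match.arg(metric)
  if (nrow(pairs) < 3L) stopf("need at least 3 paired individuals")
  x <- alpha[[metric]][match(pairs$oral_sample_id, alpha$sample_id)]
  y <- alpha[[metric]][match(pairs$faecal_sample_id, alpha$sample_id)]
  if (anyNA(x) || anyNA(y)) stopf("paired samples missing from alpha table")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pairs))
}

#' Per-OTU Spearman correlation of relative abundances across regions
#'
#' Restricted to OTUs detected (nonzero) in both the oral and the faecal
#' samples of the paired set. Relative abundances (count / sample total) are
#' correlated across pairs with average ranks on ties; on a rarefied table
#' the constant totals make this equivalent to correlating raw counts. An
#' OTU whose oral or faecal vector has fewer than 3 distinct values yields
#' an undefined (NA) coefficient rather than a spurious one.
#'
#' @param table a [count_table()].
#' @param pairs a [paired_subset()] result.
#' @return list of class `paired_spearman`: per-OTU data frame `rho`,
#'   `mean_rho`, `iqr` (25% and 75% quantiles), `n_otus`.
#' @export
paired_otu_spearman <- function(table, pairs) {
  m <- as_count_matrix(table)
  if (nrow(pairs) < 3L) stopf("need at least 3 paired individuals")
  mo <- m[pairs$oral_sample_id, , drop = FALSE]
  mf <- m[pairs$faecal_sample_id, , drop = FALSE]
  ro <- mo / rowSums(mo)
  rf <- mf / rowSums(mf)
  qual <- colSums(mo) > 0 & colSums(mf) > 0
  if (!any(qual)) stopf("no OTU detected in both regions of the paired set")
  rho <- vapply(which(qual), function(j) {
    x <- ro[, j]; y <- rf[, j]
    if (length(unique(x)) < 3L || length(unique(y)) < 3L) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }, 0)
  per_otu <- data.frame(otu_id = colnames(m)[qual], rho = unname(rho),
                        stringsAsFactors = FALSE)
  structure(list(per_otu = per_otu,
                 mean_rho = mean(rho, na.rm = TRUE),
                 iqr = stats::quantile(rho, c(0.25, 0.75), na.rm = TRUE,
                                       names = FALSE),
                 n_otus = sum(qual)),
            class = "paired_spearman")
}

#' @export
print.paired_spearman <- function(x, ...) {
  cat(sprintf(
    "Paired per-OTU Spearman: %d OTUs, mean rho = %.5f, IQR = %.5f ~ %.5f\n",
    x$n_otus, x$mean_rho, x$iqr[1], x$iqr[2]))
  invisible(x)
}

#' Within-individual Mantel comparison of region compositions
#'
#' Restricts a sample-by-sample distance matrix to the paired individuals'
#' oral samples and, in the same individual order, their faecal samples,
#' then Mantel-correlates the two within-region blocks: do individuals with
#' similar oral communities also have similar faecal communities?
#'
#' @param d full `dist_matrix` over samples.
#' @param pairs a [paired_subset()] result.
#' @inheritParams mantel_test
#' @return a `mantel_result`.
#' @export
paired_mantel_test <- function(d, pairs, n_perm = 9999L, seed = 1L) {
  m <- as.matrix(d)
  miss <- setdiff(c(pairs$oral_sample_id, pairs$faecal_sample_id), rownames(m))
  if (length(miss))
    stopf("paired sample(s) missing from distance matrix: %s",
          paste(miss, collapse = ", "))
  do <- m[pairs$oral_sample_id, pairs$oral_sample_id]
  df <- m[pairs$faecal_sample_id, pairs$faecal_sample_id]
  rownames(do) <- colnames(do) <- pairs$individual_id
  rownames(df) <- colnames(df) <- pairs$individual_id
  mantel_test(dist_matrix(do), dist_matrix(df), n_perm = n_perm, seed = seed)
}

#' Write the paired-correlation TSV (per-OTU rho plus a summary row)
#' @param ps a `paired_spearman` result.
#' @param path output path.
#' @export
write_paired_spearman <- function(ps, path) {
  df <- rbind(
    data.frame(otu_id = ps$per_otu$otu_id, rho = ps$per_otu$rho),
    data.frame(otu_id = "SUMMARY_mean", rho = ps$mean_rho),
    data.frame(otu_id = "SUMMARY_q25", rho = ps$iqr[1]),
    data.frame(otu_id = "SUMMARY_q75", rho = ps$iqr[2])
  )
  write_tsv(df, path)
}
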