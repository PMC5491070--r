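#' Pipeline configuration
#'
#' Validated settings for [run_pipeline()]. Unknown names are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param otu_table,taxonomy,metadata,tree input file paths.
#' @param out_dir output directory.
#' @param rarefaction_depth integer depth or `"auto"` (minimum sample
#'   total after contaminant filtering).
#' @param metrics dissimilarity metrics to analyse.
#' @param n_perm permutations for PERMANOVA and Mantel.
#' @param n_perm_diffabund permutations per OTU in the scan.
#' @param prevalence_min_samples prevalence threshold for the scan.
#' @param alpha significance threshold (applied to p and q in the scan).
#' @param seed master seed; every stage derives its own stream from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(otu_table, taxonomy, metadata, tree, out_dir,
                            rarefaction_depth = "auto",
                            metrics = c("bray", "jaccard",
                                        "unifrac_unweighted",
                                        "unifrac_weighted"),
                            n_perm = 9999L, n_perm_diffabund = 10000L,
                            prevalence_min_samples = 5L, alpha = 0.05,
                            seed = 1L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!identical(rarefaction_depth, "auto"))
    rarefaction_depth <- check_scalar_int(rarefaction_depth,
                                          "rarefaction_depth")
  structure(list(otu_table = otu_table, taxonomy = taxonomy,
                 metadata = metadata, tree = tree, out_dir = out_dir,
                 rarefaction_depth = rarefaction_depth, metrics = metrics,
                 n_perm = check_scalar_int(n_perm, "n_perm"),
                 n_perm_diffabund = check_scalar_int(n_perm_diffabund,
                                                     "n_perm_diffabund"),
                 prevalence_min_samples =
                   check_scalar_int(prevalence_min_samples,
                                    "prevalence_min_samples"),
                 alpha = alpha,
                 seed = check_scalar_int(seed, "seed", min = 0L)),
            class = "pipeline_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key=value`; blank lines and `#` comments ignored;
#' `metrics` may be a comma-separated list. Unknown keys are rejected.
#'
#' @param path config file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stopf("malformed config line(s): %s",
                      paste(lines[bad], collapse = "; "))
  vals <- stats::setNames(trimws(vapply(kv, `[[`, "", 2L)),
                          trimws(vapply(kv, `[[`, "", 1L)))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  args <- as.list(vals)
  for (k in c("n_perm", "n_perm_diffabund", "prevalence_min_samples", "seed"))
    if (k %in% names(args)) args[[k]] <- as.integer(args[[k]])
  if ("alpha" %in% names(args)) args$alpha <- as.numeric(args$alpha)
  if ("rarefaction_depth" %in% names(args) &&
      args$rarefaction_depth != "auto")
    args$rarefaction_depth <- as.integer(args$rarefaction_depth)
  if ("metrics" %in% names(args))
    args$metrics <- trimws(strsplit(args$metrics, ",")[[1]])
  do.call(pipeline_config, args)
}

#' Run the full paired-microbiota analysis
#'
#' Stages: read inputs -> contaminant filtering -> rarefaction -> alpha
#' diversity and its mixed-model region contrast -> distance matrices and
#' PCoA per metric -> PERMANOVA (individual strata) and dispersion test per
#' metric -> paired correlations (alpha Pearson, within-individual Mantel,
#' per-OTU Spearman) -> differential-abundance scan (on the
#' prevalence-filtered unrarefied counts, so the sequencing-depth offset is
#' informative) -> taxon-proportion tables. All outputs are TSV (plus
#' newick); identical config and inputs give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the computed objects and `manifest` (data
#'   frame of written files by stage).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(), file = character())
  logf <- file.path(out, "run_log.txt")
  cat(sprintf("micropair %s | seed %d | R %s\n",
              as.character(utils::packageVersion("micropair")), config$seed,
              getRversion()), file = logf)
  note <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(...))
    cat(line, "\n", file = logf, append = TRUE, sep = "")
    message(line)
  }
  emit <- function(stage, file) {
    manifest <<- rbind(manifest, data.frame(stage = stage, file = file))
  }

  raw <- read_count_table(config$otu_table)
  tax <- read_taxonomy(config$taxonomy)
  meta <- read_sample_metadata(config$metadata)
  tree <- read_otu_tree(config$tree)
  note("input", "%d samples x %d OTUs", nrow(raw), ncol(raw))

  filt <- filter_nonbacterial(raw, tax)
  note("filter", "%d OTUs kept; %.1f%% reads flagged", ncol(filt),
       100 * attr(filt, "removed_read_fraction"))
  meta <- meta[meta$sample_id %in% rownames(filt), , drop = FALSE]

  depth <- if (identical(config$rarefaction_depth, "auto"))
    min(rowSums(filt)) else config$rarefaction_depth
  rare <- rarefy(filt, depth = depth, seed = config$seed + 101L)
  note("rarefy", "depth %d", depth)

  if ("tarsus" %in% names(meta) && sum(stats::complete.cases(
        meta[, c("body_mass", "tarsus")])) >= 3L)
    meta <- add_body_condition(meta)
  write_sample_metadata(meta, file.path(out, "metadata_augmented.tsv"))
  emit("metadata", "metadata_augmented.tsv")

  alpha <- alpha_diversity(rare)
  write_tsv(alpha, file.path(out, "alpha_diversity.tsv"))
  emit("alpha", "alpha_diversity.tsv")
  contrasts <- lapply(c("observed", "shannon", "chao1"), function(mm)
    alpha_region_contrast(alpha, meta, metric = mm))
  write_alpha_contrast_table(contrasts, file.path(out, "alpha_contrast.tsv"))
  emit("alpha", "alpha_contrast.tsv")
  note("alpha", "LRT chi2: %s",
       paste(sprintf("%s %.3f", vapply(contrasts, `[[`, "", "metric"),
                     vapply(contrasts, `[[`, 0, "chi2")), collapse = ", "))

  meta_aligned <- align_meta(meta, rownames(rare))
  dists <- list()
  comm <- list()
  for (mm in config$metrics) {
    d <- distance_matrix(rare, metric = mm, tree = tree)
    dists[[mm]] <- d
    write_distance_matrix(d, file.path(out, paste0("distance_", mm, ".tsv")))
    emit("beta", paste0("distance_", mm, ".tsv"))
    ord <- pcoa(d)
    write_ordination(ord, file.path(out, paste0("pcoa_", mm, "_eig.tsv")),
                     file.path(out, paste0("pcoa_", mm, "_coords.tsv")))
    emit("beta", paste0("pcoa_", mm, "_eig.tsv"))
    emit("beta", paste0("pcoa_", mm, "_coords.tsv"))
    pm <- permanova(d, meta_aligned$region, strata = meta_aligned$individual_id,
                    n_perm = config$n_perm, seed = config$seed + 202L)
    dp <- dispersion_test(d, meta_aligned$region)
    comm[[mm]] <- list(permanova = pm, dispersion = dp)
    write_community_test_table(pm, dp, mm,
                               file.path(out, paste0("community_tests_", mm,
                                                     ".tsv")))
    emit("community", paste0("community_tests_", mm, ".tsv"))
    note("community", "%s: F %.3f R2 %.4f p %.5g | dispersion F %.3f p %.5g",
         mm, pm$pseudo_F, pm$r2, pm$p, dp$F, dp$p)
  }

  pairs <- tryCatch(paired_subset(meta_aligned), error = function(e) NULL)
  paired <- NULL
  if (!is.null(pairs) && nrow(pairs) >= 3L) {
    pear <- lapply(c("observed", "shannon", "chao1"), function(mm)
      c(metric = mm, paired_alpha_pearson(alpha, pairs, metric = mm)))
    mant <- lapply(dists, paired_mantel_test, pairs = pairs,
                   n_perm = config$n_perm, seed = config$seed + 303L)
    spear <- paired_otu_spearman(rare, pairs)
    write_paired_spearman(spear, file.path(out, "paired_otu_spearman.tsv"))
    emit("paired", "paired_otu_spearman.tsv")
    pear_df <- do.call(rbind, lapply(pear, as.data.frame))
    mant_df <- data.frame(metric = names(mant),
                          r = vapply(mant, `[[`, 0, "r"),
                          p = vapply(mant, `[[`, 0, "p"), row.names = NULL)
    write_tsv(pear_df, file.path(out, "paired_alpha_pearson.tsv"))
    write_tsv(mant_df, file.path(out, "paired_mantel.tsv"))
    emit("paired", "paired_alpha_pearson.tsv")
    emit("paired", "paired_mantel.tsv")
    note("paired", "%d pairs; mean per-OTU rho %.4f", nrow(pairs),
         spear$mean_rho)
    paired <- list(pairs = pairs, pearson = pear, mantel = mant,
                   spearman = spear)
  } else {
    note("paired", "skipped: fewer than 3 paired individuals")
  }

  prev <- prevalence_filter(filt, config$prevalence_min_samples)
  note("diffabund", "%d OTUs detected in >= %d samples (%.1f%% of reads)",
       ncol(prev), config$prevalence_min_samples,
       100 * attr(prev, "retained_read_fraction"))
  scan <- diff_abundance_scan(prev, meta, n_perm = config$n_perm_diffabund,
                              seed = config$seed + 404L,
                              totals = rowSums(filt), alpha = config$alpha)
  write_diff_abundance(scan, file.path(out, "diff_abundance.tsv"), tax = tax)
  emit("diffabund", "diff_abundance.tsv")
  note("diffabund", "%d significant OTUs (pi0 %.3f)", sum(scan$significant),
       attr(scan, "pi0"))
  if (any(scan$significant)) {
    hs <- heatmap_support(scan, prev, tree)
    write_tsv(data.frame(otu_id = rownames(hs$log10_abundance),
                         direction = hs$direction,
                         hs$log10_abundance, check.names = FALSE),
              file.path(out, "heatmap_log10_abundance.tsv"))
    write_otu_tree(hs$subtree, file.path(out, "heatmap_subtree.nwk"))
    emit("diffabund", "heatmap_log10_abundance.tsv")
    emit("diffabund", "heatmap_subtree.nwk")
  }

  for (rk in c("phylum", "class")) {
    pr <- taxon_rank_proportions(rare, tax, rank = rk)
    write_tsv(data.frame(sample_id = rownames(pr), pr, check.names = FALSE),
              file.path(out, paste0("proportions_", rk, ".tsv")))
    emit("taxa", paste0("proportions_", rk, ".tsv"))
  }
  emit("log", "run_log.txt")
  write_tsv(manifest, file.path(out, "manifest.tsv"))
  note("done", "%d artifacts", nrow(manifest))

  invisible(list(manifest = manifest, filtered = filt, rarefied = rare,
                 alpha = alpha, contrasts = contrasts, distances = dists,
                 community = comm, paired = paired, scan = scan,
                 metadata = meta))
}
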