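#' Specification for a synthetic paired two-region dataset
#'
#' The defaults emulate the motivating study design: 20 oral and 17 faecal
#' samples with 8 individuals sampled in both regions (37 samples, 29
#' birds), 1,127 OTUs, log-normal sequencing depths whose minimum over the
#' design is around 2,000 reads, Dirichlet-multinomial counts with a lower
#' concentration (= more interindividual dispersion) in faecal samples, a
#' subset of truly region-differential OTUs, region-asymmetric background
#' richness (more OTUs at non-negligible abundance in oral samples), and
#' small fractions of chloroplast and phylum-unassigned OTUs to exercise the
#' contaminant filter.
#'
#' @param n_oral,n_faecal number of oral/faecal samples.
#' @param n_paired number of individuals sampled in both regions.
#' @param n_otus total number of OTUs.
#' @param n_differential number of spiked region-differential OTUs.
#' @param region_log2_fold_effect log2 fold change of spiked OTUs (sign
#'   alternates between OTUs).
#' @param individual_sd sd of the per-individual, per-OTU log-abundance
#'   intercept shared across that individual's samples.
#' @param concentration_oral,concentration_faecal Dirichlet concentration
#'   per region (lower = more overdispersion).
#' @param depth_log_mean,depth_log_sd log-normal sequencing-depth
#'   parameters.
#' @param baseline_log_sd sd of per-OTU baseline log-abundances.
#' @param fraction_chloroplast,fraction_unassigned fractions of OTUs tagged
#'   as chloroplast / phylum-unassigned (region-independent abundance).
#' @param fraction_oral_enriched,fraction_faecal_enriched fractions of OTUs
#'   whose baseline is suppressed in the other region (background region
#'   structure driving the richness and sharing asymmetries).
#' @param enrichment_log_effect natural-log suppression applied to
#'   background-enriched OTUs in the other region.
#' @param sex_effect,smi_effect log-scale composition effects of sex and
#'   body condition; zero by default (the motivating study found none).
#' @param seed integer seed.
#' @return validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_oral = 20L, n_faecal = 17L, n_paired = 8L,
                           n_otus = 1127L, n_differential = 20L,
                           region_log2_fold_effect = 2,
                           individual_sd = 0.5,
                           concentration_oral = 100,
                           concentration_faecal = 30,
                           depth_log_mean = log(6700),
                           depth_log_sd = 0.55,
                           baseline_log_sd = 1.5,
                           fraction_chloroplast = 0.05,
                           fraction_unassigned = 0.03,
                           fraction_oral_enriched = 0.30,
                           fraction_faecal_enriched = 0.12,
                           enrichment_log_effect = 3,
                           sex_effect = 0, smi_effect = 0,
                           seed = 1L) {
  spec <- list(n_oral = check_scalar_int(n_oral, "n_oral"),
               n_faecal = check_scalar_int(n_faecal, "n_faecal"),
               n_paired = check_scalar_int(n_paired, "n_paired", min = 0L),
               n_otus = check_scalar_int(n_otus, "n_otus", min = 2L),
               n_differential = check_scalar_int(n_differential,
                                                 "n_differential", min = 0L),
               region_log2_fold_effect = region_log2_fold_effect,
               individual_sd = individual_sd,
               concentration_oral = concentration_oral,
               concentration_faecal = concentration_faecal,
               depth_log_mean = depth_log_mean,
               depth_log_sd = depth_log_sd,
               baseline_log_sd = baseline_log_sd,
               fraction_chloroplast = fraction_chloroplast,
               fraction_unassigned = fraction_unassigned,
               fraction_oral_enriched = fraction_oral_enriched,
               fraction_faecal_enriched = fraction_faecal_enriched,
               enrichment_log_effect = enrichment_log_effect,
               sex_effect = sex_effect, smi_effect = smi_effect,
               seed = check_scalar_int(seed, "seed", min = 0L))
  if (spec$n_paired > min(spec$n_oral, spec$n_faecal))
    stopf("n_paired exceeds the samples available in a region")
  if (spec$n_differential > spec$n_otus)
    stopf("n_differential exceeds n_otus")
  if (spec$concentration_oral <= 0 || spec$concentration_faecal <= 0)
    stopf("Dirichlet concentrations must be positive")
  if (spec$fraction_chloroplast + spec$fraction_unassigned >= 1)
    stopf("contaminant fractions must sum to < 1")
  class(spec) <- "synthetic_spec"
  spec
}

#' Random rooted bifurcating tree with exponential branch lengths
#'
#' Built by random sequential coalescence of the leaf set; branch lengths
#' are i.i.d. Exponential(1). Deterministic given the seed.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed integer seed.
#' @param labels optional leaf labels (defaults to `t1..tn`).
#' @return a rooted `phylo`.
#' @export
generate_tree <- function(n_leaves, seed = 1L, labels = NULL) {
  n_leaves <- check_scalar_int(n_leaves, "n_leaves", min = 2L)
  with_seed(seed, .random_coalescent_tree(n_leaves, labels))
}

#' @noRd
.random_coalescent_tree <- function(n_leaves, labels = NULL) {
  tr <- ape::rtree(n_leaves, rooted = TRUE, br = stats::rexp)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n_leaves)
    # rtree labels tips t1..tn in a random order; map them in index order
    tr$tip.label <- labels[as.integer(sub("^t", "", tr$tip.label))]
  }
  tr
}

#' Generate a synthetic paired two-region dataset with ground truth
#'
#' Per-OTU baseline log-abundances are Normal; spiked differential OTUs get
#' `+/- log(2) * region_log2_fold_effect` added in one region and
#' background-enriched OTUs are suppressed by `enrichment_log_effect` in the
#' other region; every individual carries a per-OTU Normal random intercept
#' shared across its samples. A sample's composition is a Dirichlet draw
#' around the softmax of its log-abundances with a region-specific
#' concentration, and counts are multinomial at a log-normal depth.
#' Chloroplast and unassigned-phylum OTUs are region-independent.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_dataset`: `table` ([count_table()]),
#'   `metadata`, `taxonomy`, `tree`, `ground_truth` (per-OTU `type`
#'   (`spiked`/`background`/`none`/`contaminant`) and signed log2 effect,
#'   oral-positive), `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n_samples <- spec$n_oral + spec$n_faecal
    n_ind <- n_samples - spec$n_paired
    ind_ids <- sprintf("IND%02d", seq_len(n_ind))
    paired <- ind_ids[seq_len(spec$n_paired)]
    oral_only <- ind_ids[spec$n_paired + seq_len(spec$n_oral - spec$n_paired)]
    faecal_only <- setdiff(ind_ids, c(paired, oral_only))
    meta <- rbind(
      data.frame(individual_id = c(paired, oral_only), region = "oral"),
      data.frame(individual_id = c(paired, faecal_only), region = "faecal")
    )
    meta$sample_id <- paste0(substr(meta$region, 1, 1), "_", meta$individual_id)
    sex <- stats::setNames(sample(c("M", "F"), n_ind, replace = TRUE), ind_ids)
    tarsus <- stats::setNames(stats::rnorm(n_ind, 19.5, 0.6), ind_ids)
    mass <- stats::setNames(
      stats::rnorm(n_ind, 18 + 1.6 * (tarsus - 19.5), 0.9), ind_ids)
    meta$sex <- unname(sex[meta$individual_id])
    meta$body_mass <- round(unname(mass[meta$individual_id]), 2)
    meta$tarsus <- round(unname(tarsus[meta$individual_id]), 2)
    meta <- sample_metadata(meta[, c("sample_id", "individual_id", "region",
                                     "sex", "body_mass", "tarsus")])

    otu_ids <- sprintf("OTU%04d", seq_len(spec$n_otus))
    n_chl <- round(spec$fraction_chloroplast * spec$n_otus)
    n_unz <- round(spec$fraction_unassigned * spec$n_otus)
    contaminant <- rep("", spec$n_otus)
    if (n_chl > 0) contaminant[seq_len(n_chl)] <- "chloroplast"
    if (n_unz > 0) contaminant[n_chl + seq_len(n_unz)] <- "unassigned"
    bacterial <- which(contaminant == "")

    base <- stats::rnorm(spec$n_otus, 0, spec$baseline_log_sd)
    region_shift <- numeric(spec$n_otus) # oral minus faecal, natural log
    type <- rep("none", spec$n_otus)
    type[contaminant != ""] <- "contaminant"

    spiked <- sample(bacterial, spec$n_differential)
    sgn <- rep_len(c(1, -1), spec$n_differential)
    region_shift[spiked] <- sgn * log(2) * spec$region_log2_fold_effect
    type[spiked] <- "spiked"

    pool <- setdiff(bacterial, spiked)
    n_oe <- round(spec$fraction_oral_enriched * spec$n_otus)
    n_fe <- round(spec$fraction_faecal_enriched * spec$n_otus)
    bg <- sample(pool, min(n_oe + n_fe, length(pool)))
    oe <- bg[seq_len(min(n_oe, length(bg)))]
    fe <- setdiff(bg, oe)
    region_shift[oe] <- spec$enrichment_log_effect
    region_shift[fe] <- -spec$enrichment_log_effect
    type[oe] <- "background"
    type[fe] <- "background"

    ind_effect <- matrix(stats::rnorm(n_ind * spec$n_otus, 0,
                                      spec$individual_sd),
                         nrow = n_ind, dimnames = list(ind_ids, otu_ids))

    depth <- pmax(50L, round(stats::rlnorm(n_samples, spec$depth_log_mean,
                                           spec$depth_log_sd)))
    counts <- matrix(0L, n_samples, spec$n_otus,
                     dimnames = list(meta$sample_id, otu_ids))
    smi_centered <- scale(meta$body_mass)[, 1]
    for (i in seq_len(n_samples)) {
      oralward <- if (meta$region[i] == "oral") 0.5 else -0.5
      eta <- base + oralward * region_shift +
        ind_effect[meta$individual_id[i], ] +
        spec$sex_effect * (meta$sex[i] == "M") * (seq_len(spec$n_otus) %% 2) +
        spec$smi_effect * smi_centered[i] * (seq_len(spec$n_otus) %% 2)
      p <- exp(eta - max(eta))
      p <- p / sum(p)
      conc <- if (meta$region[i] == "oral") spec$concentration_oral
              else spec$concentration_faecal
      w <- stats::rgamma(spec$n_otus, shape = conc * p, rate = 1)
      if (sum(w) == 0) w <- p
      w <- w / sum(w)
      counts[i, ] <- as.integer(stats::rmultinom(1L, depth[i], w))
    }

    taxonomy <- .synthetic_taxonomy(otu_ids, contaminant)
    tree <- .random_coalescent_tree(spec$n_otus, otu_ids)
    gt <- data.frame(
      otu_id = otu_ids, type = type,
      log2_effect_oral = region_shift / log(2),
      stringsAsFactors = FALSE
    )
    structure(list(table = count_table(counts), metadata = meta,
                   taxonomy = taxonomy, tree = tree, ground_truth = gt,
                   spec = spec),
              class = "synthetic_dataset")
  })
}

# plausible bacterial lineages for simulated OTUs (synthetic labels drawn
# from common amplicon-survey taxa), plus contaminant lineages
#' @noRd
.synthetic_taxonomy <- function(otu_ids, contaminant) {
  lineages <- matrix(c(
    "Bacteria", "Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Pseudomonadaceae", "Pseudomonas",
    "Bacteria", "Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Moraxellaceae", "Acinetobacter",
    "Bacteria", "Proteobacteria", "Alphaproteobacteria", "Rhizobiales", "Methylobacteriaceae", "Methylobacterium",
    "Bacteria", "Proteobacteria", "Betaproteobacteria", "Methylophilales", "Methylophilaceae", "Methylobacillus",
    "Bacteria", "Firmicutes", "Bacilli", "Bacillales", "Staphylococcaceae", "Staphylococcus",
    "Bacteria", "Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillaceae", "Lactobacillus",
    "Bacteria", "Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae", "",
    "Bacteria", "Actinobacteria", "Actinobacteria", "Actinomycetales", "Corynebacteriaceae", "Corynebacterium",
    "Bacteria", "Actinobacteria", "Actinobacteria", "Actinomycetales", "Nocardioidaceae", "",
    "Bacteria", "Bacteroidetes", "Flavobacteriia", "Flavobacteriales", "Flavobacteriaceae", "Chryseobacterium",
    "Bacteria", "Tenericutes", "Mollicutes", "Mycoplasmatales", "Mycoplasmataceae", "Ureaplasma",
    "Bacteria", "Deinococcus-Thermus", "Deinococci", "Deinococcales", "Deinococcaceae", "Deinococcus"
  ), ncol = 6, byrow = TRUE)
  pick <- sample.int(nrow(lineages), length(otu_ids), replace = TRUE)
  tax <- as.data.frame(lineages[pick, , drop = FALSE],
                       stringsAsFactors = FALSE)
  names(tax) <- c("kingdom", "phylum", "class", "order", "family", "genus")
  chl <- contaminant == "chloroplast"
  tax$phylum[chl] <- "Cyanobacteria"
  tax$class[chl] <- "Chloroplast"
  tax$order[chl] <- "Streptophyta"
  tax$family[chl] <- ""
  tax$genus[chl] <- ""
  unz <- contaminant == "unassigned"
  tax$phylum[unz] <- ""
  tax$class[unz] <- ""
  tax$order[unz] <- ""
  tax$family[unz] <- ""
  tax$genus[unz] <- ""
  taxonomy_table(cbind(data.frame(otu_id = otu_ids, stringsAsFactors = FALSE),
                       tax))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d samples (%d oral, %d faecal, %d paired), %d OTUs\n",
    nrow(x$table), sum(x$metadata$region == "oral"),
    sum(x$metadata$region == "faecal"), x$spec$n_paired, ncol(x$table)))
  invisible(x)
}

#' Write a synthetic dataset to a directory in the package's file formats
#'
#' Emits the count table, taxonomy, metadata and newick tree exactly as the
#' readers expect, plus the ground-truth TSV and the spec as a key=value
#' sidecar for reproducibility.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(dataset$table, file.path(dir, "otu_table.tsv"))
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_sample_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_otu_tree(dataset$tree, file.path(dir, "tree.nwk"))
  write_tsv(dataset$ground_truth, file.path(dir, "ground_truth.tsv"))
  sp <- dataset$spec
  writeLines(paste0(names(sp), "=", vapply(sp, format, "")),
             file.path(dir, "spec.txt"))
  invisible(dir)
}
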