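test_that("count_table enforces its invariants", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_s3_class(count_table(m), "count_table")
  bad <- m; rownames(bad) <- c("a", "a")
  expect_error(count_table(bad), "duplicate sample")
  bad <- m; bad[1, ] <- -1L
  expect_error(count_table(bad), "non-negative")
  bad <- m; bad[1, ] <- 0L
  expect_error(count_table(bad), "zero total")
  expect_error(count_table(unname(m)), "IDs")
})

test_that("table/taxonomy/metadata/tree round-trip through their files", {
  ct <- random_count_table(5, 12, seed = 3)
  tdir <- withr::local_tempdir()
  f <- file.path(tdir, "tab.tsv")
  write_count_table(ct, f)
  expect_equal(unclass(read_count_table(f)), unclass(ct))
  # BIOM-TSV dialect: leading "#OTU ID"
  lines <- readLines(f)
  lines[1] <- sub("^otu_id", "#OTU ID", lines[1])
  writeLines(lines, f)
  expect_equal(unclass(read_count_table(f)), unclass(ct))

  tax <- data.frame(otu_id = colnames(ct), kingdom = "Bacteria",
                    phylum = "Firmicutes", class = "Bacilli",
                    order = "Bacillales", family = "", genus = "")
  ftax <- file.path(tdir, "tax.tsv")
  write_taxonomy(tax, ftax)
  expect_equal(read_taxonomy(ftax)$phylum, tax$phylum)

  meta <- random_meta()
  fmeta <- file.path(tdir, "meta.tsv")
  write_sample_metadata(meta, fmeta)
  expect_equal(read_sample_metadata(fmeta)$sample_id, meta$sample_id)

  tr <- generate_tree(8, seed = 5)
  ftr <- file.path(tdir, "t.nwk")
  write_otu_tree(tr, ftr)
  tr2 <- read_otu_tree(ftr)
  expect_setequal(tr2$tip.label, tr$tip.label)
})

test_that("contaminant filter removes chloroplast and unassigned-phylum OTUs", {
  m <- matrix(c(10L, 5L, 3L, 2L, 7L, 1L), 2, 3,
              dimnames = list(c("s1", "s2"), c("good", "chl", "unk")))
  tax <- data.frame(otu_id = c("good", "chl", "unk"),
                    kingdom = "Bacteria",
                    phylum = c("Firmicutes", "Cyanobacteria", ""),
                    class = c("Bacilli", "Chloroplast", ""),
                    order = c("Bacillales", "Streptophyta", ""),
                    family = "", genus = "")
  out <- filter_nonbacterial(count_table(m), tax)
  expect_equal(colnames(out), "good")
  # case-insensitive, order-level labels too
  tax$class <- c("Bacilli", "x", "y")
  tax$order <- c("Bacillales", "streptophyta", "z")
  tax$phylum[3] <- "Firmicutes"
  out2 <- filter_nonbacterial(count_table(m), tax)
  expect_setequal(colnames(out2), c("good", "unk"))
  # identity on all-bacterial tables, and idempotence
  ct <- random_count_table(4, 10, seed = 2)
  tax_ok <- data.frame(otu_id = colnames(ct), kingdom = "Bacteria",
                       phylum = "Proteobacteria", class = "Alpha",
                       order = "o", family = "f", genus = "g")
  once <- filter_nonbacterial(ct, tax_ok)
  expect_equal(unclass(once), unclass(ct), ignore_attr = TRUE)
  twice <- filter_nonbacterial(once, tax_ok)
  expect_equal(unclass(twice), unclass(once), ignore_attr = TRUE)
  expect_error(filter_nonbacterial(ct, tax_ok[-1, ]), "otu001")
})

test_that("flagged read fraction equals the direct recount", {
  set.seed(9)
  ct <- random_count_table(6, 50, seed = 9)
  flagged <- sample(colnames(ct), 10)
  tax <- data.frame(otu_id = colnames(ct), kingdom = "Bacteria",
                    phylum = "Firmicutes", class = "Bacilli", order = "o",
                    family = "", genus = "")
  tax$phylum[tax$otu_id %in% flagged] <- ""
  out <- filter_nonbacterial(ct, tax)
  expect_equal(ncol(out), 40)
  m <- unclass(ct)
  expect_close(attr(out, "removed_read_fraction"),
               sum(m[, flagged]) / sum(m))
})

test_that("prevalence filter matches a brute-force recount", {
  ct <- random_count_table(8, 40, seed = 4, lambda = 0.6)
  for (k in c(1L, 3L, 5L)) {
    out <- prevalence_filter(ct, k)
    keep <- names(which(colSums(unclass(ct) > 0) >= k))
    expect_setequal(colnames(out), keep)
  }
  # boundary: present in exactly min_samples samples is retained
  m <- matrix(0L, 5, 2, dimnames = list(paste0("s", 1:5), c("a", "b")))
  m[, 1] <- 1L
  m[1:4, 2] <- 1L
  expect_equal(colnames(prevalence_filter(count_table(m), 5)), "a")
  expect_error(prevalence_filter(ct, 9), "exceeds")
  # min_samples = 1 removes only all-zero columns
  m2 <- unclass(ct); m2[, 1] <- 0L
  out1 <- prevalence_filter(count_table(m2), 1)
  expect_setequal(colnames(out1),
                  colnames(m2)[colSums(m2 > 0) > 0])
})

test_that("rarefaction conserves depth, zeros, and the hypergeometric mean", {
  ct <- random_count_table(4, 15, seed = 6, lambda = 30)
  r <- rarefy(ct, depth = 100, seed = 42)
  expect_true(all(rowSums(r) == 100))
  expect_true(all(unclass(r)[unclass(ct) == 0] == 0))
  # determinism
  expect_identical(unclass(rarefy(ct, 100, seed = 42)), unclass(r))
  expect_false(identical(unclass(rarefy(ct, 100, seed = 43)), unclass(r)))
  # full-depth sample passes through unchanged
  m <- unclass(ct)[1, , drop = FALSE]
  one <- count_table(m)
  expect_equal(unclass(rarefy(one, depth = sum(m), seed = 1)), m,
               ignore_attr = TRUE)
  expect_error(rarefy(ct, depth = 10^6, seed = 1), "exceeds")
  # mean over many draws approximates depth * proportion (hypergeometric)
  row <- c(a = 50L, b = 30L, c = 20L)
  tot <- sum(row); depth <- 40L
  draws <- vapply(1:2000, function(s) {
    unclass(rarefy(count_table(rbind(s1 = row)), depth, seed = s))[1, "a"]
  }, 0L)
  expv <- depth * row[["a"]] / tot
  se <- sqrt(depth * (row[["a"]] / tot) * (1 - row[["a"]] / tot) *
               (tot - depth) / (tot - 1)) / sqrt(2000)
  expect_lt(abs(mean(draws) - expv), 3 * se)
})

test_that("shared-OTU summary equals set-operation oracle", {
  meta <- random_meta(4, 4, 2, seed = 11)
  ct <- random_count_table(nrow(meta), 30, seed = 11, lambda = 0.8)
  m <- unclass(ct)
  rownames(m) <- meta$sample_id
  ct <- count_table(m)
  s <- shared_otu_summary(ct, meta)
  reg <- meta$region[match(rownames(m), meta$sample_id)]
  oral <- colnames(m)[colSums(m[reg == "oral", , drop = FALSE]) > 0]
  faecal <- colnames(m)[colSums(m[reg == "faecal", , drop = FALSE]) > 0]
  expect_equal(s$n_otus[s$category == "both"], length(intersect(oral, faecal)))
  expect_equal(s$n_otus[s$category == "oral_only"], length(setdiff(oral, faecal)))
  expect_equal(s$n_otus[s$category == "faecal_only"], length(setdiff(faecal, oral)))
  expect_close(sum(s$fraction), 1)
  meta_one <- meta[meta$region == "oral", ]
  ct_one <- count_table(unclass(ct)[meta_one$sample_id, , drop = FALSE])
  expect_error(shared_otu_summary(ct_one, meta_one), "both regions")
})

test_that("taxon rank proportions equal group-sum / row-sum", {
  ct <- random_count_table(5, 12, seed = 13)
  phyla <- rep_len(c("Firmicutes", "Proteobacteria", ""), 12)
  tax <- data.frame(otu_id = colnames(ct), kingdom = "Bacteria",
                    phylum = phyla, class = "c", order = "o", family = "f",
                    genus = "g")
  pr <- taxon_rank_proportions(ct, tax, "phylum")
  expect_close(unname(rowSums(pr)), rep(1, 5))
  m <- unclass(ct)
  lab <- ifelse(phyla == "", "Unassigned", phyla)
  for (lv in unique(lab)) {
    expect_close(unname(pr[, lv]),
                 unname(rowSums(m[, lab == lv, drop = FALSE]) / rowSums(m)))
  }
  # single-label table gives proportion 1
  tax$phylum <- "Firmicutes"
  expect_close(unname(taxon_rank_proportions(ct, tax, "phylum")[, 1]),
               rep(1, 5))
})

test_that("operations leave their inputs unmodified", {
  ct <- random_count_table(5, 20, seed = 8)
  snapshot <- unclass(ct) + 0L
  tax <- data.frame(otu_id = colnames(ct), kingdom = "Bacteria",
                    phylum = "Firmicutes", class = "c", order = "o",
                    family = "f", genus = "g")
  invisible(filter_nonbacterial(ct, tax))
  invisible(prevalence_filter(ct, 2))
  invisible(rarefy(ct, 20, seed = 1))
  invisible(taxon_rank_proportions(ct, tax, "phylum"))
  expect_identical(unclass(ct) + 0L, snapshot)
})
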