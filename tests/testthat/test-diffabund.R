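test_that("Box-Cox transform and profile-likelihood fit behave", {
  expect_close(boxcox_transform(exp(1), 0), 1)
  expect_close(boxcox_transform(c(2, 5), 1), c(1, 4))
  expect_close(boxcox_transform(4, 0.5), (2 - 1) / 0.5)
  # monotone increasing for any lambda
  y <- sort(runif(20, 0.1, 10))
  for (l in c(-1.5, -0.3, 0, 0.7, 2))
    expect_true(all(diff(boxcox_transform(y, l)) > 0))
  expect_error(boxcox_transform(c(1, -2), 1), "positive")
  expect_error(boxcox_fit(c(0, 1, 2)), "positive")
  # log-normal data recover lambda ~ 0; shifted-Gaussian recover ~ 1
  set.seed(51)
  expect_lt(abs(boxcox_fit(exp(rnorm(500)))$lambda), 0.2)
  expect_lt(abs(boxcox_fit(rnorm(500, 50, 5))$lambda - 1), 0.35)
})

test_that("Box-Cox profile likelihood agrees with MASS::boxcox", {
  skip_if_not_installed("MASS")
  set.seed(52)
  y <- rgamma(200, 3, 0.5)
  ours <- boxcox_fit(y)$lambda
  bc <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  theirs <- bc$x[which.max(bc$y)]
  expect_lt(abs(ours - theirs), 0.02)
})

test_that("profiled LMM deviance matches the variance-grid oracle", {
  set.seed(61)
  for (rep in 1:3) {
    ind <- rep(sprintf("I%d", 1:4), each = 3)
    reg <- rep(c("faecal", "oral", "oral"), 4)
    y <- rnorm(12) + 0.6 * (reg == "oral") + rep(rnorm(4, sd = 0.8), each = 3)
    X <- cbind(1, as.integer(reg == "oral"))
    f <- lme_fit_ml(y, reg, ind)
    oracle <- lmm_griddev_oracle(y, X, ind)
    expect_lt(abs(f$deviance - oracle), 1e-4)
    expect_lte(f$deviance, oracle + 1e-6) # profile optimum is the minimum
  }
})

test_that("deviance change is non-negative for nested fits", {
  set.seed(62)
  for (rep in 1:200) {
    n_ind <- sample(3:8, 1)
    per <- sample(1:3, 1)
    ind <- rep(sprintf("I%d", seq_len(n_ind)), each = per)
    reg <- sample(c("oral", "faecal"), length(ind), replace = TRUE)
    if (length(unique(reg)) < 2) reg[1] <- setdiff(c("oral", "faecal"), reg)[1]
    y <- rnorm(length(ind)) + rep(rnorm(n_ind), each = per)
    full <- lme_fit_ml(y, reg, ind)
    null <- lme_fit_ml(y, NULL, ind)
    expect_gte(null$deviance - full$deviance, -1e-6)
  }
})

test_that("permutation p-value: floor, determinism and degenerate input", {
  meta <- random_meta(6, 6, 4, seed = 71)
  set.seed(71)
  totals <- rpois(12, 5000) + 1000
  counts <- rpois(12, 40)
  r1 <- otu_permutation_pvalue(counts, totals, meta$region,
                               meta$individual_id, n_perm = 99, seed = 5)
  r2 <- otu_permutation_pvalue(counts, totals, meta$region,
                               meta$individual_id, n_perm = 99, seed = 5)
  expect_identical(r1, r2)
  expect_gte(r1$p, 1 / 100)
  # a huge injected effect reaches the permutation floor 1/(n_perm+1)
  strong <- counts + 400L * (meta$region == "oral")
  rs <- otu_permutation_pvalue(strong, totals, meta$region,
                               meta$individual_id, n_perm = 99, seed = 5)
  expect_equal(rs$p, 1 / 100)
  expect_gt(rs$coef_region, 0)
  # constant counts with constant totals -> warning, ddev 0, p 1
  expect_warning(
    r0 <- otu_permutation_pvalue(rep(7L, 12), rep(5000, 12), meta$region,
                                 meta$individual_id, n_perm = 49, seed = 1),
    "constant")
  expect_equal(r0$dev_change, 0)
  expect_equal(r0$p, 1)
})

test_that("Storey q-values reduce to BH at pi0 = 1 and estimate pi0 on null", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_close(as.numeric(storey_qvalue(p, pi0 = 1)), rep(0.04, 4))
  set.seed(81)
  p2 <- runif(300)
  expect_close(as.numeric(storey_qvalue(p2, pi0 = 1)),
               p.adjust(p2, "BH"), tol = 1e-12)
  expect_equal(as.numeric(storey_qvalue(rep(1, 4))), rep(1, 4))
  # q preserves the ordering of p and stays <= pi0
  q <- storey_qvalue(p2)
  expect_true(all(diff(q[order(p2)]) >= -1e-12))
  expect_true(all(q <= attr(q, "pi0") + 1e-12))
  # pi0 estimated near 1 on uniform p-values
  set.seed(82)
  q2 <- storey_qvalue(runif(1000))
  expect_gte(attr(q2, "pi0"), 0.85)
  expect_lte(attr(q2, "pi0"), 1)
  expect_error(storey_qvalue(numeric(0)), "empty")
  expect_error(storey_qvalue(c(0.5, 0)), "0, 1")
})

test_that("scan flags spiked OTUs, sets directions, ignores column order", {
  meta <- random_meta(10, 10, 8, seed = 91)
  spec <- synthetic_spec(n_oral = 10, n_faecal = 10, n_paired = 8,
                         n_otus = 60, n_differential = 6,
                         region_log2_fold_effect = 3,
                         fraction_chloroplast = 0, fraction_unassigned = 0,
                         fraction_oral_enriched = 0,
                         fraction_faecal_enriched = 0, seed = 91)
  ds <- generate_dataset(spec)
  tab <- prevalence_filter(ds$table, 5)
  scan <- diff_abundance_scan(tab, ds$metadata, n_perm = 99, seed = 7,
                              totals = rowSums(ds$table))
  expect_s3_class(scan, "diff_abundance")
  expect_true(all(scan$dev_change >= 0))
  expect_true(all(scan$p >= 1 / 100 & scan$p <= 1))
  expect_identical(scan$significant, scan$p < 0.05 & scan$q < 0.05)
  # q preserves p ordering
  expect_true(all(diff(scan$q[order(scan$p)]) >= -1e-12))
  # column order invariance
  perm <- sample(ncol(tab))
  tab2 <- count_table(unclass(tab)[, perm])
  scan2 <- diff_abundance_scan(tab2, ds$metadata, n_perm = 99, seed = 7,
                               totals = rowSums(ds$table))
  ix <- match(scan$otu_id, scan2$otu_id)
  expect_equal(scan$p, scan2$p[ix])
  expect_equal(scan$dev_change, scan2$dev_change[ix])
  # directions match the ground truth for detected spiked OTUs
  gt <- ds$ground_truth
  hit <- scan[scan$significant & scan$otu_id %in%
                gt$otu_id[gt$type == "spiked"], ]
  if (nrow(hit)) {
    eff <- gt$log2_effect_oral[match(hit$otu_id, gt$otu_id)]
    expect_identical(hit$direction, ifelse(eff > 0, "+oral", "+faecal"))
  }
})

test_that("direction flag equals the sign of the offset-adjusted contrast", {
  meta <- random_meta(4, 4, 4, seed = 95)
  totals <- rep(10000L, 8)
  up <- ifelse(meta$region == "oral", 600L, 30L)
  down <- ifelse(meta$region == "oral", 30L, 600L)
  m <- cbind(up = up, down = down,
             filler = 10000L - up - down)
  rownames(m) <- meta$sample_id
  # the constant filler OTU legitimately warns and returns ddev 0
  scan <- suppressWarnings(
    diff_abundance_scan(count_table(m), meta, n_perm = 49, seed = 2))
  expect_equal(scan$direction[scan$otu_id == "up"], "+oral")
  expect_equal(scan$direction[scan$otu_id == "down"], "+faecal")
})

test_that("heatmap support orders significant OTUs by the phylogeny", {
  meta <- random_meta(6, 6, 6, seed = 97)
  set.seed(97)
  m <- matrix(rpois(12 * 8, 30) + 1L, 12, 8,
              dimnames = list(meta$sample_id, sprintf("OTU%d", 1:8)))
  scan <- data.frame(otu_id = colnames(m), dev_change = 1, p = 0.01,
                     q = 0.01, direction = "+oral",
                     significant = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
                                     FALSE, FALSE))
  tree <- generate_tree(8, seed = 97, labels = colnames(m))
  hs <- heatmap_support(scan, count_table(m), tree)
  expect_setequal(rownames(hs$log10_abundance),
                  scan$otu_id[scan$significant])
  expect_identical(rownames(hs$log10_abundance), hs$subtree$tip.label)
  expect_close(hs$log10_abundance[1, 1],
               log10(m[1, rownames(hs$log10_abundance)[1]] + 1))
})
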