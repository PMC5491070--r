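test_that("strata engine enumerates the paired design completely", {
  # 8 two-sample individuals + 21 singletons: exactly 2^8 = 256 arrangements
  meta <- random_meta(20, 17, 8, seed = 1)
  sp <- strata_permutations(meta, n_perm = 9999, seed = 1)
  expect_true(sp$exhaustive)
  expect_equal(sp$n_distinct, 256)
  expect_equal(nrow(unique(as.data.frame(sp$perms))), 256)
  # first row is the observed labelling
  expect_equal(unname(sp$perms[1, ]), meta$region)
  # every permutation preserves each individual's label multiset
  for (i in seq_len(nrow(sp$perms))) {
    tb0 <- table(meta$individual_id, meta$region)
    tb <- table(meta$individual_id, factor(sp$perms[i, ],
                                           levels = colnames(tb0)))
    expect_true(all(tb == tb0))
  }
  # enumeration only triggers at n_perm >= 256
  sp2 <- strata_permutations(meta, n_perm = 255, seed = 1)
  expect_false(sp2$exhaustive)
  expect_equal(nrow(sp2$perms), 255)
  # all-singleton design: only the identity
  meta1 <- meta[!duplicated(meta$individual_id), ]
  sp3 <- strata_permutations(meta1, n_perm = 100, seed = 1)
  expect_true(sp3$exhaustive)
  expect_equal(nrow(sp3$perms), 1)
  expect_error(strata_permutations(meta, n_perm = 0), "n_perm")
})

test_that("PERMANOVA reproduces the equal-distance hand partition", {
  # n = 4, two groups of 2, all pairwise distances 1:
  # SS_total = 6/4 = 1.5, SS_within = 2 * (1/2) = 1, SS_effect = 0.5
  # F = (0.5/1)/(1/2) = 1, R2 = 1/3; all permutations tie -> p = 1
  m <- matrix(1, 4, 4) - diag(4)
  rownames(m) <- colnames(m) <- paste0("s", 1:4)
  res <- permanova(dist_matrix(m), c("a", "a", "b", "b"), n_perm = 999,
                   seed = 1)
  expect_close(res$pseudo_F, 1)
  expect_close(res$r2, 1 / 3)
  expect_equal(res$p, 1)
  expect_close(res$ss_total, 1.5)
  expect_close(res$ss_within, 1)
  expect_equal(res$df_effect + res$df_residual, 3)
})

test_that("PERMANOVA agrees with vegan::adonis2 on F and R2", {
  ct <- random_count_table(9, 30, seed = 12)
  d <- distance_matrix(ct, "bray")
  gr <- rep(c("a", "b", "c"), each = 3)
  res <- permanova(d, gr, n_perm = 99, seed = 5)
  ad <- vegan::adonis2(as.dist(unclass(d)) ~ gr, permutations = 99)
  expect_close(res$pseudo_F, ad$F[1], tol = 1e-10)
  expect_close(res$r2, ad$R2[1], tol = 1e-10)
  expect_equal(res$df_effect, ad$Df[1])
  expect_equal(res$df_residual, ad$Df[2])
})

test_that("PERMANOVA F and R2 are scale invariant; separation maxes F", {
  ct <- random_count_table(8, 20, seed = 13)
  d <- unclass(distance_matrix(ct, "bray"))
  gr <- rep(c("a", "b"), each = 4)
  r1 <- permanova(dist_matrix(d), gr, n_perm = 99, seed = 2)
  r2 <- permanova(dist_matrix(d * 3.7), gr, n_perm = 99, seed = 2)
  expect_close(r1$pseudo_F, r2$pseudo_F, tol = 1e-10)
  expect_close(r1$r2, r2$r2, tol = 1e-10)
  expect_close(r1$p, r2$p)
  # two tight, well-separated clouds: observed F is the enumeration maximum
  sep <- matrix(1, 6, 6) - diag(6)
  sep[1:3, 1:3] <- 0.01 * (matrix(1, 3, 3) - diag(3))
  sep[4:6, 4:6] <- 0.01 * (matrix(1, 3, 3) - diag(3))
  rownames(sep) <- colnames(sep) <- paste0("s", 1:6)
  rs <- permanova(dist_matrix(sep), rep(c("a", "b"), each = 3),
                  n_perm = 9999, seed = 3)
  expect_true(rs$exhaustive)
  # C(6,3) = 20 arrangements; observed and its mirror share the max F
  expect_equal(rs$p, 2 / 20)
})

test_that("Monte-Carlo p converges to the exact enumeration", {
  ct <- random_count_table(8, 15, seed = 22)
  d <- distance_matrix(ct, "bray")
  gr <- rep(c("a", "b"), each = 4)
  exact <- permanova(d, gr, n_perm = 9999, seed = 1, method = "exact")
  expect_true(exact$exhaustive)
  mc <- permanova(d, gr, n_perm = 10000, seed = 7, method = "montecarlo")
  tol <- 3 * sqrt(exact$p * (1 - exact$p) / 10000) + 2 / 10001
  expect_lt(abs(mc$p - exact$p), tol)
})

test_that("dispersion test recovers hand-placed centroid geometry", {
  # two equilateral triangles, side 1: every vertex sits 1/sqrt(3) from its
  # group centroid
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  pts <- rbind(tri, tri + 10)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("s", 1:6)
  res <- suppressWarnings(
    dispersion_test(dist_matrix(d), rep(c("a", "b"), each = 3)))
  expect_close(unname(res$distances), rep(1 / sqrt(3), 6), tol = 1e-8)
  expect_close(unname(diff(res$group_means)), 0, tol = 1e-8)
  # identical samples within a group -> zero distances for that group
  z <- matrix(0, 5, 5)
  z[4:5, 1:3] <- 1; z[1:3, 4:5] <- 1
  z[4, 5] <- z[5, 4] <- 0.5
  rownames(z) <- colnames(z) <- paste0("s", 1:5)
  res2 <- suppressWarnings(
    dispersion_test(dist_matrix(z), c("a", "a", "a", "b", "b")))
  expect_close(unname(res2$distances[1:3]), rep(0, 3), tol = 1e-8)
  expect_error(dispersion_test(dist_matrix(z), c("a", "a", "a", "a", "b")),
               "single sample")
})

test_that("dispersion distances match the coordinate-space oracle", {
  set.seed(14)
  pts <- matrix(rnorm(24), 12, 2)
  gr <- rep(c("a", "b"), each = 6)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("s", 1:12)
  res <- dispersion_test(dist_matrix(d), gr)
  direct <- unlist(lapply(split(seq_len(12), gr), function(ix) {
    ctr <- colMeans(pts[ix, ])
    sqrt(rowSums((pts[ix, ] - rep(ctr, each = length(ix)))^2))
  }))
  ord <- order(as.integer(sub("s", "", names(res$distances))))
  expect_close(unname(res$distances),
               unname(direct[order(unlist(split(seq_len(12), gr)))]),
               tol = 1e-8)
})

test_that("Mantel statistic behaves and agrees with vegan", {
  ct <- random_count_table(8, 20, seed = 19)
  d1 <- distance_matrix(ct, "bray")
  res_same <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_close(res_same$r, 1)
  d2 <- dist_matrix(unclass(d1) * 2)
  expect_close(mantel_test(d1, d2, n_perm = 99, seed = 1)$r, 1)
  ct2 <- random_count_table(8, 20, seed = 20)
  d3 <- distance_matrix(ct2, "bray")
  res <- mantel_test(d1, d3, n_perm = 999, seed = 4)
  vg <- vegan::mantel(as.dist(unclass(d1)), as.dist(unclass(d3)),
                      permutations = 999)
  expect_close(res$r, vg$statistic, tol = 1e-10)
  m4 <- unclass(d3)
  rownames(m4) <- colnames(m4) <- paste0("x", 1:8)
  expect_error(mantel_test(d1, dist_matrix(m4)), "different samples")
})
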