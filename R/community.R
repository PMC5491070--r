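#' Strata-constrained permutations of region labels
#'
#' Permutes region labels only within an individual, the permutation scheme
#' appropriate when the same bird contributes samples to both regions:
#' exchangeability holds within, not across, individuals. When the number of
#' distinct within-stratum label arrangements does not exceed `n_perm` the
#' space is enumerated completely and `exhaustive = TRUE` is returned; in
#' the motivating design (8 individuals with one sample in each region plus
#' singletons) the space collapses to exactly `2^8 = 256` arrangements.
#'
#' @param meta sample metadata (uses `region` and `individual_id`), or a
#'   data frame with those columns.
#' @param n_perm maximum number of permutations.
#' @param seed integer seed for Monte-Carlo sampling.
#' @return list with `perms` (matrix, one permuted label vector per row,
#'   first row the observed labels when exhaustive), `exhaustive`,
#'   `n_distinct`.
#' @export
strata_permutations <- function(meta, n_perm = 9999L, seed = 1L) {
  n_perm <- check_scalar_int(n_perm, "n_perm")
  region <- as.character(meta$region)
  individual <- as.character(meta$individual_id)
  n <- length(region)
  strata <- split(seq_len(n), individual)
  # distinct arrangements per stratum: multiset permutations of its labels
  counts <- vapply(strata, function(ix) {
    tab <- table(region[ix])
    exp(lgamma(length(ix) + 1) - sum(lgamma(tab + 1)))
  }, 0)
  n_distinct <- prod(counts)
  if (is.finite(n_distinct) && round(n_distinct) <= n_perm) {
    per_stratum <- lapply(strata, function(ix) multiset_perms(region[ix]))
    combos <- Reduce(function(acc, k) {
      nk <- nrow(per_stratum[[k]])
      if (is.null(acc)) return(matrix(seq_len(nk), ncol = 1))
      acc2 <- acc[rep(seq_len(nrow(acc)), each = nk), , drop = FALSE]
      cbind(acc2, rep(seq_len(nk), times = nrow(acc)))
    }, seq_along(per_stratum), NULL)
    perms <- matrix("", nrow = nrow(combos), ncol = n)
    for (k in seq_along(strata))
      perms[, strata[[k]]] <- per_stratum[[k]][combos[, k], , drop = FALSE]
    # put the observed labelling first
    obs <- which(apply(perms, 1L, function(r) all(r == region)))[1]
    perms <- perms[c(obs, setdiff(seq_len(nrow(perms)), obs)), , drop = FALSE]
    list(perms = perms, exhaustive = TRUE, n_distinct = nrow(perms))
  } else {
    perms <- with_seed(seed, {
      t(replicate(n_perm, {
        out <- region
        for (ix in strata) out[ix] <- out[ix][sample.int(length(ix))]
        out
      }))
    })
    list(perms = perms, exhaustive = FALSE, n_distinct = n_distinct)
  }
}

# distinct arrangements of a label multiset, one per row
#' @noRd
multiset_perms <- function(labs) {
  if (length(labs) <= 1L) return(matrix(labs, nrow = 1))
  blocks <- lapply(unique(labs), function(u) {
    rest <- labs[-match(u, labs)]
    sub <- multiset_perms(rest)
    cbind(rep(u, nrow(sub)), sub)
  })
  do.call(rbind, blocks)
}

#' PERMANOVA: distance-based one-factor analysis of variance
#'
#' Partitions the total sum of squared dissimilarities
#' (`SS_total = sum_{i<j} d_ij^2 / n`) into a between-group and a
#' within-group component (`SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`),
#' and tests the pseudo-F statistic by permuting group labels - within
#' individual strata when `strata` is supplied. With a feasible permutation
#' space the null is enumerated exactly and `p = #(F_perm >= F_obs) / N`
#' over all `N` distinct arrangements (the observed one included); otherwise
#' Monte-Carlo sampling gives `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#' Ties count as exceedances.
#'
#' @param d `dist_matrix` (or symmetric matrix).
#' @param groups group labels aligned to the rows of `d`.
#' @param strata optional individual IDs aligned to the rows of `d`.
#' @param n_perm number of permutations (also the enumeration cutoff).
#' @param seed integer seed.
#' @param method `"auto"` (exact when feasible), `"exact"`, `"montecarlo"`.
#' @return object of class `permanova_result`.
#' @export
permanova <- function(d, groups, strata = NULL, n_perm = 9999L, seed = 1L,
                      method = c("auto", "exact", "montecarlo")) {
  method <- match.arg(method)
  m <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) stopf("`groups` misaligned with `d`")
  if (length(unique(groups)) < 2L) stopf("need at least two groups")
  d2 <- m^2
  fstat <- function(g) {
    n <- length(g)
    ss_tot <- sum(d2[upper.tri(d2)]) / n
    ss_w <- 0
    for (lv in unique(g)) {
      ix <- which(g == lv)
      if (length(ix) > 1L)
        ss_w <- ss_w + sum(d2[ix, ix][upper.tri(d2[ix, ix])]) / length(ix)
    }
    a <- length(unique(g))
    df_e <- a - 1L
    df_r <- n - a
    ss_e <- ss_tot - ss_w
    list(F = (ss_e / df_e) / (ss_w / df_r), r2 = ss_e / ss_tot,
         ss_total = ss_tot, ss_effect = ss_e, ss_within = ss_w,
         df_effect = df_e, df_residual = df_r)
  }
  obs <- fstat(groups)
  meta <- data.frame(region = groups,
                     individual_id = if (is.null(strata))
                       paste0("u", seq_along(groups)) else as.character(strata))
  if (is.null(strata)) {
    # unconstrained: one stratum containing everything
    meta$individual_id <- "all"
  }
  sp <- strata_permutations(meta, n_perm = n_perm, seed = seed)
  use_exact <- switch(method, auto = sp$exhaustive, exact = TRUE,
                      montecarlo = FALSE)
  if (method == "exact" && !sp$exhaustive)
    stopf("exact enumeration infeasible: %.3g distinct permutations",
          sp$n_distinct)
  if (method == "montecarlo" && sp$exhaustive) {
    sp <- list(perms = with_seed(seed, t(replicate(n_perm, {
      out <- groups
      for (ix in split(seq_along(groups), meta$individual_id))
        out[ix] <- out[ix][sample.int(length(ix))]
      out
    }))), exhaustive = FALSE, n_distinct = sp$n_distinct)
  }
  fs <- apply(sp$perms, 1L, function(g) fstat(g)$F)
  if (use_exact && sp$exhaustive) {
    p <- sum(fs >= obs$F - 1e-12) / length(fs)
    n_used <- length(fs)
  } else {
    p <- (1 + sum(fs >= obs$F - 1e-12)) / (1 + nrow(sp$perms))
    n_used <- nrow(sp$perms)
  }
  structure(list(
    df_effect = obs$df_effect, df_residual = obs$df_residual,
    ss_effect = obs$ss_effect, ss_within = obs$ss_within,
    ss_total = obs$ss_total,
    ms_effect = obs$ss_effect / obs$df_effect,
    ms_within = obs$ss_within / obs$df_residual,
    pseudo_F = obs$F, r2 = obs$r2, p = p,
    n_permutations_used = n_used, exhaustive = use_exact && sp$exhaustive
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA\n")
  cat(sprintf("          Df  Mean Sum Sq.      F       R2        p\n"))
  cat(sprintf("effect    %2d  %12.5f  %7.4f  %7.5f  %g%s\n",
              x$df_effect, x$ms_effect, x$pseudo_F, x$r2, x$p,
              if (x$exhaustive) " (exact)" else ""))
  cat(sprintf("residual  %2d  %12.5f\n", x$df_residual, x$ms_within))
  invisible(x)
}

#' Multivariate dispersion contrast (distance to group centroid)
#'
#' Tests whether groups differ in their spread around their own multivariate
#' centroid - here, whether interindividual variation in community
#' composition differs between regions. Samples are embedded by PCoA with
#' negative-eigenvalue axes treated as imaginary parts, distances to the
#' own-group centroid are computed (squared distances from negative axes are
#' subtracted, floored at zero), and a one-way ANOVA on those distances
#' gives F and p. This is the centroid variant of the standard
#' `betadisper` procedure, which provides the computation.
#'
#' @param d `dist_matrix`.
#' @param groups group labels aligned to `d`'s rows.
#' @return object of class `dispersion_result`: per-sample `distances`,
#'   `group_means`, `F`, `df1`, `df2`, `p`.
#' @export
dispersion_test <- function(d, groups) {
  m <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) stopf("`groups` misaligned with `d`")
  sizes <- table(groups)
  if (length(sizes) < 2L) stopf("need at least two groups")
  if (any(sizes < 2L))
    stopf("group(s) with a single sample: %s",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  bd <- vegan::betadisper(stats::as.dist(m), factor(groups), type = "centroid")
  an <- stats::anova(bd)
  structure(list(
    distances = stats::setNames(as.numeric(bd$distances), rownames(m)),
    group_means = tapply(as.numeric(bd$distances), groups, mean),
    F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
    ms_effect = an$`Mean Sq`[1], ms_within = an$`Mean Sq`[2],
    p = an$`Pr(>F)`[1]
  ), class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Multivariate dispersion (distance to centroid)\n")
  print(round(x$group_means, 5))
  cat(sprintf("F = %.5f on %d and %d df, p = %.5g\n", x$F, x$df1, x$df2, x$p))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation between the strictly-lower-triangle entries, with a
#' permutation p-value obtained by jointly permuting the rows and columns of
#' the second matrix. One-sided (positive association), the usual
#' convention.
#'
#' @param d1,d2 `dist_matrix` objects over the same samples in the same
#'   order.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return object of class `mantel_result`: `r`, `p`, `n_permutations_used`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999L, seed = 1L) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!identical(dim(m1), dim(m2))) stopf("matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stopf("matrices cover different samples or orderings")
  n_perm <- check_scalar_int(n_perm, "n_perm")
  lt <- lower.tri(m1)
  r_obs <- stats::cor(m1[lt], m2[lt])
  n <- nrow(m1)
  rs <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ix <- sample.int(n)
    stats::cor(m1[lt], m2[ix, ix][lt])
  }, 0))
  p <- (1 + sum(rs >= r_obs - 1e-12)) / (1 + n_perm)
  structure(list(r = r_obs, p = p, n_permutations_used = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.5f, p = %.5g (%d permutations)\n",
              x$r, x$p, x$n_permutations_used))
  invisible(x)
}

#' Write a composition/dispersion report for one metric (two-block TSV)
#' @param perm a `permanova_result`.
#' @param disp a `dispersion_result`.
#' @param metric metric name recorded in the table.
#' @param path output TSV.
#' @export
write_community_test_table <- function(perm, disp, metric, path) {
  df <- data.frame(
    metric = metric,
    block = c("composition", "composition", "dispersion"),
    term = c("region", "residual", "region"),
    df = c(perm$df_effect, perm$df_residual, disp$df1),
    mean_sq = c(perm$ms_effect, perm$ms_within, disp$ms_effect),
    F = c(perm$pseudo_F, NA, disp$F),
    R2 = c(perm$r2, NA, NA),
    p = c(perm$p, NA, disp$p)
  )
  write_tsv(df, path)
}
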