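#' Box-Cox power transform chosen by profile likelihood
#'
#' `boxcox_transform()` applies `(y^lambda - 1) / lambda` (natural log at
#' `lambda = 0`), a monotone increasing transform for any lambda.
#' `boxcox_fit()` picks the lambda in `[-2, 2]` maximising the Gaussian
#' profile log-likelihood
#' `-n/2 log(sigma_hat^2(lambda)) + (lambda - 1) sum(log y)`.
#'
#' @param y positive values (after any `shift`).
#' @param lambda power parameter.
#' @param shift constant added to `y` before transforming (counts containing
#'   zeros need `shift = 1`).
#' @return `boxcox_transform()`: transformed vector. `boxcox_fit()`: list of
#'   class `boxcox_fit` with `lambda`, `shift`, `logLik`.
#' @examples
#' boxcox_transform(exp(1), 0)  # 1
#' boxcox_fit(rlnorm(200))$lambda # near 0
#' @export
boxcox_transform <- function(y, lambda) {
  if (any(y <= 0)) stopf("Box-Cox requires positive values")
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @param interval search interval for lambda.
#' @export
boxcox_fit <- function(y, shift = 0, interval = c(-2, 2)) {
  y <- y + shift
  if (any(!is.finite(y)) || any(y <= 0))
    stopf("non-positive values after shift; increase `shift`")
  n <- length(y)
  if (stats::sd(y) < 1e-12) # degenerate: any lambda fits a constant
    return(structure(list(lambda = 1, shift = shift, logLik = Inf),
                     class = "boxcox_fit"))
  sly <- sum(log(y))
  prof <- function(lambda) {
    z <- boxcox_transform(y, lambda)
    s2 <- stats::var(z) * (n - 1) / n
    if (!is.finite(s2) || s2 <= 0) return(-sqrt(.Machine$double.xmax))
    -n / 2 * log(s2) + (lambda - 1) * sly
  }
  opt <- stats::optimize(prof, interval = interval, maximum = TRUE,
                         tol = 1e-6)
  structure(list(lambda = opt$maximum, shift = shift,
                 logLik = opt$objective),
            class = "boxcox_fit")
}

#' Permutation test for a region effect on one OTU's counts
#'
#' The test statistic is the deviance change when the region effect is
#' dropped from a random-intercept linear mixed model fitted by maximum
#' likelihood to Box-Cox-transformed counts, with Box-Cox-transformed
#' per-sample totals as an offset (coefficient fixed at 1): the offset
#' encodes the assumption that an OTU's reads scale with sequencing depth.
#' The null distribution is built by jointly permuting the per-sample
#' (count, total) pairs across samples - preserving the count-depth
#' coupling while breaking any association with region - and refitting both
#' nested models per permutation. Because a joint permutation of the pairs
#' permutes the offset-adjusted response, and the transform parameters
#' depend only on the permutation-invariant marginal distributions, lambda
#' is estimated once from the observed data.
#'
#' `p = (1 + #(ddev_null >= ddev_obs)) / (1 + n_perm)`.
#'
#' @param otu_counts integer counts for one OTU across samples.
#' @param totals per-sample total read counts.
#' @param region,individual design labels aligned to samples.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param shift added to `otu_counts` before the transform (default 1;
#'   totals are positive and get no shift).
#' @param lambda_response,lambda_offset optionally fix the transform
#'   parameters instead of profiling them.
#' @return list: `dev_change`, `p`, `coef_region` (full-model region
#'   contrast, positive = higher in the second factor level, i.e. oral),
#'   `lambda_response`, `lambda_offset`.
#' @export
otu_permutation_pvalue <- function(otu_counts, totals, region, individual,
                                   n_perm = 10000L, seed = 1L, shift = 1,
                                   lambda_response = NULL,
                                   lambda_offset = NULL) {
  n_perm <- check_scalar_int(n_perm, "n_perm")
  n <- length(otu_counts)
  stopifnot(length(totals) == n, length(region) == n, length(individual) == n)
  if (is.null(lambda_response))
    lambda_response <- boxcox_fit(otu_counts, shift = shift)$lambda
  if (is.null(lambda_offset))
    lambda_offset <- boxcox_fit(totals)$lambda
  yb <- boxcox_transform(otu_counts + shift, lambda_response)
  ob <- boxcox_transform(totals, lambda_offset)
  z <- yb - ob
  rf <- factor(region)
  if (nlevels(rf) != 2L) stopf("`region` must have exactly two levels")
  if (stats::sd(z) < 1e-12) {
    warnf("constant response after transform; returning dev_change = 0")
    return(list(dev_change = 0, p = 1, coef_region = 0,
                lambda_response = lambda_response,
                lambda_offset = lambda_offset))
  }
  g <- as.integer(factor(individual)) - 1L
  x <- as.integer(rf) - 1L
  perms <- with_seed(seed, {
    cbind(seq_len(n), replicate(n_perm, sample.int(n)))
  })
  dd <- .lmm_perm_devchange(z, perms, x, g, max(g) + 1L)
  dev_obs <- dd[1]
  p <- (1 + sum(dd[-1] >= dev_obs - 1e-12)) / (1 + n_perm)
  full <- lme_fit_ml(z, region = rf, individual = individual)
  list(dev_change = dev_obs, p = p,
       coef_region = unname(full$coefficients[2]),
       lambda_response = lambda_response, lambda_offset = lambda_offset)
}

#' Storey q-values
#'
#' Estimates the null fraction `pi0` from the p-value distribution on the
#' lambda grid 0.05..0.95 (`pi0(l) = mean(p > l) / (1 - l)`), smoothed with
#' a cubic smoothing spline (df = 3) and evaluated at the largest lambda,
#' clamped to (0, 1]. Then
#' `q_i = pi0 * min over (p_j >= p_i) of (m * p_j / rank_j)`, which
#' preserves the ordering of the p-values and reduces to Benjamini-Hochberg
#' adjusted p-values when `pi0 = 1`.
#'
#' @param p p-values in (0, 1].
#' @param pi0 optionally force the null-fraction estimate.
#' @param lambdas grid for pi0 estimation.
#' @return numeric q-values with attribute `pi0`.
#' @export
storey_qvalue <- function(p, pi0 = NULL, lambdas = seq(0.05, 0.95, by = 0.05)) {
  if (length(p) == 0L) stopf("empty p-value vector")
  if (anyNA(p) || any(p <= 0 | p > 1)) stopf("p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambdas, function(l) mean(p > l) / (1 - l), 0)
    pi0 <- tryCatch({
      sp <- stats::smooth.spline(lambdas, pi0_l, df = 3)
      stats::predict(sp, x = max(lambdas))$y
    }, error = function(e) max(pi0_l))
    if (!is.finite(pi0) || pi0 <= 0) pi0 <- max(pi0_l)
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  o <- order(p)
  ranks <- seq_len(m)
  q_sorted <- pi0 * m * p[o] / ranks
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Differential-abundance scan across all OTUs
#'
#' Runs [otu_permutation_pvalue()] per OTU (the table should already be
#' prevalence-filtered, e.g. to OTUs detected in at least five samples),
#' computes Storey q-values across the scanned set, and flags an OTU as
#' significant when both its permutation p-value and its q-value fall below
#' `alpha`. The direction flag records which region the OTU is
#' overrepresented in, from the sign of the fitted region contrast.
#'
#' @param table a prevalence-filtered [count_table()].
#' @param meta sample metadata.
#' @param n_perm permutations per OTU (the reference analysis used 10,000).
#' @param seed master seed; each OTU uses a deterministic sub-seed.
#' @param totals per-sample totals for the depth offset; defaults to the row
#'   sums of `table`. Pass the totals of the unfiltered table when the scan
#'   runs on a filtered subset.
#' @param shift passed to [otu_permutation_pvalue()].
#' @param alpha significance threshold applied to both p and q.
#' @return data frame of class `diff_abundance`: `otu_id`, `dev_change`,
#'   `p`, `q`, `direction` (`"+oral"`/`"+faecal"`), `significant`; attribute
#'   `pi0`.
#' @export
diff_abundance_scan <- function(table, meta, n_perm = 10000L, seed = 1L,
                                totals = NULL, shift = 1, alpha = 0.05) {
  m <- as_count_matrix(table)
  meta <- align_meta(sample_metadata(meta), rownames(m))
  if (is.null(totals)) totals <- rowSums(m)
  if (length(totals) != nrow(m)) stopf("`totals` misaligned with samples")
  lambda_offset <- boxcox_fit(totals)$lambda
  res <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    res[[j]] <- tryCatch(
      otu_permutation_pvalue(m[, j], totals, meta$region, meta$individual_id,
                             n_perm = n_perm,
                             seed = otu_seed(seed, colnames(m)[j]),
                             shift = shift, lambda_offset = lambda_offset),
      error = function(e) {
        message(sprintf("OTU %s skipped: %s", colnames(m)[j],
                        conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(res, is.null, TRUE)
  dev <- vapply(res[ok], `[[`, 0, "dev_change")
  pv <- vapply(res[ok], `[[`, 0, "p")
  coefr <- vapply(res[ok], `[[`, 0, "coef_region")
  q <- storey_qvalue(pv)
  out <- data.frame(
    otu_id = colnames(m)[ok],
    dev_change = dev,
    p = pv,
    q = as.numeric(q),
    direction = ifelse(coefr >= 0, "+oral", "+faecal"),
    significant = pv < alpha & as.numeric(q) < alpha,
    stringsAsFactors = FALSE
  )
  attr(out, "pi0") <- attr(q, "pi0")
  attr(out, "n_failed") <- sum(!ok)
  class(out) <- c("diff_abundance", class(out))
  out
}

#' @export
print.diff_abundance <- function(x, ...) {
  cat(sprintf(
    "Differential-abundance scan: %d OTUs, %d significant (pi0 = %.3f)\n",
    nrow(x), sum(x$significant), attr(x, "pi0")))
  sig <- x[x$significant, c("otu_id", "dev_change", "p", "q", "direction")]
  if (nrow(sig)) print(utils::head(sig[order(sig$p), ], 20), digits = 4)
  invisible(x)
}

#' Heatmap-support data for significant OTUs
#'
#' Log10-scaled abundances (`log10(count + 1)`) of the significant OTUs,
#' with rows ordered by the phylogeny's leaf order, plus the pruned subtree,
#' ready for heatmap rendering.
#'
#' @param scan a [diff_abundance_scan()] result.
#' @param table the count table the scan was run on.
#' @param tree rooted `phylo` over (at least) the scanned OTUs.
#' @return list: `log10_abundance` (OTUs x samples, phylogeny order),
#'   `subtree`, `direction` (named by OTU).
#' @export
heatmap_support <- function(scan, table, tree) {
  m <- as_count_matrix(table)
  sig <- scan$otu_id[scan$significant]
  if (!length(sig)) stopf("no significant OTUs to display")
  missing <- setdiff(sig, tree$tip.label)
  if (length(missing))
    stopf("significant OTU(s) absent from the tree: %s",
          paste(missing, collapse = ", "))
  sub <- ape::keep.tip(tree, sig)
  ord <- sub$tip.label
  mat <- t(log10(m[, ord, drop = FALSE] + 1))
  list(log10_abundance = mat, subtree = sub,
       direction = stats::setNames(scan$direction[match(ord, scan$otu_id)],
                                   ord))
}

#' Write differential-abundance outputs
#' @param scan a `diff_abundance` table.
#' @param tax optional taxonomy to append a lineage string.
#' @param path output TSV path.
#' @export
write_diff_abundance <- function(scan, path, tax = NULL) {
  df <- as.data.frame(scan)
  if (!is.null(tax)) {
    tax <- taxonomy_table(tax)
    ix <- match(df$otu_id, tax$otu_id)
    df$taxonomy <- apply(tax[ix, c("kingdom", "phylum", "class", "order",
                                   "family", "genus")], 1L,
                         paste, collapse = ";")
  }
  write_tsv(df, path)
}
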