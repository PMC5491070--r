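#' Alpha diversity indices
#'
#' `observed_richness()` counts OTUs with a positive count; `shannon()` is
#' the Shannon entropy of the read proportions (natural log by default, i.e.
#' nats); `chao1()` estimates total richness from singleton and doubleton
#' counts. Chao1 uses the bias-corrected form
#' \deqn{S_{chao1} = S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))}
#' which is defined even without doubletons; the classic
#' \eqn{S_{obs} + F_1^2/(2 F_2)} form is available with
#' `bias_corrected = FALSE`.
#'
#' @param counts non-negative abundance vector for one sample.
#' @return a single number.
#' @examples
#' x <- c(5, 3, 2, 1, 1, 0)
#' observed_richness(x)
#' shannon(x)
#' chao1(x)
#' @export
observed_richness <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) stopf("counts must be non-negative")
  sum(counts > 0)
}

#' @rdname observed_richness
#' @param base logarithm base; default `exp(1)` (nats).
#' @export
shannon <- function(counts, base = exp(1)) {
  if (anyNA(counts) || any(counts < 0)) stopf("counts must be non-negative")
  if (sum(counts) == 0) stopf("all-zero abundance vector")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' @rdname observed_richness
#' @param bias_corrected use the bias-corrected estimator (default) rather
#'   than the classic `F1^2 / (2 F2)` form.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (anyNA(counts) || any(counts < 0)) stopf("counts must be non-negative")
  if (sum(counts) == 0) stopf("all-zero abundance vector")
  if (any(abs(counts - round(counts)) > 1e-8))
    warnf("chao1 expects integer counts; results may be meaningless")
  s <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) s + f1 * (f1 - 1) / (2 * (f2 + 1))
  else if (f2 > 0) s + f1^2 / (2 * f2)
  else s + f1 * (f1 - 1) / 2 # classic form falls back to bias-corrected at F2=0
}

#' Per-sample alpha diversity table
#'
#' @param table a [count_table()], normally rarefied first.
#' @return data frame: sample_id, observed, shannon (nats), chao1.
#' @export
alpha_diversity <- function(table) {
  m <- as_count_matrix(table)
  data.frame(
    sample_id = rownames(m),
    observed = apply(m, 1L, observed_richness),
    shannon = apply(m, 1L, shannon),
    chao1 = apply(m, 1L, chao1),
    row.names = NULL
  )
}

#' Mixed-model contrast of alpha diversity between GIT regions
#'
#' Fits `diversity ~ region` with a random intercept per individual by
#' maximum likelihood and compares it against the intercept-only model with
#' a likelihood-ratio test on one degree of freedom. Samples from the same
#' bird are not independent (eight individuals contribute both an oral and a
#' faecal sample in the motivating design); the random intercept absorbs
#' that dependence. Group means +/- SE (sd/sqrt(n), descriptive) are
#' reported per region.
#'
#' @param alpha output of [alpha_diversity()].
#' @param meta sample metadata.
#' @param metric one of `"observed"`, `"shannon"`, `"chao1"`.
#' @return object of class `lrt_result`: chi2, df, p, group summary.
#' @export
alpha_region_contrast <- function(alpha, meta,
                                  metric = c("observed", "shannon", "chao1")) {
  metric <- match.arg(metric)
  meta <- align_meta(sample_metadata(meta), alpha$sample_id)
  y <- alpha[[metric]]
  if (min(table(meta$region)) < 2L) stopf("need >= 2 samples per region")
  full <- lme_fit_ml(y, region = meta$region, individual = meta$individual_id)
  null <- lme_fit_ml(y, region = NULL, individual = meta$individual_id)
  chi2 <- max(0, null$deviance - full$deviance)
  grp <- split(y, meta$region)
  summ <- data.frame(
    region = names(grp),
    n = lengths(grp),
    mean = vapply(grp, mean, 0),
    se = vapply(grp, function(v) stats::sd(v) / sqrt(length(v)), 0),
    row.names = NULL
  )
  structure(list(metric = metric, chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
                 groups = summ, full = full, null = null),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Likelihood-ratio contrast (%s): chi2 = %.5f, df = %d, p = %.5g\n",
              x$metric, x$chi2, x$df, x$p))
  print(x$groups, digits = 5)
  invisible(x)
}

#' ANOVA of alpha diversity on a host covariate, within one region
#'
#' Runs per region, as is standard when the grouping factor of interest
#' (region) would otherwise confound the covariate: a one-way ANOVA for
#' `sex`, a single-slope regression for the scaled body mass index (`smi`,
#' see [add_body_condition()]).
#'
#' @param alpha output of [alpha_diversity()].
#' @param meta sample metadata; must contain the covariate (and `smi` must
#'   have been added for `covariate = "smi"`).
#' @param covariate `"sex"` or `"smi"`.
#' @param metric diversity metric column.
#' @param region which region's samples to use.
#' @return data frame with F, df1, df2, p.
#' @export
alpha_covariate_anova <- function(alpha, meta, covariate = c("sex", "smi"),
                                  metric = c("observed", "shannon", "chao1"),
                                  region = c("oral", "faecal")) {
  covariate <- match.arg(covariate)
  metric <- match.arg(metric)
  region <- match.arg(region)
  meta <- align_meta(sample_metadata(meta), alpha$sample_id)
  keep <- meta$region == region & !is.na(meta[[covariate]])
  y <- alpha[[metric]][keep]
  x <- meta[[covariate]][keep]
  if (covariate == "sex") {
    ok <- x != "unknown"
    x <- x[ok]
    y <- y[ok]
    if (length(unique(x)) < 2L) stopf("only one sex present in %s samples", region)
    fit <- stats::lm(y ~ factor(x))
  } else {
    if (!is.numeric(x)) stopf("`smi` must be numeric; run add_body_condition()")
    fit <- stats::lm(y ~ x)
  }
  an <- stats::anova(fit)
  data.frame(metric = metric, covariate = covariate, region = region,
             F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[nrow(an)],
             p = an$`Pr(>F)`[1], row.names = NULL)
}

#' Write a diversity-contrast table (metric, means +/- SE per region, chi2, p)
#' @param contrasts list of `lrt_result` objects.
#' @param path output TSV path.
#' @export
write_alpha_contrast_table <- function(contrasts, path) {
  rows <- lapply(contrasts, function(ct) {
    g <- ct$groups
    o <- g[g$region == "oral", ]; f <- g[g$region == "faecal", ]
    data.frame(metric = ct$metric,
               oral_mean = o$mean, oral_se = o$se,
               faecal_mean = f$mean, faecal_se = f$se,
               chi2 = ct$chi2, p = ct$p)
  })
  write_tsv(do.call(rbind, rows), path)
}
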