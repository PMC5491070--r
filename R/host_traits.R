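#' Standardized major axis slope of log mass on log length
#'
#' The SMA slope is the OLS slope divided by the absolute Pearson
#' correlation, equivalently `sign(r) * sd(log_mass) / sd(log_length)`.
#'
#' @param log_mass,log_length natural-log body mass and structural length.
#' @return the SMA slope.
#' @export
sma_slope <- function(log_mass, log_length) {
  if (length(log_mass) != length(log_length)) stopf("length mismatch")
  if (length(log_mass) < 3L) stopf("need at least 3 observations")
  if (stats::sd(log_mass) == 0 || stats::sd(log_length) == 0)
    stopf("zero variance in mass or length")
  r <- stats::cor(log_mass, log_length)
  if (r == 0) stopf("zero correlation: SMA slope undefined")
  b_ols <- stats::cov(log_mass, log_length) / stats::var(log_length)
  b_ols / abs(r)
}

#' Scaled body mass index
#'
#' Body condition standardised to a common structural size:
#' `SMI = mass * (L0 / length)^b`, with `b` the SMA slope of log mass on log
#' length and `L0` a reference length (conventionally the sample mean).
#' Individuals at the reference length keep their observed mass.
#'
#' @param mass body mass (g).
#' @param length structural length (mm), e.g. tarsus.
#' @param L0 reference length (mm).
#' @param b SMA scaling exponent.
#' @return SMI in grams.
#' @examples
#' scaled_mass_index(18, 20, 19.5, 2) # 17.11125
#' @export
scaled_mass_index <- function(mass, length, L0, b) {
  if (any(c(mass, length, L0) <= 0, na.rm = TRUE))
    stopf("mass, length and L0 must be positive")
  mass * (L0 / length)^b
}

#' Append the scaled body mass index to sample metadata
#'
#' Fits the SMA slope on the samples with both mass and tarsus present
#' (natural-log scale) and adds an `smi` column. `L0` defaults to the mean
#' tarsus of those samples.
#'
#' @param meta sample metadata with `body_mass` and `tarsus`.
#' @param L0 reference tarsus length; default the sample mean.
#' @return metadata with an `smi` column (NA where inputs are missing);
#'   attributes `sma_b` and `L0` record the fit.
#' @export
add_body_condition <- function(meta, L0 = NULL) {
  meta <- sample_metadata(meta)
  if (!all(c("body_mass", "tarsus") %in% names(meta)))
    stopf("metadata needs `body_mass` and `tarsus` columns")
  ok <- !is.na(meta$body_mass) & !is.na(meta$tarsus)
  if (sum(ok) < 3L) stopf("need at least 3 samples with mass and tarsus")
  b <- sma_slope(log(meta$body_mass[ok]), log(meta$tarsus[ok]))
  if (is.null(L0)) L0 <- mean(meta$tarsus[ok])
  meta$smi <- NA_real_
  meta$smi[ok] <- scaled_mass_index(meta$body_mass[ok], meta$tarsus[ok], L0, b)
  attr(meta, "sma_b") <- b
  attr(meta, "L0") <- L0
  meta
}
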