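#' Assemble test-retest records
#'
#' @param subject_id Subject identifiers.
#' @param value_visit1,value_visit2 Paired biomarker values (test and
#'   retest).
#' @param group Optional group labels.
#' @return Data frame of class `"test_retest"`; subjects with a missing
#'   visit are kept but flagged and excluded (with a warning) by downstream
#'   estimators.
#' @export
test_retest_records <- function(subject_id, value_visit1, value_visit2,
                                group = NULL) {
  d <- data.frame(subject_id = as.character(subject_id),
                  value_visit1 = value_visit1,
                  value_visit2 = value_visit2,
                  stringsAsFactors = FALSE)
  if (!is.null(group)) d$group <- as.character(group)
  class(d) <- c("test_retest", "data.frame")
  d
}

complete_records <- function(records) {
  ok <- is.finite(records$value_visit1) & is.finite(records$value_visit2)
  if (any(!ok))
    warning(sum(!ok), " subject(s) with a missing visit excluded from the ",
            "test-retest analysis")
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) < 3L)
    stop("fewer than 3 subjects with both visits")
  rec
}

#' One-way random-effects variance components from test-retest data
#'
#' Decomposes paired test-retest measurements into between-subject and
#' within-subject variance via the one-way random-effects ANOVA with two
#' replicates per subject: \eqn{\sigma_w^2 = MS_{within}} and
#' \eqn{\sigma_b^2 = \max(0, (MS_{between} - MS_{within})/2)}. A negative
#' between-subject component is truncated at zero.
#'
#' @param records A [test_retest_records()] data frame (>= 3 complete
#'   subjects).
#' @return Named list with `sigma_b2`, `sigma_w2`, `ms_between`,
#'   `ms_within`, `n_subjects`.
#' @export
variance_components_oneway <- function(records) {
  rec <- complete_records(records)
  long <- data.frame(
    subject = factor(rep(rec$subject_id, 2L)),
    value = c(rec$value_visit1, rec$value_visit2))
  ms <- summary(stats::aov(value ~ subject, data = long))[[1]][["Mean Sq"]]
  ms_between <- ms[1]; ms_within <- ms[2]
  list(sigma_b2 = max(0, (ms_between - ms_within) / 2),
       sigma_w2 = ms_within,
       ms_between = ms_between, ms_within = ms_within,
       n_subjects = nrow(rec))
}

#' Intraclass correlation coefficient from variance components
#'
#' One-way random-effects ICC,
#' \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)}.
#'
#' @param sigma_b2 Between-subject variance (>= 0).
#' @param sigma_w2 Within-subject variance (>= 0).
#' @return The ICC in \[0, 1\].
#' @examples
#' icc_from_components(2.1e-4, 2.4e-5)  # 0.90 at 2 dp
#' @export
icc_from_components <- function(sigma_b2, sigma_w2) {
  if (sigma_b2 < 0 || sigma_w2 < 0) stop("variances must be >= 0")
  if (sigma_b2 + sigma_w2 == 0)
    stop("ICC undefined: both variance components are zero")
  sigma_b2 / (sigma_b2 + sigma_w2)
}

#' ICC with its F-pivot confidence interval
#'
#' One-way random-effects ICC from test-retest records, with the confidence
#' interval obtained from the ANOVA F statistic
#' (\eqn{F = MS_{between}/MS_{within}}, df \eqn{n-1} and \eqn{n(k-1)},
#' \eqn{k = 2} replicates); the lower bound is truncated at 0.
#'
#' @param records A [test_retest_records()] data frame.
#' @param conf_level Confidence level (default 0.95).
#' @return Named list `icc`, `lower`, `upper`, plus the variance components.
#' @export
icc_oneway <- function(records, conf_level = 0.95) {
  vc <- variance_components_oneway(records)
  n <- vc$n_subjects; k <- 2
  fobs <- vc$ms_between / vc$ms_within
  a <- (1 - conf_level) / 2
  fl <- fobs / stats::qf(1 - a, n - 1, n * (k - 1))
  fu <- fobs * stats::qf(1 - a, n * (k - 1), n - 1)
  c(list(icc = icc_from_components(vc$sigma_b2, vc$sigma_w2),
         lower = max(0, (fl - 1) / (fl + k - 1)),
         upper = min(1, (fu - 1) / (fu + k - 1))),
    vc)
}

#' Within-subject standard deviation
#'
#' \eqn{\sqrt{\sigma_w^2}} from the one-way decomposition; reported in the
#' biomarker's units.
#'
#' @inheritParams variance_components_oneway
#' @return wSD.
#' @export
within_subject_sd <- function(records) {
  sqrt(variance_components_oneway(records)$sigma_w2)
}

#' Within-subject coefficient of variation (RMS method)
#'
#' \eqn{100 \sqrt{\mathrm{mean}_i\left[(d_i^2/2)/m_i^2\right]}} where
#' \eqn{d_i} is the visit difference and \eqn{m_i} the subject mean — the
#' root-mean-square pairwise CV appropriate to a two-replicate design.
#'
#' @inheritParams variance_components_oneway
#' @return wCV in percent.
#' @export
within_subject_cv <- function(records) {
  rec <- complete_records(records)
  m <- (rec$value_visit1 + rec$value_visit2) / 2
  if (any(m <= 0)) stop("within-subject CV requires positive subject means")
  d <- rec$value_visit2 - rec$value_visit1
  100 * sqrt(mean((d^2 / 2) / m^2))
}

#' Choose the variability scale: absolute or relative
#'
#' Tests whether within-subject variability grows with the biomarker's
#' magnitude using Kendall's tau between subject means and absolute visit
#' differences. Significant correlation (two-sided p < `alpha`) selects the
#' relative scale (wCV/percent SDD); otherwise the absolute scale (wSD and
#' absolute SDD) is used.
#'
#' @inheritParams variance_components_oneway
#' @param alpha Two-sided significance level (default 0.05).
#' @return `"relative"` or `"absolute"`, with attributes `tau` and
#'   `p_value`.
#' @export
select_variability_scale <- function(records, alpha = 0.05) {
  rec <- complete_records(records)
  if (nrow(rec) < 5L) stop("at least 5 complete subjects required")
  m <- (rec$value_visit1 + rec$value_visit2) / 2
  ad <- abs(rec$value_visit2 - rec$value_visit1)
  if (stats::sd(ad) == 0 || stats::sd(m) == 0) {
    out <- "absolute"
    attr(out, "tau") <- 0; attr(out, "p_value") <- 1
    return(out)
  }
  kt <- suppressWarnings(stats::cor.test(m, ad, method = "kendall"))
  sig <- is.finite(kt$p.value) && kt$p.value < alpha
  out <- if (sig) "relative" else "absolute"
  attr(out, "tau") <- unname(kt$estimate)
  attr(out, "p_value") <- kt$p.value
  out
}

#' Smallest detectable difference (repeatability coefficient)
#'
#' \eqn{\sqrt{2} \times 1.96 \approx 2.77} times the within-subject standard
#' deviation (absolute scale) or within-subject coefficient of variation
#' (relative scale): the smallest change interpretable as genuine with 95%
#' confidence under identical measurement conditions.
#'
#' @param wsd_or_wcv wSD (biomarker units) or wCV (percent), >= 0.
#' @param scale `"absolute"` or `"relative"` (annotates the result's units;
#'   the multiplier is identical).
#' @return SDD in the units of the input.
#' @export
smallest_detectable_difference <- function(wsd_or_wcv,
                                           scale = c("absolute", "relative")) {
  scale <- match.arg(scale)
  if (wsd_or_wcv < 0) stop("input must be >= 0")
  sdd <- sqrt(2) * 1.96 * wsd_or_wcv
  attr(sdd, "scale") <- scale
  sdd
}

#' Root-mean-square coefficient of variation
#'
#' Reproducibility across repeated analyses:
#' \eqn{100\sqrt{\mathrm{mean}_i\, cv_i^2}} with \eqn{cv_i} the SD/mean of
#' each measurement pair.
#'
#' @param x,y Paired repeated measurements (e.g. two observers), equal
#'   length >= 1.
#' @return RMSCV in percent.
#' @export
rmscv <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L)
    stop("need >= 1 measurement pair of equal length")
  m <- (x + y) / 2
  if (any(m <= 0)) stop("RMSCV requires positive pair means")
  s <- apply(cbind(x, y), 1L, stats::sd)
  100 * sqrt(mean((s / m)^2))
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{CCC = \frac{2\,\mathrm{cov}(x,y)}
#'   {\mathrm{var}(x) + \mathrm{var}(y) + (\bar{x} - \bar{y})^2}}
#' using population (divide-by-n) moments. Penalises location and scale
#' shifts that Pearson correlation ignores.
#'
#' @param x,y Numeric series of equal length >= 3.
#' @return CCC in \[-1, 1\].
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length series of >= 3 values")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  den <- sx2 + sy2 + (mx - my)^2
  if (den == 0) stop("CCC undefined: zero total variance")
  2 * sxy / den
}

#' Standardised mean difference between two groups
#'
#' Cohen's d: the difference in group means divided by the pooled standard
#' deviation (with \eqn{n-1} weighting).
#'
#' @param group_oa,group_hv Numeric vectors of per-subject biomarker values
#'   (each of length >= 2).
#' @return A list of class `"group_comparison"`: `mean_oa`, `mean_hv`,
#'   `pooled_sd`, `smd`, `n_oa`, `n_hv`.
#' @export
standardized_mean_difference <- function(group_oa, group_hv) {
  n1 <- length(group_oa); n2 <- length(group_hv)
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 values")
  s1 <- stats::var(group_oa); s2 <- stats::var(group_hv)
  pooled <- sqrt(((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2))
  if (pooled == 0) stop("pooled standard deviation is zero")
  structure(list(mean_oa = mean(group_oa), mean_hv = mean(group_hv),
                 pooled_sd = pooled,
                 smd = (mean(group_oa) - mean(group_hv)) / pooled,
                 n_oa = n1, n_hv = n2),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: mean OA %.4g (n=%d), mean HV %.4g (n=%d)\n",
              x$mean_oa, x$n_oa, x$mean_hv, x$n_hv))
  cat(sprintf("  pooled SD %.4g, SMD %.3f\n", x$pooled_sd, x$smd))
  invisible(x)
}

#' Count subjects whose change exceeds the smallest detectable difference
#'
#' Strict exceedance count of |change| > SDD. On the relative scale, changes
#' are expressed as a percentage of each subject's baseline before
#' comparison with the percent SDD.
#'
#' @param changes Per-subject changes (biomarker units).
#' @param sdd The SDD (absolute units, or percent for
#'   `scale = "relative"`), >= 0.
#' @param scale `"absolute"` or `"relative"`.
#' @param baseline Per-subject baselines (required for the relative scale).
#' @return Integer count.
#' @export
responsiveness_count <- function(changes, sdd,
                                 scale = c("absolute", "relative"),
                                 baseline = NULL) {
  scale <- match.arg(scale)
  if (sdd < 0) stop("`sdd` must be >= 0")
  delta <- if (scale == "relative") {
    if (is.null(baseline)) stop("`baseline` required for the relative scale")
    100 * changes / baseline
  } else changes
  sum(abs(delta) > sdd)
}

#' Full repeatability summary for one biomarker
#'
#' Runs the complete test-retest analysis: variance components, ICC with its
#' confidence interval, scale selection, wSD or wCV per the selected scale,
#' and the SDD — the per-biomarker repeatability panel.
#'
#' @inheritParams variance_components_oneway
#' @param oa_mean Optional OA group mean, used to express the SDD as a
#'   percentage of it.
#' @param scale Force `"absolute"` or `"relative"`, or `"auto"` (default) to
#'   select by the magnitude-variability correlation test.
#' @return A list of class `"repeatability_metrics"`.
#' @export
repeatability_metrics <- function(records, oa_mean = NULL, scale = "auto") {
  ic <- icc_oneway(records)
  sel <- if (identical(scale, "auto")) select_variability_scale(records)
         else match.arg(scale, c("absolute", "relative"))
  wval <- if (sel == "absolute") within_subject_sd(records)
          else within_subject_cv(records)
  sdd <- smallest_detectable_difference(wval, sel)
  sdd_pct <- if (!is.null(oa_mean) && sel == "absolute" && oa_mean > 0)
    100 * as.numeric(sdd) / oa_mean else NA_real_
  structure(list(sigma_b2 = ic$sigma_b2, sigma_w2 = ic$sigma_w2,
                 icc = ic$icc, icc_lower = ic$lower, icc_upper = ic$upper,
                 scale = as.character(sel),
                 wsd_or_wcv = wval, sdd = as.numeric(sdd),
                 oa_mean = if (is.null(oa_mean)) NA_real_ else oa_mean,
                 sdd_pct_of_mean = sdd_pct,
                 n_subjects = ic$n_subjects),
            class = "repeatability_metrics")
}

#' @export
print.repeatability_metrics <- function(x, ...) {
  cat("Test-retest repeatability (", x$n_subjects, " subjects, ",
      x$scale, " scale)\n", sep = "")
  cat(sprintf("  sigma_b2 %.3g  sigma_w2 %.3g  ICC %.2f (%.2f, %.2f)\n",
              x$sigma_b2, x$sigma_w2, x$icc, x$icc_lower, x$icc_upper))
  unit <- if (x$scale == "relative") "%" else ""
  cat(sprintf("  %s %.3g%s  SDD %.3g%s",
              if (x$scale == "relative") "wCV" else "wSD",
              x$wsd_or_wcv, unit, x$sdd, unit))
  if (is.finite(x$sdd_pct_of_mean))
    cat(sprintf("  (%.0f%% of OA mean %.3g)", x$sdd_pct_of_mean, x$oa_mean))
  cat("\n")
  invisible(x)
}
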