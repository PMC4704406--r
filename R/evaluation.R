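#' Descriptive statistics for one analyte
#'
#' Mean, SD (n-1 denominator), CV%, min, max, range, median, and the
#' bias-adjusted sample skewness and excess kurtosis (the G1/G2 estimators
#' conventional in clinical statistics software). CV is flagged undefined
#' (NA) when the mean is zero; skewness/kurtosis are undefined for constant
#' vectors.
#'
#' @param values Numeric vector, length >= 3.
#' @return A `descriptive_stats` list.
#' @export
#' @examples
#' descriptive_stats(c(1, 2, 3, 4, 5))
descriptive_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  if (s > 0) {
    z <- (values - m) / s
    g1 <- n / ((n - 1) * (n - 2)) * sum(z^3)
    g2 <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
      3 * (n - 1)^2 / ((n - 2) * (n - 3))
  } else {
    g1 <- NA_real_
    g2 <- NA_real_
  }
  structure(list(n = n, mean = m, sd = s,
                 cv_percent = cv_percent(m, s),
                 min = min(values), max = max(values),
                 range = max(values) - min(values),
                 median = stats::median(values),
                 skewness = g1, kurtosis = g2),
            class = "descriptive_stats")
}

#' @export
print.descriptive_stats <- function(x, ...) {
  cat(sprintf("<descriptive_stats> n=%d mean=%.4g sd=%.4g cv=%.4g%% range=[%.4g, %.4g] median=%.4g SK=%.3g KU=%.3g\n",
              x$n, x$mean, x$sd, x$cv_percent, x$min, x$max, x$median,
              x$skewness, x$kurtosis))
  invisible(x)
}

#' Coefficient of variation in percent
#'
#' @param mean Mean (nonzero for a defined CV).
#' @param sd Nonnegative standard deviation.
#' @return `100 * sd / mean`, or `NA` when the mean is 0 (undefined).
#' @export
#' @examples
#' cv_percent(4.07, 0.20)   # potassium: ~4.9%
cv_percent <- function(mean, sd) {
  if (sd < 0) stop("sd must be nonnegative", call. = FALSE)
  if (mean == 0) return(NA_real_)
  100 * sd / mean
}

#' Decide whether an analyte needs a normalising transform
#'
#' Shapiro-Wilk test of the raw values; under non-normality
#' (p < `alpha`) strictly positive analytes are assigned the natural-log
#' transform, and analytes with nonpositive values fall back to the
#' exponential-family alternative (kept as a named option; plasma analytes
#' are positive in practice, so the log branch is the one exercised).
#'
#' @param values Numeric vector, 3 <= n <= 5000 (Shapiro-Wilk range).
#' @param alpha Significance level (default 0.05).
#' @return A `transform_decision`: `shapiro_p`, `transformed`, `transform`
#'   (`"none"`, `"log"` or `"exponential"`).
#' @export
decide_transform <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 3 || length(values) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  p <- stats::shapiro.test(values)$p.value
  transformed <- p < alpha
  transform <- if (!transformed) "none"
    else if (all(values > 0)) "log" else "exponential"
  structure(list(shapiro_p = p, transformed = transformed,
                 transform = transform, alpha = alpha),
            class = "transform_decision")
}

#' Apply / invert a transform decision
#'
#' @param decision A `transform_decision`.
#' @param values Values to transform (or back-transform).
#' @return Transformed values.
#' @export
apply_transform <- function(decision, values) {
  switch(decision$transform,
         none = values,
         log = log(values),
         exponential = exp(values))
}

#' @rdname apply_transform
#' @export
invert_transform <- function(decision, values) {
  switch(decision$transform,
         none = values,
         log = exp(values),
         exponential = log(values))
}

#' Squared correlation of cross-validated predictions vs measured values
#'
#' The displayed calibration R2 is the squared Pearson correlation of
#' predicted versus measured values (not 1 - PRESS/SStot). Undefined (NA)
#' when either vector has zero variance.
#'
#' @param measured,predicted Equal-length numeric vectors, n >= 3.
#' @return Numeric in `[0, 1]`, or NA when undefined.
#' @export
r_squared <- function(measured, predicted) {
  if (length(measured) != length(predicted)) {
    stop("measured and predicted must have equal length", call. = FALSE)
  }
  if (length(measured) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(measured) == 0 || stats::sd(predicted) == 0) return(NA_real_)
  stats::cor(measured, predicted)^2
}

.stat_field <- function(stats, field) {
  if (inherits(stats, "descriptive_stats") || is.list(stats)) {
    return(stats[[field]])
  }
  as.numeric(stats)
}

#' Range error ratio (RER)
#'
#' Range of the analyte divided by the standard deviation of prediction
#' errors (RMSECV). RER below 3 signals little practical utility, 3-10
#' limited-to-good utility, above 10 high utility.
#'
#' @param stats A `descriptive_stats` object (its `range` is used) or a
#'   plain numeric range.
#' @param rmsecv Positive RMSECV in analyte units.
#' @return RER (dimensionless).
#' @export
#' @examples
#' rer(86.89 - 63.57, 0.7452)   # total protein: ~31.3
rer <- function(stats, rmsecv) {
  if (rmsecv <= 0) stop("rmsecv must be > 0", call. = FALSE)
  .stat_field(stats, "range") / rmsecv
}

#' Ratio of prediction to deviation (RPD)
#'
#' Analyte SD divided by RMSECV. Below 1.5 the calibration is not usable;
#' 1.5-2.0 distinguishes low from high values; 2.0-2.5 allows approximate
#' quantitative prediction; 2.5-3.0 is good; above 3.0 excellent.
#'
#' @param stats A `descriptive_stats` object (its `sd` is used) or a plain
#'   numeric SD.
#' @param rmsecv Positive RMSECV in analyte units.
#' @return RPD (dimensionless).
#' @export
#' @examples
#' rpd(1.59, 0.1156)   # total cholesterol: ~13.8
rpd <- function(stats, rmsecv) {
  if (rmsecv <= 0) stop("rmsecv must be > 0", call. = FALSE)
  .stat_field(stats, "sd") / rmsecv
}

#' Interpretation bands for calibration quality metrics
#'
#' Maps R2, RER and RPD onto their conventional utility classes. Bands are
#' closed on the left and open on the right, except that the top RPD band
#' is "above 3.0" (an RPD of exactly 3.0 is still "good") and the top RER
#' band is "above 10".
#'
#' * R2: `< 0.66` below; `0.66-0.81` approximate; `0.82-0.90` good;
#'   `>= 0.91` excellent.
#' * RER: `< 3` little utility; `3-10` limited-to-good; `> 10` high.
#' * RPD: `< 1.5` not usable; `1.5-2.0` low/high discrimination;
#'   `2.0-2.5` approximate; `2.5-3.0` good; `> 3.0` excellent.
#'
#' @param r2,rer,rpd Numeric metric values (vectors recycle).
#' @return A data.frame with columns `r2_class`, `rer_class`, `rpd_class`
#'   (ordered factors).
#' @export
#' @examples
#' classify_quality(r2 = 0.99, rer = 43.8, rpd = 13.8)
classify_quality <- function(r2 = NA, rer = NA, rpd = NA) {
  r2_lv <- c("below", "approximate", "good", "excellent")
  rer_lv <- c("little", "limited-good", "high")
  rpd_lv <- c("not usable", "low/high discrimination", "approximate",
              "good", "excellent")
  band <- function(x, lv, pick) {
    factor(ifelse(is.na(x), NA_character_, lv[vapply(x, pick, integer(1))]),
           levels = lv, ordered = TRUE)
  }
  r2_class <- band(r2, r2_lv, function(v) {
    if (is.na(v)) return(1L)
    if (v < 0.66) 1L else if (v < 0.82) 2L else if (v < 0.91) 3L else 4L
  })
  rer_class <- band(rer, rer_lv, function(v) {
    if (is.na(v)) return(1L)
    if (v < 3) 1L else if (v <= 10) 2L else 3L
  })
  rpd_class <- band(rpd, rpd_lv, function(v) {
    if (is.na(v)) return(1L)
    if (v < 1.5) 1L else if (v < 2.0) 2L else if (v < 2.5) 3L
    else if (v <= 3.0) 4L else 5L
  })
  data.frame(r2_class = r2_class, rer_class = rer_class,
             rpd_class = rpd_class)
}

#' Duplicate-based repeatability
#'
#' Repeatability standard deviation from paired determinations:
#' `S_r = sqrt(sum(d_i^2) / (2n))` with `d_i` the within-pair difference --
#' the standard estimator when each sample is measured twice under
#' repeatability conditions. The relative form is
#' `RSD_r = 100 * S_r / grand mean`. A naive alternative (mean per-pair SD,
#' `mean(|d|)/sqrt(2)`) is available via `method = "per_pair"`.
#'
#' @param rep1,rep2 Paired prediction vectors (first and second replicate).
#' @param method `"pooled"` (default) or `"per_pair"`.
#' @return A `repeatability_result`: `s_r`, `rsd_r_percent`, `n_pairs`.
#' @export
#' @examples
#' repeatability(c(10), c(12))   # S_r = sqrt(2)
repeatability <- function(rep1, rep2, method = c("pooled", "per_pair")) {
  method <- match.arg(method)
  if (length(rep1) != length(rep2)) {
    stop("replicate vectors must have equal length", call. = FALSE)
  }
  d <- rep1 - rep2
  n <- length(d)
  s_r <- switch(method,
                pooled = sqrt(sum(d^2) / (2 * n)),
                per_pair = mean(abs(d)) / sqrt(2))
  grand <- mean(c(rep1, rep2))
  structure(list(s_r = s_r,
                 rsd_r_percent = if (grand != 0) 100 * s_r / grand
                                 else NA_real_,
                 n_pairs = n, method = method),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("<repeatability> S_r = %.4g, RSD_r = %.4g%% (%d pairs, %s)\n",
              x$s_r, x$rsd_r_percent, x$n_pairs, x$method))
  invisible(x)
}
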