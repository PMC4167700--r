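#' Between-manufacturer comparisons
#'
#' Statistics for comparing automated interval measurements between two
#' device manufacturers: pooled-variance Student t tests per sex, Fisher
#' exact tests on outlier rates, covariate-adjusted (gender, age)
#' multivariable regressions of QT on both scales, the multiplicative
#' back-transform of a log-scale device coefficient to milliseconds, the
#' age-adjusted RR offset, and raw-vs-log normality diagnostics.
#'
#' @name cohort_comparison
NULL

#' Two-sample Student t comparison
#'
#' Pooled-variance ("Student") t test by default, since equal residual
#' variance is the working assumption for same-protocol ECG extracts;
#' Welch's unequal-variance test is available by flag.
#'
#' @param group_a,group_b numeric samples (each n >= 2).
#' @param welch use Welch's test instead of the pooled-variance test.
#' @return list with per-group `n`, `mean`, `sd`, the `difference`
#'   (mean A - mean B), `t`, `df` and two-sided `p_value`.
#' @export
student_t_compare <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("both groups need at least 2 observations")
  ht <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(n = c(a = length(group_a), b = length(group_b)),
       mean = c(a = mean(group_a), b = mean(group_b)),
       sd = c(a = stats::sd(group_a), b = stats::sd(group_b)),
       difference = mean(group_a) - mean(group_b),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Fisher exact test on two outlier rates
#'
#' Exact two-sided p for the 2x2 table (outliers, inliers) x group,
#' using the probability-mass rule (sum of all tables whose
#' hypergeometric probability does not exceed the observed one) — the
#' convention of `stats::fisher.test`. Two-sided Fisher conventions
#' differ; the doubling rule can give slightly larger p on the same
#' table.
#'
#' @param out_a,n_a outlier count and total in group A.
#' @param out_b,n_b outlier count and total in group B.
#' @return two-sided p-value.
#' @export
fisher_exact_outliers <- function(out_a, n_a, out_b, n_b) {
  if (out_a < 0 || out_b < 0 || out_a > n_a || out_b > n_b)
    stop("counts must satisfy 0 <= out <= n")
  m <- matrix(c(out_a, n_a - out_a, out_b, n_b - out_b),
              nrow = 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

# design variables: male indicator, second-manufacturer indicator
.design_vars <- function(table) {
  lv <- manufacturer_levels(table)
  if (length(lv) < 2) stop("single-level factor: manufacturer")
  if (length(unique(table$sex)) < 2) stop("single-level factor: sex")
  list(male = as.numeric(table$sex == "male"),
       device = as.numeric(table$manufacturer == lv[2]),
       second_label = lv[2])
}

#' Covariate-adjusted QT regression
#'
#' Multivariable OLS of QT on RR, gender, age and manufacturer on the
#' combined two-device table. On the log scale both QT and RR enter as
#' natural logs (coefficients are unit-free); on the raw scale QT and RR
#' enter in milliseconds, so gender/age/device coefficients are in ms.
#' Coding: male = 1, female = 0; second manufacturer label = 1.
#'
#' @param table an [interval_table()] containing both sexes and both
#'   manufacturer labels.
#' @param scale `"log"` or `"raw"`.
#' @return a `multivariate_fit`: data frame `coefficients` (term,
#'   estimate, ci_lower, ci_upper, p_value) plus `scale`, `coding`,
#'   `n`, `r_squared`.
#' @export
fit_multivariate <- function(table, scale = c("log", "raw")) {
  scale <- match.arg(scale)
  if (nrow(table) < 10) stop("need at least 10 records")
  dv <- .design_vars(table)
  if (scale == "log") {
    y <- log(table$qt); x <- log(table$rr)
  } else {
    y <- table$qt * 1000; x <- table$rr * 1000
  }
  d <- data.frame(y = y, rr = x, male = dv$male, age = table$age,
                  device = dv$device)
  fit <- stats::lm(y ~ rr + male + age + device, data = d)
  # constructed collinear inputs fit perfectly; the advisory is expected
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  terms <- c("(Intercept)", "rr", "male", "age", "device")
  structure(list(
    scale = scale,
    coefficients = data.frame(
      term = c("intercept", "rr", "gender_male", "age", "manufacturer"),
      estimate = unname(stats::coef(fit)[terms]),
      ci_lower = unname(ci[terms, 1]), ci_upper = unname(ci[terms, 2]),
      p_value = unname(sm$coefficients[terms, "Pr(>|t|)"]),
      stringsAsFactors = FALSE),
    coding = c(male = 1, female = 0,
               second_manufacturer = dv$second_label),
    n = nrow(table), r_squared = sm$r.squared),
    class = "multivariate_fit")
}

#' @export
print.multivariate_fit <- function(x, ...) {
  cat(sprintf("multivariate_fit (%s scale), n = %d, R^2 = %.3f\n",
              x$scale, x$n, x$r_squared))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Extract one coefficient from a multivariate fit
#' @param fit a `multivariate_fit`.
#' @param term one of `"rr"`, `"gender_male"`, `"age"`, `"manufacturer"`.
#' @return the point estimate.
#' @export
coef_of <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("unknown term '", term, "'")
  fit$coefficients$estimate[i]
}

#' Millisecond QT difference implied by a log-scale coefficient
#'
#' A coefficient c on natural-log QT multiplies QT by exp(c); at a
#' baseline QT of b ms the implied absolute difference is
#' b (exp(c) - 1) ms. (The linear approximation b c is smaller by
#' O(c^2)/2; both are quoted in the vignette.)
#'
#' @param log_coefficient coefficient on ln QT.
#' @param baseline_qt baseline QT in ms (> 0).
#' @return implied difference in ms.
#' @export
implied_qt_difference <- function(log_coefficient, baseline_qt) {
  stopifnot(baseline_qt > 0)
  baseline_qt * (exp(log_coefficient) - 1)
}

#' Age-adjusted RR offset between manufacturers
#'
#' Within one sex, fits RR(ms) ~ age + manufacturer (second label coded
#' 1) and reports the device coefficient in ms, plus the percent
#' difference relative to an explicit denominator: the age-adjusted
#' first-manufacturer mean RR, i.e. the model prediction for the first
#' device at the stratum's overall mean age.
#'
#' @param table an [interval_table()] with both manufacturers.
#' @param sex `"female"` or `"male"`.
#' @return list with `coefficient_ms`, `percent`, `denominator_ms`, `n`.
#' @export
adjusted_rr_difference <- function(table, sex = c("male", "female")) {
  sex <- match.arg(sex)
  lv <- manufacturer_levels(table)
  sub <- table[table$sex == sex, , drop = FALSE]
  if (length(unique(sub$manufacturer)) < 2)
    stop("single-manufacturer stratum: ", sex)
  d <- data.frame(rr = sub$rr * 1000, age = sub$age,
                  device = as.numeric(sub$manufacturer == lv[2]))
  fit <- stats::lm(rr ~ age + device, data = d)
  cf <- stats::coef(fit)
  denom <- unname(cf["(Intercept)"] + cf["age"] * mean(d$age))
  list(coefficient_ms = unname(cf["device"]),
       percent = 100 * unname(cf["device"]) / denom,
       denominator_ms = denom, n = nrow(sub))
}

#' Raw-vs-log normality diagnostics
#'
#' Sample skewness and excess kurtosis of QT, RR, ln QT and ln RR, with
#' a per-pair flag for whether the log transform brings the variable
#' closer to Gaussian (smaller absolute skewness).
#'
#' @param table an [interval_table()] with n >= 10.
#' @return data frame with columns `variable`, `skewness`,
#'   `excess_kurtosis`; attribute `"log_closer"` is a named logical for
#'   qt and rr.
#' @export
distribution_diagnostics <- function(table) {
  if (nrow(table) < 10) stop("need at least 10 records")
  vars <- list(qt = table$qt, rr = table$rr,
               log_qt = log(table$qt), log_rr = log(table$rr))
  out <- data.frame(
    variable = names(vars),
    skewness = vapply(vars, e1071::skewness, numeric(1), type = 2),
    excess_kurtosis = vapply(vars, e1071::kurtosis, numeric(1), type = 2),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "log_closer") <- c(
    qt = abs(out$skewness[out$variable == "log_qt"]) <
      abs(out$skewness[out$variable == "qt"]),
    rr = abs(out$skewness[out$variable == "log_rr"]) <
      abs(out$skewness[out$variable == "rr"]))
  out
}
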