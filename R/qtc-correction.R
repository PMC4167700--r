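#' Heart-rate correction of the QT interval
#'
#' All corrections are anchored so that QTc = QT when RR = 1 s (heart
#' rate 60 bpm). Named formulas: Bazett QT/RR^0.5, Fridericia
#' QT/RR^(1/3), Framingham QT + 0.154 (1 - RR), ECAPS12
#' QT + (1 - RR)/7. Fitted corrections come in two families: `power`
#' with exponent alpha (from a log-log fit, QTc = QT RR^-alpha) and
#' `linear` with slope s (from a raw fit, QTc = QT + s (1 - RR)); the
#' fit intercept is discarded by the RR = 1 anchoring.
#'
#' @param kind one of `"bazett"`, `"fridericia"`, `"framingham"`,
#'   `"ecaps12"`, `"power"`, `"linear"`.
#' @param parameter exponent (power) or slope (linear); ignored, and
#'   must be omitted, for the fixed named formulas.
#' @return a `qtc_model`.
#' @export
correction_model <- function(kind = c("bazett", "fridericia", "framingham",
                                      "ecaps12", "power", "linear"),
                             parameter = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("power", "linear")) {
    if (is.null(parameter)) stop(kind, " model needs a parameter")
  } else if (!is.null(parameter)) {
    stop("named formula '", kind, "' takes no parameter")
  }
  structure(list(kind = kind, parameter = parameter), class = "qtc_model")
}

#' @export
print.qtc_model <- function(x, ...) {
  lbl <- switch(x$kind,
    bazett = "QTc = QT/RR^0.5",
    fridericia = "QTc = QT/RR^(1/3)",
    framingham = "QTc = QT + 0.154*(1-RR)",
    ecaps12 = "QTc = QT + (1-RR)/7",
    power = sprintf("QTc = QT*RR^-%.4g", x$parameter),
    linear = sprintf("QTc = QT + %.4g*(1-RR)", x$parameter))
  cat("qtc_model [", x$kind, "]: ", lbl, "  (RR in s)\n", sep = "")
  invisible(x)
}

#' Apply a heart-rate correction
#'
#' @param model a `qtc_model`.
#' @param qt,rr intervals in seconds (> 0), vectorized.
#' @return QTc in seconds.
#' @export
compute_qtc <- function(model, qt, rr) {
  stopifnot(inherits(model, "qtc_model"))
  if (any(qt <= 0) || any(rr <= 0)) stop("qt and rr must be positive")
  switch(model$kind,
    bazett = qt / sqrt(rr),
    fridericia = qt / rr^(1 / 3),
    framingham = qt + 0.154 * (1 - rr),
    ecaps12 = qt + (1 - rr) / 7,
    power = qt * rr^(-model$parameter),
    linear = qt + model$parameter * (1 - rr))
}

# shared OLS core: y ~ x via stats::lm, 95% t-based CI on the slope
.fit_simple <- function(x, y, scale) {
  if (length(x) < 3) stop("degenerate fit: fewer than 3 points")
  if (stats::var(x) == 0) stop("degenerate fit: zero-variance predictor")
  fit <- stats::lm(y ~ x)
  # zero-noise validation data legitimately fit perfectly; silence the
  # "essentially perfect fit" advisory from summary.lm
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit, "x", level = 0.95))
  structure(list(scale = scale,
                 slope = unname(stats::coef(fit)["x"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 ci = c(lower = ci[1], upper = ci[2]),
                 p_value = sm$coefficients["x", "Pr(>|t|)"],
                 r_squared = sm$r.squared,
                 n = length(x),
                 residual_sd = sm$sigma),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(paste0("regression_fit (%s scale): slope %.4f ",
                     "[%.4f, %.4f], R^2 %.3f, n %d\n"),
              x$scale, x$slope, x$ci["lower"], x$ci["upper"],
              x$r_squared, x$n))
  invisible(x)
}

#' Fit the log-log QT-RR relation
#'
#' Ordinary least squares of ln QT on ln RR; the slope is the
#' heart-rate correction exponent alpha.
#'
#' @param table an [interval_table()].
#' @return a `regression_fit` (scale `"log"`).
#' @export
fit_log_correction <- function(table) {
  .fit_simple(log(table$rr), log(table$qt), "log")
}

#' Fit the raw-scale QT-RR relation
#'
#' Ordinary least squares of QT on RR in seconds; the slope s defines
#' the linear correction QTc = QT + s (1 - RR).
#'
#' @param table an [interval_table()].
#' @return a `regression_fit` (scale `"raw"`).
#' @export
fit_raw_correction <- function(table) {
  .fit_simple(table$rr, table$qt, "raw")
}

#' Turn a fitted relation into a correction model
#'
#' A log-scale fit gives the power correction with alpha = slope; a
#' raw-scale fit gives the linear correction with s = slope. The fit
#' intercept is discarded so that QTc = QT at RR = 1.
#'
#' @param fit a `regression_fit`.
#' @return a `qtc_model` of kind `"power"` or `"linear"`.
#' @export
build_correction <- function(fit) {
  stopifnot(inherits(fit, "regression_fit"))
  if (fit$scale == "log") correction_model("power", fit$slope)
  else correction_model("linear", fit$slope)
}

#' Residual heart-rate dependence of a correction
#'
#' Regresses corrected QT on RR; a slope (beta) of zero certifies that
#' the correction removed the heart-rate effect. Validation is done on
#' the log scale by default (ln QTc on ln RR) for every correction
#' family; a raw-scale variant is available.
#'
#' @param table an [interval_table()].
#' @param model a `qtc_model`.
#' @param scale `"log"` (default) or `"raw"` validation regression.
#' @return a `regression_fit`; its `slope` is beta.
#' @export
residual_slope <- function(table, model, scale = c("log", "raw")) {
  scale <- match.arg(scale)
  qtc <- compute_qtc(model, table$qt, table$rr)
  if (scale == "log") .fit_simple(log(table$rr), log(qtc), "log")
  else .fit_simple(table$rr, qtc, "raw")
}
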