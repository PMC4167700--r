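#' Bivariate-normal ellipse outlier gate
#'
#' Outliers are points outside the probability contour of a bivariate
#' normal distribution that encloses a stated fraction (default 99.9%)
#' of its density. The contour is the ellipse of constant Mahalanobis
#' distance; for two dimensions the squared-distance cutoff has the
#' closed form t = -2 ln(1 - p), which equals the chi-square quantile
#' with 2 degrees of freedom.
#'
#' @param x,y coordinates of the points the gate is fitted to (log QT
#'   vs log RR, or raw QT vs raw RR).
#' @param coverage probability mass the ellipse must contain, in (0, 1).
#' @return an `ellipse_gate` with fields `mean_x`, `mean_y`, `sd_x`,
#'   `sd_y`, `rho`, `coverage` and `threshold`.
#' @export
fit_gate <- function(x, y, coverage = 0.999) {
  stopifnot(length(x) == length(y), coverage > 0, coverage < 1)
  if (length(x) < 3) stop("degenerate gate: fewer than 3 points")
  sdx <- stats::sd(x); sdy <- stats::sd(y)
  if (sdx == 0 || sdy == 0) stop("degenerate gate: zero variance")
  rho <- stats::cor(x, y)
  if (abs(rho) >= 1 - 1e-12) stop("degenerate gate: collinear input")
  structure(list(mean_x = mean(x), mean_y = mean(y), sd_x = sdx,
                 sd_y = sdy, rho = rho, coverage = coverage,
                 threshold = -2 * log(1 - coverage)),
            class = "ellipse_gate")
}

#' @export
print.ellipse_gate <- function(x, ...) {
  cat(sprintf(paste0("ellipse_gate: mean (%.4g, %.4g), sd (%.4g, %.4g),",
                     " rho %.4f\n  coverage %.4f, d^2 threshold %.4f\n"),
              x$mean_x, x$mean_y, x$sd_x, x$sd_y, x$rho,
              x$coverage, x$threshold))
  invisible(x)
}

#' Squared Mahalanobis distance from a gate's centre
#'
#' Uses the standardized bivariate form
#' d^2 = (zx^2 - 2 rho zx zy + zy^2) / (1 - rho^2), which equals the
#' quadratic form with the explicit inverse covariance matrix; it is
#' invariant under affine rescaling of either axis.
#'
#' @param gate an `ellipse_gate`.
#' @param x,y point coordinates (vectorized).
#' @return squared distances (>= 0).
#' @export
mahalanobis_sq <- function(gate, x, y) {
  zx <- (x - gate$mean_x) / gate$sd_x
  zy <- (y - gate$mean_y) / gate$sd_y
  (zx^2 - 2 * gate$rho * zx * zy + zy^2) / (1 - gate$rho^2)
}

#' Gate an interval table
#'
#' Fits one ellipse per (manufacturer x sex) stratum (or one pooled
#' gate) to the chosen scale of (QT, RR) and classifies each record as
#' inlier (squared Mahalanobis distance at most the coverage threshold)
#' or outlier, in a single pass with no refitting after exclusion.
#'
#' @param table an [interval_table()].
#' @param scale `"log"` (natural log of QT and RR) or `"raw"`.
#' @param coverage ellipse probability mass (default 0.999).
#' @param stratify `"stratum"` (per manufacturer x sex, the default) or
#'   `"pooled"` (one gate for the whole table).
#' @return list with `inliers` (an `interval_table`) and `summary`, a
#'   data frame of per-stratum `n_before`, `n_inliers`, `n_outliers`
#'   and `pct_outliers`.
#' @export
apply_gate <- function(table, scale = c("log", "raw"), coverage = 0.999,
                       stratify = c("stratum", "pooled")) {
  scale <- match.arg(scale)
  stratify <- match.arg(stratify)
  fx <- if (scale == "log") log(table$qt) else table$qt
  fy <- if (scale == "log") log(table$rr) else table$rr
  if (stratify == "pooled") {
    key <- rep("pooled", nrow(table))
  } else {
    key <- paste(table$manufacturer, table$sex, sep = ":")
  }
  inlier <- logical(nrow(table))
  groups <- unique(key)
  rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    idx <- which(key == groups[gi])
    gate <- tryCatch(fit_gate(fx[idx], fy[idx], coverage),
                     error = function(e)
                       stop("stratum '", groups[gi], "': ",
                            conditionMessage(e), call. = FALSE))
    d2 <- mahalanobis_sq(gate, fx[idx], fy[idx])
    inlier[idx] <- d2 <= gate$threshold
    rows[[gi]] <- data.frame(
      stratum = groups[gi],
      manufacturer = if (stratify == "pooled") NA_character_
                     else table$manufacturer[idx[1]],
      sex = if (stratify == "pooled") NA_character_
            else as.character(table$sex[idx[1]]),
      n_before = length(idx), n_inliers = sum(inlier[idx]),
      n_outliers = sum(!inlier[idx]),
      pct_outliers = 100 * mean(!inlier[idx]),
      stringsAsFactors = FALSE)
  }
  kept <- table[inlier, , drop = FALSE]
  attr(kept, "manufacturer_levels") <- manufacturer_levels(table)
  attr(kept, "provenance") <- attr(table, "provenance")
  class(kept) <- class(table)
  list(inliers = kept, summary = do.call(rbind, rows))
}
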