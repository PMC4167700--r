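#' Pipeline configuration
#'
#' Exactly one input source: a CSV of interval measurements or a
#' synthetic-cohort preset. The remaining fields mirror the stage
#' options: gate scale/coverage/stratification, the correction methods
#' to evaluate, and the adult-inclusion age bound.
#'
#' @param csv path to an interval CSV (mutually exclusive with
#'   `preset`).
#' @param units unit of the CSV qt/rr columns.
#' @param preset a [cohort_presets()] name.
#' @param n_scale multiplicative factor on preset stratum sizes.
#' @param seed RNG seed for generation.
#' @param gate_scale `"log"` or `"raw"` gating coordinates.
#' @param coverage ellipse coverage, in (0, 1).
#' @param stratify `"stratum"` or `"pooled"` gate fitting.
#' @param methods published corrections to evaluate alongside the fitted
#'   ones; subset of bazett, fridericia, framingham, ecaps12.
#' @param min_age inclusion bound in years.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(csv = NULL, units = "ms", preset = NULL,
                            n_scale = 1, seed = 1,
                            gate_scale = "log", coverage = 0.999,
                            stratify = "stratum",
                            methods = c("fridericia", "bazett",
                                        "framingham", "ecaps12"),
                            min_age = 20) {
  if (is.null(csv) == is.null(preset))
    stop("exactly one of csv and preset must be given")
  if (!(coverage > 0 && coverage < 1))
    stop("coverage must be in (0, 1)")
  if (length(methods) < 1) stop("at least one correction method")
  methods <- match.arg(methods, c("fridericia", "bazett", "framingham",
                                  "ecaps12"), several.ok = TRUE)
  structure(list(csv = csv, units = units, preset = preset,
                 n_scale = n_scale, seed = as.integer(seed),
                 gate_scale = match.arg(gate_scale, c("log", "raw")),
                 coverage = coverage,
                 stratify = match.arg(stratify, c("stratum", "pooled")),
                 methods = methods, min_age = min_age),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", name, "]: ", conditionMessage(e),
         call. = FALSE))
}

.mean_sd_ms <- function(x) {
  if (length(x) == 0) return(c(mean = NA_real_, sd = NA_real_))
  s <- if (length(x) == 1) {
    warning("single-record stratum: SD reported as 0", call. = FALSE)
    0
  } else stats::sd(x)
  c(mean = mean(x) * 1000, sd = s * 1000)
}

#' Run the full comparison pipeline
#'
#' Stages, in order: load or simulate the interval table; apply
#' adult-inclusion validation; gate outliers; fit the log and raw QT-RR
#' relations per manufacturer and build the corresponding "ours"
#' corrections; validate residual heart-rate dependence of every
#' correction; tabulate per-stratum means/SDs; run between-manufacturer
#' Student t tests per sex and metric, Fisher exact tests on outlier
#' rates, and (log and raw) covariate-adjusted multivariable fits with
#' the implied millisecond device offset. Deterministic given the
#' config (which includes the seed); any stage failure aborts the run
#' with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return a `report_bundle` list; see [render_summary()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  table <- .stage("load", {
    if (!is.null(config$csv))
      read_interval_csv(config$csv, units = config$units)
    else
      generate_cohort(scale_cohort(default_params(config$preset),
                                   factor = config$n_scale),
                      seed = config$seed)
  })
  val <- .stage("validate", validate_table(table, config$min_age))
  gated <- .stage("gate", apply_gate(val$table, scale = config$gate_scale,
                                     coverage = config$coverage,
                                     stratify = config$stratify))
  inl <- gated$inliers
  manufacturers <- manufacturer_levels(inl)

  fits <- .stage("fit", {
    out <- list()
    for (m in manufacturers) {
      sub <- inl[inl$manufacturer == m, , drop = FALSE]
      out[[m]] <- list(log = fit_log_correction(sub),
                       raw = fit_raw_correction(sub))
    }
    out
  })
  models <- .stage("build", {
    out <- list()
    for (m in manufacturers)
      out[[m]] <- list(ours_log = build_correction(fits[[m]]$log),
                       ours_raw = build_correction(fits[[m]]$raw))
    out
  })
  named_models <- lapply(stats::setNames(config$methods, config$methods),
                         correction_model)

  resid <- .stage("residual", {
    rows <- list()
    for (m in manufacturers) {
      sub <- inl[inl$manufacturer == m, , drop = FALSE]
      mods <- c(models[[m]], named_models)
      for (nm in names(mods)) {
        rs <- residual_slope(sub, mods[[nm]])
        rows[[length(rows) + 1]] <- data.frame(
          manufacturer = m, method = nm, beta = rs$slope,
          ci_lower = rs$ci["lower"], ci_upper = rs$ci["upper"],
          p_value = rs$p_value, stringsAsFactors = FALSE)
      }
    }
    r <- do.call(rbind, rows); rownames(r) <- NULL; r
  })

  strata <- .stage("summarize", {
    rows <- list()
    for (m in manufacturers) for (sx in c("male", "female")) {
      sub <- inl[inl$manufacturer == m & inl$sex == sx, , drop = FALSE]
      row <- list(manufacturer = m, sex = sx, n = nrow(sub))
      if (nrow(sub) == 0) {
        row <- c(row, list(age_mean = NA_real_, age_sd = NA_real_,
                           qt_mean = NA_real_, qt_sd = NA_real_,
                           rr_mean = NA_real_, rr_sd = NA_real_))
      } else {
        ag <- c(mean = mean(sub$age),
                sd = if (nrow(sub) > 1) stats::sd(sub$age) else 0)
        qt <- .mean_sd_ms(sub$qt); rr <- .mean_sd_ms(sub$rr)
        row <- c(row, list(age_mean = ag[["mean"]], age_sd = ag[["sd"]],
                           qt_mean = qt[["mean"]], qt_sd = qt[["sd"]],
                           rr_mean = rr[["mean"]], rr_sd = rr[["sd"]]))
      }
      mods <- c(models[[m]], named_models)
      for (nm in names(mods)) {
        ms <- if (nrow(sub) == 0) c(mean = NA_real_, sd = NA_real_)
              else .mean_sd_ms(compute_qtc(mods[[nm]], sub$qt, sub$rr))
        row[[paste0("qtc_", nm, "_mean")]] <- ms[["mean"]]
        row[[paste0("qtc_", nm, "_sd")]] <- ms[["sd"]]
      }
      rows[[length(rows) + 1]] <- as.data.frame(row,
                                                stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  two_devices <- length(manufacturers) >= 2
  t_tests <- fisher <- multivariate <- NULL
  if (two_devices) {
    t_tests <- .stage("compare", {
      rows <- list()
      metrics <- c(list(qt = function(s) s$qt, rr = function(s) s$rr),
                   lapply(names(named_models), function(nm) {
                     force(nm); function(s) compute_qtc(named_models[[nm]],
                                                        s$qt, s$rr)
                   }))
      names(metrics) <- c("qt", "rr", paste0("qtc_", names(named_models)))
      for (sx in c("male", "female")) {
        a <- inl[inl$manufacturer == manufacturers[1] & inl$sex == sx, ]
        b <- inl[inl$manufacturer == manufacturers[2] & inl$sex == sx, ]
        if (nrow(a) < 2 || nrow(b) < 2) next
        for (mt in names(metrics)) {
          va <- metrics[[mt]](a); vb <- metrics[[mt]](b)
          tt <- student_t_compare(va, vb)
          rows[[length(rows) + 1]] <- data.frame(
            sex = sx, metric = mt,
            difference_ms = tt$difference * 1000, t = tt$t, df = tt$df,
            p_value = tt$p_value, stringsAsFactors = FALSE)
        }
        for (sc in c("ours_log", "ours_raw")) {
          va <- compute_qtc(models[[manufacturers[1]]][[sc]], a$qt, a$rr)
          vb <- compute_qtc(models[[manufacturers[2]]][[sc]], b$qt, b$rr)
          tt <- student_t_compare(va, vb)
          rows[[length(rows) + 1]] <- data.frame(
            sex = sx, metric = paste0("qtc_", sc),
            difference_ms = tt$difference * 1000, t = tt$t, df = tt$df,
            p_value = tt$p_value, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
    fisher <- .stage("fisher", {
      sm <- gated$summary
      rows <- list()
      for (sx in c("male", "female")) {
        a <- sm[sm$manufacturer == manufacturers[1] & sm$sex == sx, ]
        b <- sm[sm$manufacturer == manufacturers[2] & sm$sex == sx, ]
        if (nrow(a) != 1 || nrow(b) != 1) next
        rows[[length(rows) + 1]] <- data.frame(
          sex = sx,
          out_a = a$n_outliers, n_a = a$n_before,
          out_b = b$n_outliers, n_b = b$n_before,
          p_value = fisher_exact_outliers(a$n_outliers, a$n_before,
                                          b$n_outliers, b$n_before),
          stringsAsFactors = FALSE)
      }
      if (length(rows)) do.call(rbind, rows) else NULL
    })
    multivariate <- .stage("multivariate", {
      if (length(unique(inl$sex)) < 2) NULL else {
        mlog <- fit_multivariate(inl, "log")
        mraw <- fit_multivariate(inl, "raw")
        list(log = mlog, raw = mraw,
             implied_ms = implied_qt_difference(
               coef_of(mlog, "manufacturer"), 400))
      }
    })
  }

  structure(list(config = config, n_input = nrow(table),
                 validation = val[c("n_total", "n_kept", "n_rejected",
                                    "rules")],
                 outliers = gated$summary, fisher = fisher,
                 fits = fits, models = models, residual_beta = resid,
                 strata = strata, t_tests = t_tests,
                 multivariate = multivariate,
                 seed = config$seed),
            class = "report_bundle")
}

# stratum table with ms values rounded to one decimal (round half to
# even, R's default rounding), the single source for all render formats
.rounded_strata <- function(bundle) {
  st <- bundle$strata
  num <- setdiff(names(st), c("manufacturer", "sex", "n"))
  for (v in num) st[[v]] <- round(st[[v]], 1)
  st
}

#' Render the stratified summary report
#'
#' One row per (manufacturer, sex) stratum with n, age, QT, RR and
#' every QTc method as mean and SD in milliseconds, rounded to one
#' decimal (round-half-even). The three formats serialize the same
#' rounded table; empty strata render as explicit n = 0 rows.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param format `"text"`, `"tsv"` or `"json"`.
#' @return a character scalar holding the serialized report.
#' @export
render_summary <- function(bundle, format = c("text", "tsv", "json")) {
  format <- match.arg(format)
  st <- .rounded_strata(bundle)
  if (format == "json")
    return(as.character(jsonlite::toJSON(st, dataframe = "rows",
                                         auto_unbox = TRUE, digits = NA,
                                         na = "null")))
  if (format == "tsv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(st, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  fmt <- function(m, s) ifelse(is.na(m), "-",
                               sprintf("%s ± %s",
                                       formatC(m, format = "f", digits = 1),
                                       formatC(s, format = "f", digits = 1)))
  # method column order mirrors the reference layout:
  # log family Ours | Fridericia | Bazett, raw family Ours | Framingham
  # | ECAPs12 (only the methods actually evaluated are shown)
  want <- intersect(c("ours_log", "fridericia", "bazett",
                      "ours_raw", "framingham", "ecaps12"),
                    sub("_(mean)$", "",
                        sub("^qtc_", "",
                            grep("^qtc_.*_mean$", names(st), value = TRUE))))
  lines <- c(sprintf("%-14s %-7s %8s %14s %16s %16s", "manufacturer",
                     "sex", "n", "age", "QT (ms)", "RR (ms)"),
             strrep("-", 78))
  for (i in seq_len(nrow(st))) {
    lines <- c(lines, sprintf("%-14s %-7s %8d %14s %16s %16s",
                              st$manufacturer[i], st$sex[i], st$n[i],
                              fmt(st$age_mean[i], st$age_sd[i]),
                              fmt(st$qt_mean[i], st$qt_sd[i]),
                              fmt(st$rr_mean[i], st$rr_sd[i])))
    for (w in want) {
      mc <- paste0("qtc_", w, "_mean"); sc <- paste0("qtc_", w, "_sd")
      lines <- c(lines, sprintf("    QTc %-12s %16s", w,
                                fmt(st[[mc]][i], st[[sc]][i])))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
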