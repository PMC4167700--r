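#' ECG interval tables
#'
#' An `interval_table` is a data frame with one row per ECG and columns
#' `qt` and `rr` (durations in seconds), `sex` (factor with levels
#' `female`, `male`), `age` (years) and `manufacturer` (character label).
#' Seconds are the canonical internal unit because every correction
#' formula (e.g. QTc = QT + (1 - RR)/7) is stated for QT and RR in
#' seconds; file I/O defaults to milliseconds, the unit interval tables
#' are usually distributed in.
#'
#' @param qt QT intervals in seconds (> 0).
#' @param rr RR intervals in seconds (> 0).
#' @param sex character or factor; values `"female"`/`"male"`.
#' @param age ages in years.
#' @param manufacturer character device labels.
#' @param provenance optional list recording source and original unit.
#' @param manufacturer_levels optional character vector fixing the order
#'   of manufacturer labels (the second label is the "exposed" device in
#'   regression codings). Defaults to order of first appearance.
#' @return An `interval_table` (data frame subclass).
#' @export
interval_table <- function(qt, rr, sex, age, manufacturer,
                           provenance = NULL, manufacturer_levels = NULL) {
  n <- length(qt)
  if (length(sex) == 1) sex <- rep(sex, n)
  if (length(age) == 1) age <- rep(age, n)
  if (length(manufacturer) == 1) manufacturer <- rep(manufacturer, n)
  stopifnot(length(rr) == n, length(sex) == n, length(age) == n,
            length(manufacturer) == n)
  if (any(!is.finite(qt)) || any(qt <= 0))
    stop("qt must be finite and positive")
  if (any(!is.finite(rr)) || any(rr <= 0))
    stop("rr must be finite and positive")
  sex <- factor(as.character(sex), levels = c("female", "male"))
  if (anyNA(sex)) stop("sex must be 'female' or 'male'")
  manufacturer <- as.character(manufacturer)
  if (is.null(manufacturer_levels))
    manufacturer_levels <- unique(manufacturer)
  if (!all(manufacturer %in% manufacturer_levels))
    stop("manufacturer labels outside declared manufacturer_levels")
  out <- data.frame(qt = as.numeric(qt), rr = as.numeric(rr), sex = sex,
                    age = as.numeric(age), manufacturer = manufacturer,
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  attr(out, "manufacturer_levels") <- manufacturer_levels
  class(out) <- c("interval_table", "data.frame")
  out
}

#' @export
print.interval_table <- function(x, ...) {
  cat(sprintf("interval_table: %d records, %d manufacturer(s)\n",
              nrow(x), length(manufacturer_levels(x))))
  print(stratum_counts(x))
  invisible(x)
}

#' Manufacturer label order of a table
#'
#' @param table an `interval_table`.
#' @return character vector of manufacturer labels in coding order.
#' @export
manufacturer_levels <- function(table) {
  lv <- attr(table, "manufacturer_levels")
  if (is.null(lv)) lv <- unique(table$manufacturer)
  lv
}

#' Record counts by manufacturer and sex
#'
#' @param table an `interval_table`.
#' @return contingency table of counts, manufacturer by sex.
#' @export
stratum_counts <- function(table) {
  table(factor(table$manufacturer, levels = manufacturer_levels(table)),
        table$sex, dnn = c("manufacturer", "sex"))
}

.required_cols <- c("qt", "rr", "sex", "age", "manufacturer")

.normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("female", "f")] <- "female"
  out[x %in% c("male", "m")] <- "male"
  out
}

#' Read an interval table from CSV
#'
#' Expects a header naming (case-insensitively) columns qt, rr, sex, age
#' and manufacturer; `col_map` can redirect any of them to differently
#' named file columns. Rows with non-numeric qt/rr/age, non-positive
#' qt/rr, or an unrecognizable sex are rejected individually and
#' reported, not fatal; a missing column or an empty file is fatal.
#'
#' @param path CSV file path (comma separator, `.` decimal, UTF-8).
#' @param units unit of the qt/rr columns in the file: `"ms"` (default)
#'   or `"s"`. Values are converted to seconds internally.
#' @param col_map optional named character vector mapping internal names
#'   (qt, rr, sex, age, manufacturer) to file column names.
#' @return An `interval_table`; rejected rows are recorded in the
#'   `"rejections"` attribute as a data frame with columns `row` (data
#'   row number) and `reason`.
#' @export
read_interval_csv <- function(path, units = c("ms", "s"), col_map = NULL) {
  units <- match.arg(units)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character"),
    error = function(e) stop("empty or unreadable file: ", path,
                             call. = FALSE))
  if (nrow(raw) == 0 && ncol(raw) == 0) stop("empty file: ", path)
  names(raw) <- tolower(trimws(names(raw)))
  wanted <- stats::setNames(.required_cols, .required_cols)
  if (!is.null(col_map)) wanted[names(col_map)] <- tolower(col_map)
  missing <- wanted[!wanted %in% names(raw)]
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0) stop("empty file (header only): ", path)

  qt <- suppressWarnings(as.numeric(raw[[wanted["qt"]]]))
  rr <- suppressWarnings(as.numeric(raw[[wanted["rr"]]]))
  age <- suppressWarnings(as.numeric(raw[[wanted["age"]]]))
  sex <- .normalize_sex(raw[[wanted["sex"]]])
  man <- trimws(raw[[wanted["manufacturer"]]])

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(age)] <- "non-numeric age"
  reason[is.na(rr)] <- "non-numeric rr"
  reason[is.na(qt)] <- "non-numeric qt"
  reason[!is.na(rr) & rr <= 0] <- "non-positive rr"
  reason[!is.na(qt) & qt <= 0] <- "non-positive qt"
  reason[is.na(reason) & is.na(sex)] <- "unrecognized sex"
  keep <- is.na(reason)

  scale <- if (units == "ms") 1e-3 else 1
  tab <- interval_table(qt[keep] * scale, rr[keep] * scale, sex[keep],
                        age[keep], man[keep],
                        provenance = list(source = path, units = units))
  attr(tab, "rejections") <- data.frame(row = which(!keep),
                                        reason = reason[!keep],
                                        stringsAsFactors = FALSE)
  tab
}

#' Write an interval table to CSV
#'
#' Inverse of [read_interval_csv()]: values are converted from internal
#' seconds to `units` and written with full double precision, so a
#' write/read round trip preserves values and record order.
#'
#' @param table an `interval_table`.
#' @param path output file path.
#' @param units unit for the written qt/rr columns (`"ms"` default).
#' @return `path`, invisibly.
#' @export
write_interval_csv <- function(table, path, units = c("ms", "s")) {
  units <- match.arg(units)
  scale <- if (units == "ms") 1e3 else 1
  out <- data.frame(qt = table$qt * scale, rr = table$rr * scale,
                    sex = as.character(table$sex), age = table$age,
                    manufacturer = table$manufacturer)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply study-inclusion validation to a table
#'
#' The study population is adults (age at or above `min_age` years,
#' inclusive); positivity of qt/rr is already guaranteed by the
#' `interval_table` constructor but is re-checked for defense in depth.
#'
#' @param table an `interval_table`.
#' @param min_age inclusion threshold in years (default 20).
#' @return list with `table` (kept records), `n_total`, `n_kept`,
#'   `n_rejected`, and `rules`, a named count of rejections per rule.
#' @export
validate_table <- function(table, min_age = 20) {
  underage <- table$age < min_age
  bad_qt <- table$qt <= 0
  bad_rr <- table$rr <= 0
  drop <- underage | bad_qt | bad_rr
  kept <- table[!drop, , drop = FALSE]
  attr(kept, "manufacturer_levels") <- manufacturer_levels(table)
  attr(kept, "provenance") <- attr(table, "provenance")
  class(kept) <- class(table)
  list(table = kept,
       n_total = nrow(table),
       n_kept = sum(!drop),
       n_rejected = sum(drop),
       rules = c(underage = sum(underage),
                 `non-positive qt` = sum(bad_qt),
                 `non-positive rr` = sum(bad_rr)))
}
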