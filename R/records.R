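# Tabular dose-survival records and their aggregation into mean curves.
#
# A record is one dose group of one experiment: the matched experimental
# factors (the "condition key"), the dosing vehicle, the screener and
# experiment identifiers, the dose in mg per kg per injection, the observed
# survival fraction and the number of animals in the group. Experiments are
# comparable only when every condition-key field matches exactly.

#' Condition-key field names
#'
#' The experimental factors that must match exactly for two experiments to
#' be comparable: compound, route, species, number of injections, injection
#' interval, first injection day, number of repetitions, assessment day and
#' any restart days. All fields are stored as character strings and compared
#' verbatim.
#'
#' @return character vector of column names.
#' @export
condition_fields <- function() {
  c("compound_id", "route", "species", "n_injections", "injection_interval",
    "first_injection_day", "n_repetitions", "assessment_day", "restart_days")
}

#' Full record schema
#'
#' @return character vector: condition-key fields plus vehicle, screener,
#'   experiment_id, dose, survival and n_animals.
#' @export
record_fields <- function() {
  c(condition_fields(), "vehicle", "screener", "experiment_id",
    "dose", "survival", "n_animals")
}

# Canonical file-header names; `dose` is spelled out in files.
.file_columns <- function() {
  cols <- record_fields()
  cols[cols == "dose"] <- "dose_mg_per_kg_per_injection"
  cols
}

# Parse a survival column that may carry percent signs or percent-scale
# numbers. Values ending in "%" and bare values above 1 are treated as
# percentages and divided by 100.
.parse_survival <- function(x) {
  x <- trimws(as.character(x))
  pct <- grepl("%$", x)
  val <- suppressWarnings(as.numeric(sub("%$", "", x)))
  val[pct] <- val[pct] / 100
  over <- !pct & !is.na(val) & val > 1
  val[over] <- val[over] / 100
  val
}

#' Validate toxicity records
#'
#' Checks each row against the record invariants: non-empty condition-key
#' fields, dose > 0, survival in \[0, 1\], a positive integer animal count,
#' and survival times animal count within rounding of a whole number of
#' animals. Failing rows are separated out with a reason, never silently
#' dropped.
#'
#' @param df data.frame in the internal record schema (see [record_fields()]).
#' @return list with `records` (valid rows) and `rejected` (failing rows with
#'   a `reason` column).
#' @export
validate_records <- function(df) {
  reason <- character(nrow(df))
  key_ok <- rep(TRUE, nrow(df))
  for (f in setdiff(condition_fields(), "restart_days")) {
    bad <- is.na(df[[f]]) | !nzchar(trimws(as.character(df[[f]])))
    reason[bad & !nzchar(reason)] <- paste0("missing ", f)
    key_ok <- key_ok & !bad
  }
  bad_dose <- is.na(df$dose) | df$dose <= 0
  reason[bad_dose & !nzchar(reason)] <- "non-positive dose"
  bad_surv <- is.na(df$survival) | df$survival < 0 | df$survival > 1
  reason[bad_surv & !nzchar(reason)] <- "survival outside [0,1]"
  bad_n <- is.na(df$n_animals) | df$n_animals <= 0 |
    abs(df$n_animals - round(df$n_animals)) > 1e-9
  reason[bad_n & !nzchar(reason)] <- "invalid animal count"
  # survival * n_animals should be a whole number of surviving animals up to
  # percent-scale rounding of the reported fraction
  survivors <- df$survival * df$n_animals
  ok_so_far <- !nzchar(reason)
  bad_frac <- ok_so_far &
    abs(survivors - round(survivors)) > 0.01 * df$n_animals + 1e-9
  reason[bad_frac] <- "survival inconsistent with animal count"
  keep <- !nzchar(reason)
  rejected <- df[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep]
  list(records = df[keep, , drop = FALSE], rejected = rejected)
}

#' Read dose-survival records from CSV/TSV
#'
#' Reads a records table, renames foreign headers through an optional
#' dialect map, converts percent survival to fractions and validates every
#' row. Rejected rows are attached as the `"rejected"` attribute and can be
#' written to a sidecar report file.
#'
#' @param path file path; `.tsv`/`.tab` files are read tab-separated.
#' @param dialect optional named character vector mapping canonical column
#'   names (see [record_fields()]; dose is `dose_mg_per_kg_per_injection`)
#'   to the names used in the file.
#' @param reject_path optional path for a CSV report of rejected rows.
#' @return data.frame of validated records (class `tox_records`) with
#'   attribute `rejected`.
#' @export
read_records <- function(path, dialect = NULL, reject_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", na.strings = c("NA"))
  wanted <- .file_columns()
  have <- wanted
  if (!is.null(dialect)) {
    idx <- match(wanted, names(dialect))
    have[!is.na(idx)] <- unname(dialect[idx[!is.na(idx)]])
  }
  missing <- setdiff(have, names(raw))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- raw[have]
  names(df) <- record_fields()
  df$restart_days[is.na(df$restart_days)] <- ""
  df$dose <- suppressWarnings(as.numeric(df$dose))
  df$survival <- .parse_survival(df$survival)
  df$n_animals <- suppressWarnings(as.numeric(df$n_animals))
  out <- validate_records(df)
  rec <- out$records
  rownames(rec) <- NULL
  class(rec) <- c("tox_records", "data.frame")
  attr(rec, "rejected") <- out$rejected
  if (!is.null(reject_path)) {
    utils::write.csv(out$rejected, reject_path, row.names = FALSE)
  }
  rec
}

#' Write records to CSV
#'
#' @param records data.frame of records.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  df <- as.data.frame(records)[record_fields()]
  names(df)[names(df) == "dose"] <- "dose_mg_per_kg_per_injection"
  for (col in c("dose_mg_per_kg_per_injection", "survival", "n_animals")) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Merge dose levels equal within relative tolerance 1e-9 onto one
# representative value; returns the representative for each input dose.
.merge_dose_levels <- function(dose, rtol = 1e-9) {
  u <- sort(unique(dose))
  if (length(u) > 1) {
    rep_of <- u
    for (i in 2:length(u)) {
      if (u[i] - rep_of[i - 1] <= rtol * max(abs(u[i]), 1)) {
        rep_of[i] <- rep_of[i - 1]
      }
    }
    u_map <- stats::setNames(rep_of, format(u, digits = 17))
    return(unname(u_map[format(dose, digits = 17)]))
  }
  dose
}

# Internal grouping id: condition key + vehicle, concatenated verbatim.
.group_id <- function(df, with_vehicle = TRUE) {
  cols <- condition_fields()
  if (with_vehicle) cols <- c(cols, "vehicle")
  do.call(paste, c(lapply(df[cols], as.character), sep = "\r"))
}

#' Aggregate replicate experiments into mean dose-survival curves
#'
#' Groups records by (condition key, vehicle) and averages survival over all
#' records at each distinct dose; replicate experiments within and across
#' screeners contribute equally. The union of dose levels is taken: each
#' dose averages only the experiments that tested it. Doses equal within
#' relative tolerance 1e-9 are treated as one level.
#'
#' @param records validated records (see [read_records()]).
#' @return long-format data.frame (class `tox_curves`): condition-key
#'   columns, `vehicle`, `n_experiments`, and one row per (dose, mean
#'   survival) point, sorted by dose within each curve.
#' @export
aggregate_curves <- function(records) {
  df <- as.data.frame(records)
  empty <- df[0, c(condition_fields(), "vehicle")]
  if (!nrow(df)) {
    out <- cbind(empty, n_experiments = integer(), dose = numeric(),
                 survival = numeric())
    class(out) <- c("tox_curves", "data.frame")
    return(out)
  }
  gid <- .group_id(df)
  pieces <- lapply(split(seq_len(nrow(df)), gid), function(ix) {
    g <- df[ix, , drop = FALSE]
    lev <- .merge_dose_levels(g$dose)
    s <- tapply(g$survival, lev, mean)
    d <- as.numeric(names(s))
    o <- order(d)
    cbind(g[rep(1, length(d)), c(condition_fields(), "vehicle"),
            drop = FALSE],
          n_experiments = length(unique(g$experiment_id)),
          dose = d[o], survival = as.numeric(s)[o])
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("tox_curves", "data.frame")
  out
}

#' Write aggregate curves to CSV
#'
#' Numeric columns are serialised at full double precision so that a
#' write/read cycle is lossless.
#'
#' @param curves `tox_curves` data.frame from [aggregate_curves()].
#' @param path output path.
#' @export
write_curves <- function(curves, path) {
  df <- as.data.frame(curves)
  for (col in c("dose", "survival")) df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read aggregate curves from CSV
#'
#' @param path file written by [write_curves()].
#' @return `tox_curves` data.frame.
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$restart_days[is.na(df$restart_days)] <- ""
  df$n_experiments <- as.integer(df$n_experiments)
  df$dose <- as.numeric(df$dose)
  df$survival <- as.numeric(df$survival)
  class(df) <- c("tox_curves", "data.frame")
  df
}

#' Extract one dose-survival curve
#'
#' @param curves `tox_curves` data.frame.
#' @param compound_id compound identifier.
#' @param vehicle vehicle name.
#' @param ... further condition-key fields to filter on (needed when a
#'   compound was tested under several conditions).
#' @return a [survival_curve()] object.
#' @export
get_curve <- function(curves, compound_id, vehicle, ...) {
  df <- as.data.frame(curves)
  keep <- df$compound_id == compound_id & df$vehicle == vehicle
  extra <- list(...)
  for (f in names(extra)) keep <- keep & df[[f]] == extra[[f]]
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) stop("no curve for compound ", compound_id,
                      " in vehicle ", vehicle)
  if (length(unique(.group_id(df))) > 1) {
    stop("more than one condition matches; restrict with key fields")
  }
  survival_curve(df$dose, df$survival, vehicle = vehicle,
                 n_experiments = df$n_experiments[1])
}
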