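#' Canonical measure-name mapping for GBD results-tool exports
#'
#' Named character vector mapping the verbose measure labels used by GHDx
#' results-tool CSV exports (and their short forms) onto the canonical
#' measure names used throughout this package: `incidence`, `prevalence`,
#' `deaths`, `YLLs`, `YLDs`, `DALYs`.  Pass a modified copy to
#' [read_gbd_csv()] via `measure_map` when an export uses different labels.
#'
#' @format Named character vector; names are input labels, values canonical
#'   measure names.
#' @export
gbd_measure_map <- c(
  "Incidence"                               = "incidence",
  "Prevalence"                              = "prevalence",
  "Deaths"                                  = "deaths",
  "YLLs (Years of Life Lost)"               = "YLLs",
  "YLDs (Years Lived with Disability)"      = "YLDs",
  "DALYs (Disability-Adjusted Life Years)"  = "DALYs",
  "incidence"  = "incidence",
  "prevalence" = "prevalence",
  "deaths"     = "deaths",
  "YLLs"       = "YLLs",
  "YLDs"       = "YLDs",
  "DALYs"      = "DALYs"
)

canonical_measures <- c("incidence", "prevalence", "deaths",
                        "YLLs", "YLDs", "DALYs")

metric_map <- c("Number" = "number", "Rate" = "rate", "Percent" = "percent",
                "number" = "number", "rate" = "rate", "percent" = "percent")

sex_map <- c("Male" = "male", "Female" = "female", "Both" = "both",
             "male" = "male", "female" = "female", "both" = "both")

#' Infer the aggregation level of a location label
#'
#' Heuristic classification of GBD location names into the levels used by
#' the pipeline: the global aggregate, World Bank income groups, SDI
#' quintiles, named world regions, and (by default) countries.
#'
#' @param location Character vector of location names.
#' @return Character vector with entries from `global`, `income_group`,
#'   `sdi_quintile`, `region`, `country`.
#' @export
infer_location_level <- function(location) {
  lev <- rep("country", length(location))
  lev[grepl("^(Global|World)$", location)] <- "global"
  lev[grepl("income", location, ignore.case = TRUE)] <- "income_group"
  lev[grepl("SDI", location)] <- "sdi_quintile"
  lev[grepl("^(World Bank|Region:)", location)] <- "region"
  lev
}

#' Read a GBD results-tool CSV export
#'
#' Reads a results-tool style CSV (columns `measure`, `location`, `sex`,
#' `age`, `cause`, `metric`, `year`, `val`/`value`, `upper`, `lower`),
#' normalizes labels to the canonical vocabulary, validates the table and
#' returns it in canonical long format.  Rows whose measure or metric is
#' not recognised are dropped with a single warning stating the count.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema_map Optional named character vector renaming input columns,
#'   e.g. `c(val = "value")` maps the export's `val` column onto `value`.
#'   The default already accepts both `val` and `value`.
#' @param measure_map Named character vector mapping measure labels to
#'   canonical measure names; defaults to [gbd_measure_map].
#' @return A data.frame in canonical long format with columns `location`,
#'   `location_level`, `year`, `sex`, `age`, `measure`, `metric`, `value`,
#'   `lower`, `upper`.  Rate values are interpreted as per 100,000.
#' @seealso [write_epi_csv()], [filter_observations()], [compute_ratios()]
#' @export
read_gbd_csv <- function(path, schema_map = NULL,
                         measure_map = gbd_measure_map) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, encoding = "UTF-8")

  if (!is.null(schema_map)) {
    hit <- match(names(raw), names(schema_map))
    names(raw)[!is.na(hit)] <- unname(schema_map[hit[!is.na(hit)]])
  }
  if (!"value" %in% names(raw) && "val" %in% names(raw)) {
    names(raw)[names(raw) == "val"] <- "value"
  }

  required <- c("location", "year", "sex", "age", "measure", "metric", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("schema error: required column(s) missing: ",
         paste(missing_cols, collapse = ", "))
  }
  for (opt in c("lower", "upper")) if (!opt %in% names(raw)) raw[[opt]] <- NA_real_

  # label normalization
  raw$measure <- unname(ifelse(raw$measure %in% names(measure_map),
                               measure_map[raw$measure], NA_character_))
  raw$metric <- unname(ifelse(raw$metric %in% names(metric_map),
                              metric_map[raw$metric], NA_character_))
  raw$sex <- unname(ifelse(raw$sex %in% names(sex_map),
                           sex_map[raw$sex], raw$sex))

  drop <- is.na(raw$measure) | is.na(raw$metric)
  if (any(drop)) {
    warning(sum(drop), " row(s) with unrecognised measure or metric dropped")
    raw <- raw[!drop, , drop = FALSE]
  }

  if (!"location_level" %in% names(raw)) {
    raw$location_level <- infer_location_level(raw$location)
  }
  raw$year <- as.integer(raw$year)

  out <- raw[epi_col_order]
  out <- out[order(out$location, out$year, out$sex, out$age,
                   out$measure, out$metric), , drop = FALSE]
  rownames(out) <- NULL
  validate_epi_table(out)
  out
}

#' Validate a canonical long-format burden table
#'
#' Checks the invariants of the canonical table: required columns present,
#' non-negative values, `lower <= value <= upper` where bounds are present,
#' unique `(location, year, sex, age, measure, metric)` keys, and canonical
#' measure/metric/sex vocabularies.
#'
#' @param table A data.frame as returned by [read_gbd_csv()].
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_epi_table <- function(table) {
  missing_cols <- setdiff(setdiff(epi_col_order, "location_level"), names(table))
  if (length(missing_cols)) {
    stop("schema error: required column(s) missing: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.na(table$value) & table$value < 0)
  if (length(bad)) {
    stop("validation error: negative value at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  has_bounds <- !is.na(table$lower) & !is.na(table$upper) & !is.na(table$value)
  viol <- which(has_bounds &
                  (table$lower > table$value | table$value > table$upper))
  if (length(viol)) {
    stop("validation error: value outside [lower, upper] at row(s) ",
         paste(utils::head(viol, 5L), collapse = ", "))
  }
  key <- do.call(paste, c(table[epi_key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("integrity error: duplicated (location, year, sex, age, measure, ",
         "metric) key, first at row ", which(duplicated(key))[1L])
  }
  bad_measure <- setdiff(unique(table$measure), canonical_measures)
  if (length(bad_measure)) {
    stop("validation error: non-canonical measure(s): ",
         paste(bad_measure, collapse = ", "))
  }
  invisible(table)
}

#' Write a canonical burden table to CSV
#'
#' Writes the fixed canonical column order so that a read/write cycle is
#' byte-stable.
#'
#' @param table Canonical table (see [read_gbd_csv()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_epi_csv <- function(table, path) {
  validate_epi_table(table)
  out <- table[epi_col_order]
  out <- out[order(out$location, out$year, out$sex, out$age,
                   out$measure, out$metric), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a burden table in the GHDx results-tool dialect
#'
#' Emits the verbose results-tool CSV dialect (columns `measure`,
#' `location`, `sex`, `age`, `cause`, `metric`, `year`, `val`, `upper`,
#' `lower` with verbose measure labels), the shape [read_gbd_csv()]
#' consumes.  Useful for exercising the full import path on generated data.
#'
#' @param table Canonical table.
#' @param path Output CSV path.
#' @param cause Cause label written to the `cause` column.
#' @return `path`, invisibly.
#' @export
write_gbd_csv <- function(table, path, cause = "Orofacial clefts") {
  validate_epi_table(table)
  verbose <- gbd_measure_map[1:6]  # verbose labels precede the short forms
  verbose_measure <- names(verbose)[match(table$measure, unname(verbose))]
  out <- data.frame(
    measure  = verbose_measure,
    location = table$location,
    sex      = c(male = "Male", female = "Female", both = "Both")[table$sex],
    age      = table$age,
    cause    = cause,
    metric   = c(number = "Number", rate = "Rate", percent = "Percent")[
      table$metric],
    year     = table$year,
    val      = table$value,
    upper    = table$upper,
    lower    = table$lower,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Subset a burden table by sex, age label, metric, years and level
#'
#' Selection helper used before ratio computation; typically the analysis
#' keeps age-standardized rates for 1990-2019.  Filters are applied only
#' when given; key uniqueness is preserved because output rows are a subset
#' of input rows.
#'
#' @param table Canonical table.
#' @param sexes Character vector of sexes to keep (`male`, `female`, `both`).
#' @param age_label Single age-group label to keep, e.g. `"Age-standardized"`.
#'   An error is raised if the label is absent from the table entirely.
#' @param metric Single metric to keep (`number`, `rate`, `percent`).
#' @param years Length-2 numeric `(from, to)` inclusive year range.
#' @param location_level Character vector of location levels to keep.
#' @return The filtered table.  An empty result is allowed (a message is
#'   emitted).
#' @export
filter_observations <- function(table, sexes = NULL, age_label = NULL,
                                metric = NULL, years = NULL,
                                location_level = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(age_label)) {
    if (!age_label %in% table$age) {
      stop("lookup error: age label '", age_label, "' not present in table")
    }
    keep <- keep & table$age == age_label
  }
  if (!is.null(sexes)) keep <- keep & table$sex %in% sexes
  if (!is.null(metric)) keep <- keep & table$metric %in% metric
  if (!is.null(years)) {
    keep <- keep & table$year >= years[1] & table$year <= years[2]
  }
  if (!is.null(location_level) && "location_level" %in% names(table)) {
    keep <- keep & table$location_level %in% location_level
  }
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L) message("filter_observations: empty result")
  rownames(out) <- NULL
  out
}

#' Age-standardize age-specific rates with a standard population
#'
#' Computes the weighted sum of age-specific rates under a fixed standard
#' population, `sum(weight_a * rate_a)`, the usual direct standardization.
#' Weights must cover every age group and sum to 1.
#'
#' @param rates Data.frame with columns `age_group` and `rate`
#'   (per 100,000).
#' @param std_pop Data.frame with columns `age_group` and `weight`
#'   (weights in `[0, 1]`, summing to 1 within 1e-9).
#' @return The age-standardized rate (per 100,000).
#' @export
age_standardize <- function(rates, std_pop) {
  stopifnot(all(c("age_group", "rate") %in% names(rates)),
            all(c("age_group", "weight") %in% names(std_pop)))
  if (abs(sum(std_pop$weight) - 1) > 1e-9) {
    stop("standard population weights must sum to 1")
  }
  idx <- match(rates$age_group, std_pop$age_group)
  if (anyNA(idx)) {
    stop("lookup error: no standard-population weight for age group(s): ",
         paste(rates$age_group[is.na(idx)], collapse = ", "))
  }
  sum(std_pop$weight[idx] * rates$rate)
}
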