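#' Gender disparity ratio band definitions
#'
#' The five GDR categories with their pinned boundary convention:
#' `[0, 0.5)`, `[0.5, 0.95)`, `[0.95, 1.05]`, `(1.05, 1.5]`, `(1.5, Inf)`.
#' The optimal band is closed on both ends so that a GDR of exactly 0.95
#' or 1.05 counts as optimal; the lower bands close on the left.
#'
#' @format Data.frame with columns `band`, `lower`, `upper`, `optimal`.
#' @export
gdr_bands <- data.frame(
  band = c("[0,0.5)", "[0.5,0.95)", "[0.95,1.05]", "(1.05,1.5]", "(1.5,Inf)"),
  lower = c(0, 0.5, 0.95, 1.05, 1.5),
  upper = c(0.5, 0.95, 1.05, 1.5, Inf),
  optimal = c(FALSE, FALSE, TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' Classify a gender disparity ratio into its categorical band
#'
#' Assigns each positive finite GDR to exactly one of the five bands (see
#' [gdr_bands]).  The assignment is exhaustive and mutually exclusive over
#' `(0, Inf)`.
#'
#' @param gdr Numeric vector of positive finite ratios.
#' @return Factor with the five band levels.
#' @examples
#' classify_gdr_band(c(0.3, 0.95, 1.0, 1.05, 1.6))
#' @export
classify_gdr_band <- function(gdr) {
  if (any(!is.finite(gdr) | gdr <= 0)) {
    stop("domain error: GDR must be positive and finite")
  }
  lab <- ifelse(gdr < 0.5, gdr_bands$band[1L],
         ifelse(gdr < 0.95, gdr_bands$band[2L],
         ifelse(gdr <= 1.05, gdr_bands$band[3L],
         ifelse(gdr <= 1.5, gdr_bands$band[4L], gdr_bands$band[5L]))))
  factor(lab, levels = gdr_bands$band)
}

#' Gender disparity ratio per location-year
#'
#' Computes the gender disparity ratio `gdr = qci_male / qci_female` for
#' every `(location, year)` with a male and a female QCI, together with its
#' categorical band.  A female QCI of exactly zero leaves the GDR undefined
#' (`NA`, with a message); a GDR of zero (male QCI 0 with positive female
#' QCI) gets an `NA` band since the bands are defined on positive ratios.
#'
#' @param x A fitted `"qci"` object or a data.frame of scores with columns
#'   `location`, `year`, `sex`, `qci`.
#' @return Data.frame with columns `location`, `year`, `qci_male`,
#'   `qci_female`, `gdr`, `band`.
#' @export
compute_gdr <- function(x) {
  sc <- if (inherits(x, "qci")) x$scores else as.data.frame(x)
  stopifnot(all(c("location", "year", "sex", "qci") %in% names(sc)))
  males <- sc[sc$sex == "male" & !is.na(sc$qci),
              c("location", "year", "qci")]
  females <- sc[sc$sex == "female" & !is.na(sc$qci),
                c("location", "year", "qci")]
  names(males)[3L] <- "qci_male"
  names(females)[3L] <- "qci_female"
  out <- merge(males, females, by = c("location", "year"))
  if (nrow(out) == 0L) {
    stop("no overlapping location-years with both male and female QCI")
  }
  out$gdr <- ifelse(out$qci_female > 0, out$qci_male / out$qci_female,
                    NA_real_)
  n_undef <- sum(is.na(out$gdr))
  if (n_undef) {
    message("compute_gdr: GDR undefined (female QCI = 0) for ", n_undef,
            " location-year(s)")
  }
  out$band <- factor(NA_character_, levels = gdr_bands$band)
  ok <- !is.na(out$gdr) & out$gdr > 0
  out$band[ok] <- classify_gdr_band(out$gdr[ok])
  out <- out[order(out$location, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count locations per GDR band in a given year
#'
#' @param gdr_table Output of [compute_gdr()].
#' @param year Calendar year present in the table.
#' @return Named integer vector over the five bands; counts partition the
#'   locations with a defined, banded GDR in that year.
#' @export
count_by_band <- function(gdr_table, year) {
  if (!year %in% gdr_table$year) stop("year ", year, " not present")
  sub <- gdr_table[gdr_table$year == year & !is.na(gdr_table$band), ,
                   drop = FALSE]
  table(sub$band)
}

#' Rank locations into QCI quintiles for a given year
#'
#' Rank-based quintile assignment: locations are sorted by QCI ascending
#' (ties broken alphabetically by location name, a stable, pinned rule)
#' and cut into five groups of near-equal size.  Quintile 5 holds the
#' highest QCIs.  When the location count is not divisible by five, the
#' extra members go to the extreme quintiles first, in the order 1, 5, 2,
#' 4, 3 (largest-remainder with pinned priority), so e.g. 7 locations give
#' group sizes 2, 1, 1, 1, 2.
#'
#' @param x A `"qci"` object or scores data.frame.
#' @param year Year to rank.
#' @param sex Sex series to rank (default `"both"`).
#' @return Data.frame with columns `location`, `qci`, `quintile`, sorted
#'   by ascending QCI.
#' @export
qci_quintiles <- function(x, year, sex = "both") {
  sc <- if (inherits(x, "qci")) x$scores else as.data.frame(x)
  sub <- sc[sc$year == year & sc$sex == sex & !is.na(sc$qci), , drop = FALSE]
  n <- nrow(sub)
  if (n < 5L) {
    stop("insufficient data: need at least 5 locations with a QCI in ",
         year, "/", sex, ", got ", n)
  }
  ord <- order(sub$qci, sub$location)
  sub <- sub[ord, , drop = FALSE]
  sizes <- rep(n %/% 5L, 5L)
  rem <- n %% 5L
  if (rem > 0L) {
    priority <- c(1L, 5L, 2L, 4L, 3L)[seq_len(rem)]
    sizes[priority] <- sizes[priority] + 1L
  }
  out <- data.frame(location = sub$location, qci = sub$qci,
                    quintile = rep.int(1:5, sizes),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarise QCI by location grouping (income groups, SDI quintiles, ...)
#'
#' For each group in a grouping scheme, reports the group's QCI either from
#' a group-level aggregate observation (a row of the fitted scores whose
#' location is the group label itself, as GBD publishes for income groups
#' and SDI quintiles) or, as a fallback, the unweighted mean of the member
#' locations' QCIs.  Group-level rows are preferred because unweighted
#' member means ignore population size; the `source` column records which
#' mode produced each value.
#'
#' @param x A `"qci"` object or scores data.frame.
#' @param scheme Data.frame with columns `location` and `group` mapping
#'   member locations to group labels.
#' @param year Year to summarise.
#' @param sex Sex series (default `"both"`).
#' @param mode `"auto"` (group-level row when present, else member mean),
#'   `"group_rows"` (group-level rows only), or `"member_mean"`.
#' @return Data.frame with columns `group`, `qci`, `n_members`, `source`.
#'   Groups with neither a group-level row nor any scored member are
#'   omitted with a warning.
#' @export
group_summary <- function(x, scheme, year, sex = "both",
                          mode = c("auto", "group_rows", "member_mean")) {
  mode <- match.arg(mode)
  sc <- if (inherits(x, "qci")) x$scores else as.data.frame(x)
  stopifnot(all(c("location", "group") %in% names(scheme)))
  if (anyDuplicated(scheme$location)) {
    stop("scheme maps some location to more than one group")
  }
  sub <- sc[sc$year == year & sc$sex == sex & !is.na(sc$qci), , drop = FALSE]
  groups <- unique(scheme$group)
  res <- lapply(groups, function(g) {
    members <- scheme$location[scheme$group == g]
    grow <- sub[sub$location == g, , drop = FALSE]
    mem <- sub[sub$location %in% members, , drop = FALSE]
    use_group <- nrow(grow) > 0L && mode != "member_mean"
    if (use_group) {
      data.frame(group = g, qci = grow$qci[1L],
                 n_members = length(members), source = "group_row",
                 stringsAsFactors = FALSE)
    } else if (nrow(mem) > 0L && mode != "group_rows") {
      data.frame(group = g, qci = mean(mem$qci),
                 n_members = nrow(mem), source = "member_mean",
                 stringsAsFactors = FALSE)
    } else {
      warning("group '", g, "' has no usable QCI in ", year, "; omitted")
      NULL
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Signed change between two years
#'
#' The change statistic used in period summaries: end-of-period value minus
#' start-of-period value, `change = value_b - value_a` with `(a, b) =
#' (1990, 2019)` in the canonical comparison, so declining burden rates
#' give negative changes and improving QCIs positive ones.  Vectorised;
#' missing endpoints give `NA`.
#'
#' @param value_a Value at the start year.
#' @param value_b Value at the end year.
#' @return `value_b - value_a`.
#' @examples
#' change_between(19.63, 7.51)   # -12.12
#' change_between(66.36, 90.20)  # 23.84
#' @export
change_between <- function(value_a, value_b) {
  value_b - value_a
}
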