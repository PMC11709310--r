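#' Compute the four care-quality ratios per (location, year, sex)
#'
#' Pivots a canonical long-format burden table to one row per observation
#' unit and computes the four dimensionless ratios that feed the QCI:
#'
#' * `r_pi` — prevalence / incidence (disease-pool persistence; direction
#'   ambiguous on its own),
#' * `r_mi` — deaths / incidence (case fatality proxy; lower is better),
#' * `r_dp` — DALYs / prevalence (burden per prevalent case; lower is
#'   better),
#' * `r_ly` — YLLs / YLDs (mortality share of burden; lower is better).
#'
#' The input should already be filtered to a single metric and age label
#' (see [filter_observations()]); ratios of age-standardized rates are the
#' intended default.  Division by zero and missing measures yield
#' non-finite entries and `complete = FALSE`; no epsilon padding or
#' imputation is performed.  Missing DALYs are reconstructed as
#' `YLLs + YLDs` (the defining identity) when both parts are present, with
#' a message stating the count.
#'
#' @param table Canonical burden table (see [read_gbd_csv()]).
#' @param reconstruct_dalys Reconstruct missing DALYs as YLLs + YLDs?
#' @return Data.frame with one row per distinct `(location, year, sex)` in
#'   the input and columns `location`, `year`, `sex`, `r_pi`, `r_mi`,
#'   `r_dp`, `r_ly`, `complete`.
#' @export
compute_ratios <- function(table, reconstruct_dalys = TRUE) {
  stopifnot(all(c("location", "year", "sex", "measure", "value") %in%
                  names(table)))
  if (length(unique(table$metric)) > 1L) {
    stop("table mixes metrics; filter to a single metric first")
  }
  if ("age" %in% names(table) && length(unique(table$age)) > 1L) {
    stop("table mixes age labels; filter to a single age label first")
  }

  units <- unique(table[c("location", "year", "sex")])
  wide <- units
  for (m in canonical_measures) {
    sub <- table[table$measure == m, c("location", "year", "sex", "value")]
    names(sub)[4L] <- m
    wide <- merge(wide, sub, by = c("location", "year", "sex"),
                  all.x = TRUE, sort = FALSE)
  }
  wide <- wide[order(wide$location, wide$year, wide$sex), , drop = FALSE]

  if (reconstruct_dalys) {
    fix <- is.na(wide$DALYs) & !is.na(wide$YLLs) & !is.na(wide$YLDs)
    if (any(fix)) {
      wide$DALYs[fix] <- wide$YLLs[fix] + wide$YLDs[fix]
      message("compute_ratios: DALYs reconstructed as YLLs + YLDs for ",
              sum(fix), " unit(s)")
    }
  }

  out <- data.frame(
    location = wide$location,
    year     = wide$year,
    sex      = wide$sex,
    r_pi     = wide$prevalence / wide$incidence,
    r_mi     = wide$deaths / wide$incidence,
    r_dp     = wide$DALYs / wide$prevalence,
    r_ly     = wide$YLLs / wide$YLDs,
    stringsAsFactors = FALSE
  )
  out$complete <- is.finite(out$r_pi) & is.finite(out$r_mi) &
    is.finite(out$r_dp) & is.finite(out$r_ly)
  if (!any(out$complete)) {
    stop("no usable observations: every (location, year, sex) unit has a ",
         "missing measure or zero denominator")
  }
  rownames(out) <- NULL
  out
}
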