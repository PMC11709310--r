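#' Configuration for the synthetic burden-data generator
#'
#' Assembles and validates the parameters of the latent care-quality model
#' behind [simulate_gbd()].  Defaults describe a 100-country, 1990-2019
#' panel of a congenital, low-lethality condition with moderate estimation
#' noise; all structural constants are exposed here so tests can pin or
#' perturb them.
#'
#' @param n_locations Number of countries (>= 5).
#' @param years Integer vector of calendar years.
#' @param seed Integer seed; the generator draws from R's default
#'   Mersenne-Twister stream seeded once with this value.
#' @param quality_range Interval within `[0, 1]` from which each country's
#'   baseline latent quality `q0` is drawn uniformly.
#' @param sex_offset_sd SD of the additive Normal offset applied to each
#'   (location, sex) latent quality before clamping; 0 gives perfectly
#'   symmetric sexes.
#' @param trend_per_year Annual additive drift in latent quality; the
#'   latent value is clamped to `[0, 1]`.
#' @param base_incidence_rate Structural incidence rate per 100,000.
#' @param noise_cv Coefficient of variation of the independent
#'   multiplicative lognormal noise applied to each measure (must be < 1).
#' @param m_max Mortality-to-incidence fraction at the worst quality
#'   (`q = 0`); deaths = `m_max * (1 - q) * incidence`.
#' @param duration_base,duration_slope Mean disease duration in years is
#'   `duration_base + duration_slope * q` (better care keeps patients
#'   alive longer), so prevalence = incidence x duration.
#' @param disability_weight Disability weight applied to prevalence to
#'   produce YLDs.
#' @param life_exp_base,life_exp_slope Residual life expectancy at death is
#'   `life_exp_base - life_exp_slope * q` (deaths under good care occur
#'   later), so YLLs = deaths x residual life expectancy.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_locations = 100L,
                             years = 1990:2019,
                             seed = 1L,
                             quality_range = c(0.1, 0.9),
                             sex_offset_sd = 0.05,
                             trend_per_year = 0.005,
                             base_incidence_rate = 20,
                             noise_cv = 0.1,
                             m_max = 0.2,
                             duration_base = 20,
                             duration_slope = 40,
                             disability_weight = 0.05,
                             life_exp_base = 60,
                             life_exp_slope = 20) {
  cfg <- list(n_locations = as.integer(n_locations),
              years = as.integer(years), seed = as.integer(seed),
              quality_range = as.numeric(quality_range),
              sex_offset_sd = sex_offset_sd,
              trend_per_year = trend_per_year,
              base_incidence_rate = base_incidence_rate,
              noise_cv = noise_cv, m_max = m_max,
              duration_base = duration_base,
              duration_slope = duration_slope,
              disability_weight = disability_weight,
              life_exp_base = life_exp_base,
              life_exp_slope = life_exp_slope)
  problems <- character(0)
  if (cfg$n_locations < 5L) problems <- c(problems, "n_locations must be >= 5")
  if (length(cfg$years) < 1L) problems <- c(problems, "years must be non-empty")
  if (length(cfg$quality_range) != 2L ||
      cfg$quality_range[1] < 0 || cfg$quality_range[2] > 1 ||
      cfg$quality_range[1] > cfg$quality_range[2]) {
    problems <- c(problems, "quality_range must be an ordered interval in [0,1]")
  }
  if (cfg$sex_offset_sd < 0) problems <- c(problems, "sex_offset_sd must be >= 0")
  if (cfg$noise_cv < 0 || cfg$noise_cv >= 1) {
    problems <- c(problems, "noise_cv must be in [0, 1)")
  }
  if (cfg$base_incidence_rate <= 0) {
    problems <- c(problems, "base_incidence_rate must be positive")
  }
  if (length(problems)) {
    stop("invalid synthetic config: ", paste(problems, collapse = "; "))
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a GBD-shaped burden table from a latent care-quality model
#'
#' Simulates the canonical long-format table consumed by the pipeline,
#' together with the latent truth that generated it, so every downstream
#' stage can be tested for parameter recovery.
#'
#' Per (location, year, sex in male/female) the latent care quality is
#' `q = clamp(q0_location + trend_per_year * (year - start) + offset, 0, 1)`
#' with `q0` uniform over `quality_range` and `offset ~ N(0,
#' sex_offset_sd)` per (location, sex).  Structural age-standardized rates
#' per 100,000 follow the four ratio semantics:
#' incidence `I = base_incidence_rate`; deaths `D = m_max (1 - q) I`;
#' prevalence `P = I (duration_base + duration_slope q)`;
#' `YLD = P * disability_weight`; `YLL = D (life_exp_base - life_exp_slope
#' q)`.  Each of the five measures then receives independent multiplicative
#' lognormal noise with mean 1 and coefficient of variation `noise_cv`,
#' and DALYs are formed as the exact sum `YLL + YLD` of the noisy parts,
#' so the DALY identity holds exactly at any noise level.  Both-sex rows
#' are the male/female average of each measure (truth: the average latent
#' quality).
#'
#' Output is deterministic given `config$seed` (single seeded
#' Mersenne-Twister stream, fixed draw order).
#'
#' @param config A [synthetic_config()] object (defaults used if omitted).
#' @return List with `epi` (canonical burden table: one `rate` row per
#'   location, year, sex and measure, age label `"Age-standardized"`) and
#'   `truth` (data.frame `location`, `year`, `sex`, `q`).
#' @examples
#' sim <- simulate_gbd(synthetic_config(n_locations = 5, years = 1990:1992))
#' head(sim$epi)
#' @export
simulate_gbd <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  set.seed(config$seed)
  locs <- sprintf("country_%03d", seq_len(config$n_locations))
  q0 <- stats::runif(config$n_locations,
                     config$quality_range[1], config$quality_range[2])
  offsets <- matrix(
    if (config$sex_offset_sd > 0)
      stats::rnorm(2L * config$n_locations, 0, config$sex_offset_sd)
    else 0,
    nrow = config$n_locations, ncol = 2L,
    dimnames = list(locs, c("male", "female")))

  grid <- expand.grid(sex = c("male", "female"), year = config$years,
                      location = locs, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[c("location", "year", "sex")]
  li <- match(grid$location, locs)
  q <- clamp(q0[li] +
               config$trend_per_year * (grid$year - min(config$years)) +
               offsets[cbind(li, match(grid$sex, c("male", "female")))],
             0, 1)

  n <- nrow(grid)
  I0 <- rep(config$base_incidence_rate, n)
  D0 <- config$m_max * (1 - q) * I0
  P0 <- I0 * (config$duration_base + config$duration_slope * q)
  YLD0 <- P0 * config$disability_weight
  YLL0 <- D0 * (config$life_exp_base - config$life_exp_slope * q)

  noise <- matrix(lnorm_noise(5L * n, config$noise_cv), nrow = n, ncol = 5L)
  vals <- cbind(incidence = I0 * noise[, 1L],
                deaths = D0 * noise[, 2L],
                prevalence = P0 * noise[, 3L],
                YLDs = YLD0 * noise[, 4L],
                YLLs = YLL0 * noise[, 5L])
  vals <- cbind(vals, DALYs = vals[, "YLLs"] + vals[, "YLDs"])

  # both-sex rows: average the male/female measures, unit by unit
  is_m <- grid$sex == "male"
  both_vals <- (vals[is_m, , drop = FALSE] + vals[!is_m, , drop = FALSE]) / 2
  # re-derive the DALY sum so the identity stays exact in floating point
  both_vals[, "DALYs"] <- both_vals[, "YLLs"] + both_vals[, "YLDs"]
  both_grid <- grid[is_m, , drop = FALSE]
  both_grid$sex <- "both"
  q_both <- (q[is_m] + q[!is_m]) / 2

  all_grid <- rbind(grid, both_grid)
  all_vals <- rbind(vals, both_vals)
  all_q <- c(q, q_both)

  measures <- colnames(all_vals)
  epi <- data.frame(
    location = rep(all_grid$location, times = length(measures)),
    location_level = "country",
    year = rep(all_grid$year, times = length(measures)),
    sex = rep(all_grid$sex, times = length(measures)),
    age = "Age-standardized",
    measure = rep(measures, each = nrow(all_grid)),
    metric = "rate",
    value = as.vector(all_vals),
    stringsAsFactors = FALSE
  )
  epi$lower <- epi$value * 0.85
  epi$upper <- epi$value * 1.15
  epi <- epi[order(epi$location, epi$year, epi$sex, epi$measure), ,
             drop = FALSE]
  rownames(epi) <- NULL

  truth <- data.frame(location = all_grid$location, year = all_grid$year,
                      sex = all_grid$sex, q = all_q,
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$location, truth$year, truth$sex), , drop = FALSE]
  rownames(truth) <- NULL

  list(epi = epi, truth = truth)
}

#' Delete a fraction of measure cells at random
#'
#' Removes rows (measure cells) of a canonical burden table uniformly at
#' random, deterministically per seed.  Used to exercise the pipeline's
#' exclusion-not-imputation rule for incomplete observation units.
#'
#' @param table Canonical burden table.
#' @param fraction Fraction of rows to delete, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The table with `round(fraction * nrow)` rows removed
#'   (`fraction = 0` returns the table unchanged).
#' @export
inject_missingness <- function(table, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (fraction == 0) return(table)
  set.seed(seed)
  n_drop <- round(fraction * nrow(table))
  drop_idx <- sample.int(nrow(table), n_drop)
  out <- table[-drop_idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
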