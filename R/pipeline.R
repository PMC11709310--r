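#' Run the full QCI pipeline and write its artifact set
#'
#' Chains the stages — import (or simulate), filter, ratio computation,
#' QCI fit, gender disparity ratios, quintiles, change statistics, group
#' summaries and validation — and writes every tabular artifact as CSV
#' plus the model, validation and manifest JSONs to an output directory.
#' Identical configuration and inputs produce identical artifacts (the
#' manifest records md5 checksums, the echoed configuration and versions;
#' no timestamps).
#'
#' @param config A named list, or path to a YAML file holding one.
#'   Recognised fields (all optional):
#'   * `input`: path to a GBD results-tool CSV; when absent, data are
#'     simulated with [simulate_gbd()];
#'   * `sim`: list of [synthetic_config()] overrides for simulated input;
#'   * `grouping`: path to a CSV with columns `location`, `group`;
#'   * `reference`: path to a CSV with columns `location`, `year`,
#'     `reference_index` (plus covariate columns for the mixed model);
#'   * `out_dir`: output directory (default `"qci_output"`);
#'   * `age_label` (`"Age-standardized"`), `metric` (`"rate"`),
#'     `sexes` (`male`, `female`, `both`), `years` (`c(1990, 2019)`,
#'     must be ordered), `quintile_year` (default: last year),
#'     `seed` (default 1), `verbose` (default `TRUE`).
#' @param out_dir Overrides `config$out_dir` when given.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(input = NULL, sim = list(), grouping = NULL,
                   reference = NULL, out_dir = "qci_output",
                   age_label = "Age-standardized", metric = "rate",
                   sexes = c("male", "female", "both"),
                   years = c(1990, 2019), quintile_year = NULL,
                   seed = 1L, verbose = TRUE)
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir

  log_msg <- function(...) if (isTRUE(cfg$verbose)) message("[qcindex] ", ...)
  written <- character(0)
  stage <- "configuration"
  on_error <- function(e) {
    unlink(written)  # no partial artifact sets
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }

  tryCatch({
    cfg$years <- as.numeric(cfg$years)
    if (length(cfg$years) != 2L || cfg$years[1] > cfg$years[2]) {
      stop("years must be an ordered (from, to) pair")
    }
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- function(f) file.path(cfg$out_dir, f)

    stage <- "input"
    if (is.null(cfg$input)) {
      log_msg("no input CSV; simulating (seed ", cfg$seed, ")")
      sim_cfg <- do.call(synthetic_config,
                         utils::modifyList(list(seed = cfg$seed), cfg$sim))
      sim <- simulate_gbd(sim_cfg)
      epi <- sim$epi
      utils::write.csv(sim$truth, paths("truth.csv"), row.names = FALSE)
      written <- c(written, paths("truth.csv"))
    } else {
      log_msg("reading ", cfg$input)
      epi <- read_gbd_csv(cfg$input)
    }

    stage <- "filter"
    epi <- filter_observations(epi, sexes = cfg$sexes,
                               age_label = cfg$age_label,
                               metric = cfg$metric, years = cfg$years)

    stage <- "ratios"
    ratios <- compute_ratios(epi)
    utils::write.csv(ratios, paths("ratios.csv"), row.names = FALSE)
    written <- c(written, paths("ratios.csv"))
    log_msg(nrow(ratios), " observation units; ",
            sum(ratios$complete), " complete")

    stage <- "qci"
    fit <- qci(ratios)
    utils::write.csv(fit$scores, paths("qci.csv"), row.names = FALSE)
    write_qci_model(fit, paths("model.json"))
    written <- c(written, paths("qci.csv"), paths("model.json"))

    stage <- "gdr"
    if (all(c("male", "female") %in% cfg$sexes)) {
      gdr <- compute_gdr(fit)
      utils::write.csv(gdr, paths("gdr.csv"), row.names = FALSE)
      written <- c(written, paths("gdr.csv"))
    } else {
      stop("gender disparity ratios need both 'male' and 'female' in the ",
           "sexes filter")
    }

    stage <- "quintiles"
    qyear <- cfg$quintile_year %||% max(fit$scores$year)
    quint <- qci_quintiles(fit, year = qyear,
                           sex = if ("both" %in% cfg$sexes) "both" else
                             cfg$sexes[1])
    utils::write.csv(quint, paths("quintiles.csv"), row.names = FALSE)
    written <- c(written, paths("quintiles.csv"))

    stage <- "changes"
    sc <- fit$scores
    a <- sc[sc$year == min(sc$year), c("location", "sex", "qci")]
    b <- sc[sc$year == max(sc$year), c("location", "sex", "qci")]
    names(a)[3L] <- "qci_start"
    names(b)[3L] <- "qci_end"
    changes <- merge(a, b, by = c("location", "sex"))
    changes$change <- change_between(changes$qci_start, changes$qci_end)
    changes <- changes[order(changes$location, changes$sex), , drop = FALSE]
    utils::write.csv(changes, paths("changes.csv"), row.names = FALSE)
    written <- c(written, paths("changes.csv"))

    stage <- "groups"
    if (!is.null(cfg$grouping)) {
      scheme <- utils::read.csv(cfg$grouping, stringsAsFactors = FALSE)
      groups <- group_summary(fit, scheme, year = qyear)
      utils::write.csv(groups, paths("groups.csv"), row.names = FALSE)
      written <- c(written, paths("groups.csv"))
    }

    stage <- "validation"
    if (!is.null(cfg$reference)) {
      panel <- utils::read.csv(cfg$reference, stringsAsFactors = FALSE)
      corr <- correlate_with_reference(fit, panel)
      covars <- setdiff(names(panel), c("location", "year",
                                        "reference_index"))
      val <- list(pearson_r = corr$r, n = corr$n)
      if (length(covars)) {
        merged <- merge(fit$scores[fit$scores$sex == "both", ], panel,
                        by = c("location", "year"))
        fml <- stats::reformulate(covars, response = "qci")
        mm <- fit_random_intercept(fml, merged, group = "location")
        val$mixed_model <- list(
          coefficients = as.list(mm$coefficients),
          sigma_intercept = unname(mm$sigma["intercept"]),
          sigma_residual = unname(mm$sigma["residual"]),
          n_groups = mm$n_groups)
      }
      jsonlite::write_json(val, paths("validation.json"),
                           auto_unbox = TRUE, digits = NA)
      written <- c(written, paths("validation.json"))
    }

    stage <- "manifest"
    inputs <- Filter(Negate(is.null),
                     list(input = cfg$input, grouping = cfg$grouping,
                          reference = cfg$reference))
    manifest <- list(
      package = "qcindex",
      package_version = as.character(utils::packageVersion("qcindex")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      config = cfg[setdiff(names(cfg), "verbose")],
      input_md5 = if (length(inputs))
        as.list(tools::md5sum(unlist(inputs))) else
          list(synthetic_seed = cfg$seed),
      artifact_md5 = as.list(tools::md5sum(sort(written)))
    )
    jsonlite::write_json(manifest, paths("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, paths("manifest.json"))
    log_msg("wrote ", length(written), " artifacts to ", cfg$out_dir)
    invisible(stats::setNames(as.list(written), basename(written)))
  }, error = on_error)
}
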