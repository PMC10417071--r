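#' Pipeline configuration
#'
#' Assembles everything [run_pipeline()] needs: the study configuration
#' file (arm profiles, Markov and CEA sections), the master seed, which
#' stages to run, where to write results, and an optional pre-existing
#' cohort CSV for runs that skip generation.
#'
#' @param out_dir directory for stage outputs (created if missing).
#' @param seed master seed for all stochastic stages.
#' @param stages named logical vector enabling the stages `generate`,
#'   `analyze`, `match`, `markov`, `cea`.
#' @param config_path YAML/JSON study configuration (defaults to the
#'   packaged three-arm configuration).
#' @param cohort_csv path to an existing cohort CSV, used when `generate`
#'   is disabled but a downstream stage needs patient-level data.
#' @param psa_draws override of the configured number of PSA draws
#'   (`NULL` keeps the configured value).
#' @param censor_horizon administrative censoring horizon in years.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("nutricea_"), seed = 20180515,
                            stages = c(generate = TRUE, analyze = TRUE,
                                       match = TRUE, markov = TRUE,
                                       cea = TRUE),
                            config_path = NULL, cohort_csv = NULL,
                            psa_draws = NULL, censor_horizon = 3) {
  all_stages <- c("generate", "analyze", "match", "markov", "cea")
  st <- stats::setNames(rep(TRUE, 5), all_stages)
  assert_that(!is.null(names(stages)) && all(names(stages) %in% all_stages),
              "stages must be named among: ", paste(all_stages, collapse = ", "))
  st[names(stages)] <- stages
  assert_that(is.numeric(seed) && length(seed) == 1,
              "a single numeric seed is required")
  structure(class = "pipeline_config", list(
    out_dir = out_dir, seed = seed, stages = st,
    config_path = config_path %||% default_config_path(),
    cohort_csv = cohort_csv, psa_draws = psa_draws,
    censor_horizon = censor_horizon))
}

#' @rdname pipeline_config
#' @param path YAML/JSON file with a `pipeline` section carrying any of
#'   the [pipeline_config()] fields; remaining sections (arms, markov,
#'   cea) are used as the study configuration.
#' @export
read_pipeline_config <- function(path) {
  cfg <- read_config_file(path)
  pl <- cfg$pipeline %||% list()
  stages <- unlist(pl$stages) %||% c(generate = TRUE)
  pipeline_config(
    out_dir = pl$out_dir %||% tempfile("nutricea_"),
    seed = pl$seed %||% cfg$seed %||% 20180515,
    stages = stages,
    config_path = path,
    cohort_csv = pl$cohort_csv,
    psa_draws = pl$psa_draws,
    censor_horizon = pl$censor_horizon %||% 3)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — cohort generation, trial
#' analysis, propensity matching, Markov modelling, cost-effectiveness
#' analysis — writing each stage's outputs under `config$out_dir`
#' (cohort CSV, summary CSVs, JSON bundles) and returning a consolidated
#' report that embeds the seed and configuration needed to regenerate it.
#' A downstream stage whose inputs are unavailable (e.g. `analyze` with
#' generation disabled and no `cohort_csv`) raises a dependency error.
#'
#' @param config a [pipeline_config()].
#' @return the report, an object of class `pipeline_report` (also written
#'   to `report.json` in `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  study <- read_config_file(config$config_path)
  profiles <- read_arm_profiles(config$config_path)
  st <- config$stages
  report <- list(
    package = "nutricea",
    version = as.character(utils::packageVersion("nutricea")),
    seed = config$seed,
    config_path = config$config_path,
    stages = as.list(st),
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  cohort <- NULL
  need_cohort <- st[["analyze"]] || st[["match"]]
  if (st[["generate"]]) {
    cohort <- generate_trial(profiles, config$seed, config$censor_horizon)
    write_cohort(cohort, out("cohort.csv"))
    report$generate <- list(n = nrow(cohort),
                            arms = as.list(table(cohort$arm_label)),
                            cohort_csv = out("cohort.csv"))
  } else if (need_cohort) {
    assert_that(!is.null(config$cohort_csv),
                "stage dependency error: analyze/match need a cohort but ",
                "generation is disabled and no cohort_csv was provided")
    cohort <- read_cohort(config$cohort_csv)
  }

  if (st[["analyze"]]) {
    summ <- nutrition_summary(cohort)
    utils::write.csv(summ, out("nutrition_summary.csv"), row.names = FALSE)
    tests <- list(
      weight_category = compare_groups(cohort, "weight_category", "categorical"),
      weight_change_pct = compare_groups(cohort, "weight_change_pct", "continuous"),
      response = compare_groups(cohort, "response", "categorical"),
      albumin_ge35 = compare_groups(cohort, "albumin_ge35", "categorical"))
    km1 <- lapply(split(cohort, cohort$arm_label), function(g) {
      lr <- km_estimate(g$lrfs_time, g$lrfs_event)
      os <- km_estimate(g$os_time, g$os_event)
      list(lrfs_1yr = survival_at(lr, 1), os_1yr = survival_at(os, 1))
    })
    report$analyze <- list(
      summary_csv = out("nutrition_summary.csv"),
      group_tests = lapply(tests, unclass),
      km_1yr = km1)
  }

  if (st[["match"]]) {
    mc <- match_config(reference_arm = profiles[[1]]$arm_label)
    ps <- fit_multinomial_ps(cohort, mc$covariates, mc$reference_arm)
    mr <- match_triplets(cohort, ps, mc)
    bal <- balance_table(cohort, mr, mc$covariates)
    utils::write.csv(bal, out("balance.csv"), row.names = FALSE)
    match_out <- list(
      n_triplets = nrow(mr$triplets), n_unmatched = mr$n_unmatched,
      caliper = mr$caliper, logit_sd = mr$logit_sd,
      triplets = mr$triplets)
    jsonlite::write_json(match_out, out("match.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    report$match <- match_out[c("n_triplets", "n_unmatched", "caliper",
                                "logit_sd")]
  }

  markov_results <- NULL
  if (st[["markov"]]) {
    specs <- default_markov_specs(config$config_path)
    markov_results <- lapply(specs, run_markov)
    for (lab in names(markov_results)) {
      r <- markov_results[[lab]]
      trace <- data.frame(cycle = as.numeric(rownames(r$occupancy)),
                          r$occupancy,
                          discounted_cost = c(r$discounted_cost_per_cycle, NA),
                          discounted_qaly = c(r$discounted_qaly_per_cycle, NA))
      utils::write.csv(trace, out(paste0("trace_", lab, ".csv")),
                       row.names = FALSE)
    }
    strat <- strategy_table(markov_results)
    jsonlite::write_json(strat, out("strategies.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    report$markov <- list(strategies = strat)
  }

  if (st[["cea"]]) {
    assert_that(!is.null(markov_results),
                "stage dependency error: cea requires the markov stage")
    cc <- study$cea %||% list()
    cfg_cea <- cea_config(
      wtp_grid = unlist(cc$wtp_grid) %||% seq(0, 50000, 5000),
      headline_thresholds = unlist(cc$headline_thresholds) %||% c(10000, 50000),
      cost_effective_threshold = cc$cost_effective_threshold %||% 33962,
      psa_draws = config$psa_draws %||% cc$psa_draws %||% 10000,
      seed = config$seed,
      usd_per_cny = cc$usd_per_cny %||% 6.37)
    fr <- icer_frontier(markov_results)
    nmb <- sapply(cfg_cea$wtp_grid, function(w)
      net_monetary_benefit(markov_results, w))
    colnames(nmb) <- cfg_cea$wtp_grid
    specs <- default_markov_specs(config$config_path)
    psa <- run_psa(specs, default_psa_distributions(specs), cfg_cea)
    acc <- acceptability_report(psa, cfg_cea)
    utils::write.csv(data.frame(wtp = psa$wtp_grid, psa$ceac,
                                check.names = FALSE),
                     out("ceac.csv"), row.names = FALSE)
    utils::write.csv(psa$draws, out("psa_draws.csv"), row.names = FALSE)
    jsonlite::write_json(fr$table, out("frontier.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    report$cea <- list(
      frontier = fr$table,
      nmb = as.data.frame(nmb),
      acceptability = as.data.frame(acc$table),
      preferred_at_threshold = acc$preferred,
      threshold = acc$threshold,
      psa_draws = cfg_cea$psa_draws,
      psa_clamped = psa$n_clamped)
  }

  class(report) <- "pipeline_report"
  jsonlite::write_json(unclass(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("nutricea pipeline report (seed", x$seed, ")\n")
  on <- names(Filter(isTRUE, x$stages))
  cat("  stages:", paste(on, collapse = ", "), "\n")
  if (!is.null(x$generate))
    cat("  cohort:", x$generate$n, "subjects\n")
  if (!is.null(x$match))
    cat("  match:", x$match$n_triplets, "triplets,",
        x$match$n_unmatched, "unmatched\n")
  if (!is.null(x$cea)) {
    cat("  frontier:\n")
    print(x$cea$frontier[, c("label", "cost", "qaly", "on_frontier", "icer")],
          row.names = FALSE)
    cat("  preferred at $", format(x$cea$threshold, big.mark = ","),
        "/QALY: ", x$cea$preferred_at_threshold, "\n", sep = "")
  }
  invisible(x)
}
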