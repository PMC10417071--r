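#' Cost-effectiveness analysis configuration
#'
#' Willingness-to-pay grid, headline thresholds, the cost-effectiveness
#' threshold used for the headline verdict (three times 2020 GDP per
#' capita in China, $33,962/QALY, by default), the number of probabilistic
#' sensitivity-analysis draws and the PSA seed.
#'
#' @param wtp_grid sorted non-negative willingness-to-pay grid (USD/QALY).
#' @param headline_thresholds thresholds reported in the acceptability
#'   summary.
#' @param cost_effective_threshold threshold deciding the preferred
#'   strategy.
#' @param psa_draws number of Monte Carlo draws.
#' @param seed PSA seed.
#' @param usd_per_cny exchange rate used when costs are converted from
#'   CNY (stored for reporting; all shipped costs are already USD).
#' @return object of class `cea_config`.
#' @export
cea_config <- function(wtp_grid = seq(0, 50000, by = 5000),
                       headline_thresholds = c(10000, 50000),
                       cost_effective_threshold = 33962,
                       psa_draws = 10000, seed = 1, usd_per_cny = 6.37) {
  assert_that(!is.unsorted(wtp_grid) && all(wtp_grid >= 0),
              "wtp_grid must be sorted and non-negative")
  assert_that(psa_draws >= 1, "psa_draws must be positive")
  assert_that(all(headline_thresholds >= min(wtp_grid)) &&
                all(headline_thresholds <= max(wtp_grid)),
              "headline thresholds must lie inside the wtp grid")
  structure(class = "cea_config", list(
    wtp_grid = wtp_grid, headline_thresholds = headline_thresholds,
    cost_effective_threshold = cost_effective_threshold,
    psa_draws = as.integer(psa_draws), seed = seed,
    usd_per_cny = usd_per_cny))
}

#' Declare the sampling distribution of one model parameter
#'
#' Distributions are parameterised by the base-case mean and a relative
#' SD via method of moments: `beta` for probabilities and utilities
#' (default relative SD 10\%), `gamma` for costs (default 30\%), `fixed`
#' for parameters held at the mean. Beta requires a mean in (0, 1) and a
#' variance below `mean (1 - mean)`.
#'
#' @param path parameter path into the strategy specifications (see
#'   [one_way_sensitivity()] for the syntax).
#' @param family `"beta"`, `"gamma"` or `"fixed"`.
#' @param mean base-case value.
#' @param rel_sd relative standard deviation (SD / mean).
#' @return object of class `param_distribution` with a `sample(n)` closure.
#' @export
param_distribution <- function(path, family = c("beta", "gamma", "fixed"),
                               mean, rel_sd = NULL) {
  family <- match.arg(family)
  parse_param_path(path)  # syntax check
  assert_that(is.finite(mean), "mean must be finite")
  rel_sd <- rel_sd %||% switch(family, beta = 0.10, gamma = 0.30, fixed = 0)
  pars <- NULL
  if (family == "beta") {
    assert_that(mean > 0 && mean < 1, "beta requires mean in (0, 1)")
    v <- (mean * rel_sd)^2
    assert_that(v < mean * (1 - mean),
                "beta variance too large for mean ", mean)
    nu <- mean * (1 - mean) / v - 1
    pars <- c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
  } else if (family == "gamma") {
    assert_that(mean > 0, "gamma requires mean > 0")
    assert_that(rel_sd > 0, "gamma requires rel_sd > 0")
    pars <- c(shape = 1 / rel_sd^2, rate = 1 / (rel_sd^2 * mean))
  }
  structure(class = "param_distribution",
            list(path = path, family = family, mean = mean,
                 rel_sd = rel_sd, pars = pars))
}

sample_param <- function(dist, n = 1) {
  switch(dist$family,
         fixed = rep(dist$mean, n),
         beta = rbeta(n, dist$pars["shape1"], dist$pars["shape2"]),
         gamma = rgamma(n, shape = dist$pars["shape"], rate = dist$pars["rate"]))
}

#' Default PSA parameter distributions for a set of strategies
#'
#' Beta distributions (relative SD 10\%) on the shared disease-free and
#' relapse utilities and on each strategy's stay-disease-free and
#' relapse-death transition probabilities; gamma distributions (relative
#' SD 30\%) on one-time and non-zero state costs.
#'
#' @param base_specs named list of [markov_spec()] objects.
#' @return list of [param_distribution()] objects.
#' @export
default_psa_distributions <- function(base_specs) {
  first <- base_specs[[1]]
  dists <- list(
    param_distribution("*/utilities/1", "beta", first$utilities[1]),
    param_distribution("*/utilities/2", "beta", first$utilities[2]))
  for (k in 1:2) {
    if (first$state_costs[k] > 0)
      dists[[length(dists) + 1]] <-
        param_distribution(paste0("*/state_costs/", k), "gamma",
                           first$state_costs[k])
  }
  for (lab in names(base_specs)) {
    s <- base_specs[[lab]]
    dists[[length(dists) + 1]] <-
      param_distribution(paste0(lab, "/one_time_cost"), "gamma",
                         s$one_time_cost)
    dists[[length(dists) + 1]] <-
      param_distribution(paste0(lab, "/transitions/1/1"), "beta",
                         s$transitions[1, 1])
    dists[[length(dists) + 1]] <-
      param_distribution(paste0(lab, "/transitions/2/3"), "beta",
                         s$transitions[2, 3])
  }
  dists
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: in each draw every
#' declared parameter is sampled once and applied to all strategies it
#' targets (common random numbers, so between-strategy differences are not
#' inflated by sampling noise), each strategy's cohort model is run, and
#' the (cost, QALY) pair recorded. Cost-effectiveness acceptability curves
#' give, at each willingness-to-pay value, the fraction of draws in which
#' each strategy has the highest net monetary benefit. Sampled transition
#' entries are clamped into `[0, 1]` (occurrences counted in
#' `n_clamped`) and their rows rebalanced. Fully seeded: the same
#' `config$seed` reproduces the draws bit for bit.
#'
#' @param base_specs named list of [markov_spec()] objects.
#' @param distributions list of [param_distribution()] objects (default
#'   [default_psa_distributions()]).
#' @param config a [cea_config()].
#' @return object of class `psa_result`: `draws` (long data frame: draw,
#'   strategy, cost, qaly), `ceac` (matrix wtp grid x strategies, rows
#'   summing to 1), `wtp_grid`, `n_clamped`, `seed`.
#' @export
run_psa <- function(base_specs, distributions = NULL, config = cea_config()) {
  assert_that(length(base_specs) >= 2 && !is.null(names(base_specs)),
              "base_specs must be a named list of at least two strategies")
  distributions <- distributions %||% default_psa_distributions(base_specs)
  assert_that(all(vapply(distributions, inherits, logical(1),
                         "param_distribution")),
              "distributions must be param_distribution objects")
  labs <- names(base_specs)
  D <- config$psa_draws
  cost <- matrix(NA_real_, D, length(labs), dimnames = list(NULL, labs))
  qaly <- cost
  n_clamped <- 0L
  with_seed(config$seed, {
    for (d in seq_len(D)) {
      specs <- base_specs
      for (dist in distributions) {
        specs <- apply_param(specs, dist$path, sample_param(dist))
        if (isTRUE(attr(specs, "clamped"))) n_clamped <- n_clamped + 1L
      }
      for (lab in labs) {
        tot <- markov_totals(specs[[lab]])
        cost[d, lab] <- tot["cost"]
        qaly[d, lab] <- tot["qaly"]
      }
    }
  })
  if (n_clamped > 0)
    warning(n_clamped, " sampled transition entries clamped into [0, 1]")
  ceac <- t(vapply(config$wtp_grid, function(lambda) {
    nmb <- lambda * qaly - cost
    best <- max.col(nmb, ties.method = "first")
    tabulate(best, nbins = length(labs)) / D
  }, numeric(length(labs))))
  dimnames(ceac) <- list(config$wtp_grid, labs)
  draws <- data.frame(draw = rep(seq_len(D), times = length(labs)),
                      strategy = rep(labs, each = D),
                      cost = as.vector(cost), qaly = as.vector(qaly),
                      stringsAsFactors = FALSE)
  structure(class = "psa_result", list(
    draws = draws, cost = cost, qaly = qaly, ceac = ceac,
    wtp_grid = config$wtp_grid, n_clamped = n_clamped,
    seed = config$seed))
}

#' @export
print.psa_result <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:",
      nrow(x$cost), "draws x", ncol(x$cost), "strategies\n")
  cat("  mean cost:", paste(sprintf("%s $%.0f", colnames(x$cost),
                                    colMeans(x$cost)), collapse = ", "), "\n")
  cat("  mean QALYs:", paste(sprintf("%s %.3f", colnames(x$qaly),
                                     colMeans(x$qaly)), collapse = ", "), "\n")
  if (x$n_clamped > 0) cat("  clamped transition draws:", x$n_clamped, "\n")
  invisible(x)
}

#' @export
plot.psa_result <- function(x, xlab = "Willingness to pay (USD/QALY)",
                            ylab = "Probability cost-effective", ...) {
  graphics::matplot(x$wtp_grid, x$ceac, type = "l", lty = 1, lwd = 2,
                    ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  graphics::legend("right", legend = colnames(x$ceac), lty = 1, lwd = 2,
                   col = seq_len(ncol(x$ceac)), bty = "n")
  invisible(x)
}

# linear interpolation of a CEAC column at an arbitrary threshold
ceac_at <- function(psa, wtp) {
  vapply(colnames(psa$ceac), function(s)
    stats::approx(psa$wtp_grid, psa$ceac[, s], xout = wtp, rule = 2)$y,
    numeric(1))
}

#' Cost-effectiveness acceptability summary
#'
#' Per-strategy probabilities of being cost-effective at the headline
#' willingness-to-pay thresholds (interpolated from the CEAC where a
#' threshold is off-grid), plus the strategy preferred at the
#' cost-effectiveness threshold.
#'
#' @param psa a [run_psa()] result.
#' @param config the [cea_config()] used.
#' @return object of class `acceptability_report`: `table` (strategies x
#'   thresholds), `preferred`, `threshold`.
#' @export
acceptability_report <- function(psa, config = cea_config()) {
  assert_that(inherits(psa, "psa_result"), "psa must be a psa_result")
  tab <- vapply(config$headline_thresholds, function(w) ceac_at(psa, w),
                numeric(ncol(psa$ceac)))
  tab <- matrix(tab, nrow = ncol(psa$ceac),
                dimnames = list(colnames(psa$ceac),
                                paste0("wtp_", config$headline_thresholds)))
  at_thr <- ceac_at(psa, config$cost_effective_threshold)
  structure(class = "acceptability_report", list(
    table = tab,
    preferred = names(which.max(at_thr)),
    threshold = config$cost_effective_threshold))
}

#' @export
print.acceptability_report <- function(x, ...) {
  cat("Probability of cost-effectiveness\n")
  print(round(x$table, 4))
  cat(sprintf("Preferred strategy at $%s/QALY: %s\n",
              format(x$threshold, big.mark = ","), x$preferred))
  invisible(x)
}
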