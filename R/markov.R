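#' Specify a three-state Markov cohort model
#'
#' The decision model has ordered states disease_free / relapse / death,
#' an annual (configurable) cycle, a row-stochastic transition matrix
#' (optionally per-cycle as a `3 x 3 x horizon` array), per-state annual
#' utilities and costs, a one-time treatment cost incurred undiscounted at
#' cycle 0, and exponential discounting of future costs and QALYs.
#'
#' @param transitions `3 x 3` row-stochastic matrix (rows = from-state) or
#'   a `3 x 3 x horizon_cycles` array for time-varying transitions. The
#'   death row must be absorbing, `(0, 0, 1)`.
#' @param state_costs per-state annual costs (USD/year), length 3.
#' @param one_time_cost treatment cost (USD) at cycle 0, undiscounted.
#' @param utilities per-state QALY weights per year, in `[0, 1]`
#'   (default 0.80 disease-free, 0.53 relapsed, 0 dead).
#' @param discount_rate annual discount rate (default 0.03).
#' @param horizon_cycles number of cycles; the default 38 annual cycles
#'   carries a cohort with median age 62 to age 100, a lifetime horizon.
#' @param cycle_length cycle length in years (default 1).
#' @param initial_distribution starting state-occupancy fractions
#'   (default everyone disease-free).
#' @param states state labels.
#' @param label optional strategy label.
#' @return object of class `markov_spec`.
#' @seealso [run_markov()], [calibrate_annual_probs()]
#' @export
markov_spec <- function(transitions, state_costs, one_time_cost = 0,
                        utilities = c(0.80, 0.53, 0),
                        discount_rate = 0.03, horizon_cycles = 38,
                        cycle_length = 1,
                        initial_distribution = c(1, 0, 0),
                        states = c("disease_free", "relapse", "death"),
                        label = NULL) {
  assert_that(length(states) == 3, "exactly three states are supported")
  if (length(dim(transitions)) == 3) {
    assert_that(all(dim(transitions)[1:2] == 3) &&
                  dim(transitions)[3] >= horizon_cycles,
                "per-cycle transitions need dim 3 x 3 x >=horizon_cycles")
    for (t in seq_len(horizon_cycles)) validate_tmatrix(transitions[, , t])
  } else {
    assert_that(is.matrix(transitions) && all(dim(transitions) == 3),
                "transitions must be a 3 x 3 matrix")
    validate_tmatrix(transitions)
  }
  assert_that(length(state_costs) == 3 && all(state_costs >= 0),
              "state_costs must be 3 non-negative values")
  assert_that(length(utilities) == 3, "utilities must have length 3")
  assert_prob(utilities, "utilities")
  assert_that(one_time_cost >= 0, "one_time_cost must be >= 0")
  assert_that(discount_rate >= 0, "discount_rate must be >= 0")
  assert_that(horizon_cycles >= 1 && horizon_cycles == floor(horizon_cycles),
              "horizon_cycles must be a positive integer")
  assert_that(cycle_length > 0, "cycle_length must be > 0")
  assert_prob_vector(initial_distribution, "initial_distribution")
  structure(class = "markov_spec", list(
    states = states, transitions = transitions,
    state_costs = as.numeric(state_costs),
    one_time_cost = one_time_cost,
    utilities = as.numeric(utilities),
    discount_rate = discount_rate,
    horizon_cycles = as.integer(horizon_cycles),
    cycle_length = cycle_length,
    initial_distribution = as.numeric(initial_distribution),
    label = label))
}

validate_tmatrix <- function(m, tol = 1e-9) {
  assert_that(all(is.finite(m)) && all(m >= -tol) && all(m <= 1 + tol),
              "transition probabilities must lie in [0, 1]")
  assert_that(all(abs(rowSums(m) - 1) <= tol),
              "transition matrix rows must sum to 1")
  assert_that(all(abs(m[3, ] - c(0, 0, 1)) <= tol),
              "the death state must be absorbing")
  invisible(TRUE)
}

#' @export
print.markov_spec <- function(x, ...) {
  cat("Markov cohort model", if (!is.null(x$label)) paste0("[", x$label, "]"),
      "\n")
  cat(sprintf("  states %s; %d cycles of %g yr; discount %.1f%%\n",
              paste(x$states, collapse = "/"), x$horizon_cycles,
              x$cycle_length, 100 * x$discount_rate))
  if (length(dim(x$transitions)) == 2) {
    tm <- round(x$transitions, 4)
    dimnames(tm) <- list(x$states, x$states)
    print(tm)
  } else cat("  (per-cycle transition array)\n")
  cat(sprintf("  utilities %s; state costs %s; one-time cost %.2f\n",
              paste(x$utilities, collapse = "/"),
              paste(x$state_costs, collapse = "/"), x$one_time_cost))
  invisible(x)
}

#' Annual transition probabilities from observed 1-year rates
#'
#' Builds the disease-free and relapse rows of the transition matrix from
#' follow-up summaries: the probability of remaining disease-free equals
#' the 1-year loco-regional progression-free survival; the probability of
#' dying from the disease-free state combines the 1-year excess mortality
#' `1 - os_1yr` with the background rate as
#' `1 - (1 - p1)(1 - p2)` and is capped at `1 - lrfs_1yr` so the row stays
#' stochastic; the remainder moves to relapse. From relapse, death combines
#' `relapse_mortality` with the background rate; recovery to disease-free
#' is not modelled. Death is absorbing.
#'
#' @param lrfs_1yr 1-year loco-regional progression-free survival, in
#'   (0, 1]; cannot exceed `os_1yr`.
#' @param os_1yr 1-year overall survival in (0, 1].
#' @param relapse_mortality annual death probability in the relapse state
#'   attributable to the disease (default 0.5, i.e. a median post-relapse
#'   survival of about one year).
#' @param background_mortality annual death probability from other causes
#'   (default 0.01).
#' @return `3 x 3` row-stochastic matrix with state names.
#' @export
calibrate_annual_probs <- function(lrfs_1yr, os_1yr,
                                   relapse_mortality = 0.5,
                                   background_mortality = 0.01) {
  assert_that(lrfs_1yr > 0 && lrfs_1yr <= 1, "lrfs_1yr must lie in (0, 1]")
  assert_that(os_1yr > 0 && os_1yr <= 1, "os_1yr must lie in (0, 1]")
  assert_that(lrfs_1yr <= os_1yr,
              "lrfs_1yr cannot exceed os_1yr (progression-free survival ",
              "cannot exceed overall survival)")
  assert_prob(relapse_mortality, "relapse_mortality")
  assert_prob(background_mortality, "background_mortality")
  p_df_df <- lrfs_1yr
  p_df_death <- min(1 - (1 - (1 - os_1yr)) * (1 - background_mortality),
                    1 - lrfs_1yr)
  p_df_rel <- 1 - p_df_df - p_df_death
  p_r_death <- 1 - (1 - relapse_mortality) * (1 - background_mortality)
  m <- rbind(c(p_df_df, p_df_rel, p_df_death),
             c(0, 1 - p_r_death, p_r_death),
             c(0, 0, 1))
  dimnames(m) <- list(c("disease_free", "relapse", "death"),
                      c("disease_free", "relapse", "death"))
  m
}

# Lean totals-only evaluation used in tight loops (PSA): no validation,
# no trace retained.
markov_totals <- function(spec) {
  occ <- spec$initial_distribution
  tv <- length(dim(spec$transitions)) == 3
  disc <- (1 + spec$discount_rate)^(-(seq_len(spec$horizon_cycles) - 1) *
                                      spec$cycle_length)
  cost <- spec$one_time_cost
  qaly <- 0
  for (t in seq_len(spec$horizon_cycles)) {
    cost <- cost + sum(occ * spec$state_costs) * spec$cycle_length * disc[t]
    qaly <- qaly + sum(occ * spec$utilities) * spec$cycle_length * disc[t]
    P <- if (tv) spec$transitions[, , t] else spec$transitions
    occ <- as.numeric(occ %*% P)
    if (1 - occ[3] < 1e-6) {
      # cohort extinct: remaining cycles contribute nothing material
      break
    }
  }
  c(cost = cost, qaly = qaly)
}

#' Run the Markov cohort model
#'
#' Propagates the cohort through the transition matrix and accumulates
#' discounted costs and QALYs. Rewards are evaluated on state membership
#' at the start of each cycle (no half-cycle correction): cycle `t`
#' (0-based) contributes `occupancy(t) . rewards x cycle_length /
#' (1 + discount_rate)^t`, and the one-time treatment cost enters
#' undiscounted at `t = 0`. Propagation stops early once the fraction
#' alive falls below 1e-6.
#'
#' @param spec a [markov_spec()].
#' @return object of class `markov_result`: `occupancy`
#'   (`cycles + 1` rows by 3 states), `discounted_cost_per_cycle`,
#'   `discounted_qaly_per_cycle`, `total_cost`, `total_qalys`,
#'   `life_expectancy` (undiscounted years alive), `label`, `spec`.
#' @export
run_markov <- function(spec) {
  assert_that(inherits(spec, "markov_spec"), "spec must be a markov_spec")
  tv <- length(dim(spec$transitions)) == 3
  H <- spec$horizon_cycles
  occ <- matrix(NA_real_, nrow = H + 1, ncol = 3,
                dimnames = list(0:H, spec$states))
  occ[1, ] <- spec$initial_distribution
  cost_cy <- numeric(H)
  qaly_cy <- numeric(H)
  alive <- numeric(H)
  last <- H
  for (t in seq_len(H)) {
    disc <- (1 + spec$discount_rate)^(-(t - 1) * spec$cycle_length)
    cost_cy[t] <- sum(occ[t, ] * spec$state_costs) * spec$cycle_length * disc
    qaly_cy[t] <- sum(occ[t, ] * spec$utilities) * spec$cycle_length * disc
    alive[t] <- (1 - occ[t, 3]) * spec$cycle_length
    P <- if (tv) spec$transitions[, , t] else spec$transitions
    occ[t + 1, ] <- occ[t, ] %*% P
    if (1 - occ[t + 1, 3] < 1e-6) { last <- t; break }
  }
  occ <- occ[seq_len(last + 1), , drop = FALSE]
  cost_cy <- cost_cy[seq_len(last)]
  qaly_cy <- qaly_cy[seq_len(last)]
  cost_cy[1] <- cost_cy[1] + spec$one_time_cost
  structure(class = "markov_result", list(
    occupancy = occ,
    discounted_cost_per_cycle = cost_cy,
    discounted_qaly_per_cycle = qaly_cy,
    total_cost = sum(cost_cy),
    total_qalys = sum(qaly_cy),
    life_expectancy = sum(alive[seq_len(last)]),
    label = spec$label, spec = spec))
}

#' @export
print.markov_result <- function(x, ...) {
  cat("Markov cohort result",
      if (!is.null(x$label)) paste0("[", x$label, "]"), "\n")
  cat(sprintf("  %d cycles; total cost $%.2f; total QALYs %.4f; ",
              nrow(x$occupancy) - 1, x$total_cost, x$total_qalys))
  cat(sprintf("undiscounted life expectancy %.2f yr\n", x$life_expectancy))
  invisible(x)
}

#' @export
summary.markov_result <- function(object, ...) {
  data.frame(strategy = object$label %||% NA_character_,
             cycles = nrow(object$occupancy) - 1,
             total_cost = object$total_cost,
             total_qalys = object$total_qalys,
             life_expectancy = object$life_expectancy)
}

#' @export
plot.markov_result <- function(x, xlab = "Cycle", ylab = "Fraction of cohort",
                               ...) {
  cy <- as.numeric(rownames(x$occupancy))
  graphics::matplot(cy, x$occupancy, type = "l", lty = 1, lwd = 2,
                    col = c("forestgreen", "orange", "black"),
                    xlab = xlab, ylab = ylab, ylim = c(0, 1), ...)
  graphics::legend("right", legend = colnames(x$occupancy), lty = 1, lwd = 2,
                   col = c("forestgreen", "orange", "black"), bty = "n")
  invisible(x)
}

#' Undiscounted life expectancy of a Markov specification
#'
#' Expected years alive over the model horizon, counting state membership
#' at the start of each cycle: `sum over cycles of (1 - P(death)) x
#' cycle_length`.
#'
#' @param spec a [markov_spec()].
#' @return years of life expectancy (truncated at the horizon).
#' @export
life_expectancy <- function(spec) {
  assert_that(inherits(spec, "markov_spec"), "spec must be a markov_spec")
  tv <- length(dim(spec$transitions)) == 3
  occ <- spec$initial_distribution
  total <- 0
  for (t in seq_len(spec$horizon_cycles)) {
    total <- total + (1 - occ[3]) * spec$cycle_length
    P <- if (tv) spec$transitions[, , t] else spec$transitions
    occ <- as.numeric(occ %*% P)
  }
  total
}

#' Extract a strategy's (cost, QALY) summary
#'
#' @param label strategy label.
#' @param total_cost discounted lifetime cost (USD).
#' @param total_qalys discounted lifetime QALYs.
#' @return object of class `strategy_result`.
#' @export
strategy_result <- function(label, total_cost, total_qalys) {
  assert_that(is.character(label) && length(label) == 1, "label must be a string")
  structure(class = "strategy_result",
            list(strategy_label = label, total_cost = total_cost,
                 total_qalys = total_qalys))
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("%s: cost $%.2f, %.4f QALYs\n", x$strategy_label,
              x$total_cost, x$total_qalys))
  invisible(x)
}

#' Default Markov specifications for the shipped three-arm study
#'
#' Builds one [markov_spec()] per strategy from the packaged
#' configuration: transition rows calibrated with
#' [calibrate_annual_probs()] to each arm's 1-year LRFS and OS, shared
#' utilities, discount rate and state costs, and each arm's observed mean
#' 6-month healthcare cost as the one-time cost.
#'
#' @param config_path optional path to an alternative YAML/JSON config.
#' @return named list of `markov_spec` objects (PEG, NTF, ONS by default).
#' @export
default_markov_specs <- function(config_path = NULL) {
  path <- config_path %||% default_config_path()
  cfg <- read_config_file(path)
  mk <- cfg$markov
  profiles <- read_arm_profiles(path)
  specs <- lapply(names(profiles), function(a) {
    p <- profiles[[a]]
    markov_spec(
      transitions = calibrate_annual_probs(
        p$lrfs_1yr, p$os_1yr,
        relapse_mortality = mk$relapse_mortality,
        background_mortality = mk$background_mortality),
      state_costs = unlist(mk$state_costs),
      one_time_cost = mk$one_time_cost[[a]],
      utilities = unlist(mk$utilities),
      discount_rate = mk$discount_rate,
      horizon_cycles = mk$horizon_cycles,
      cycle_length = mk$cycle_length,
      label = a)
  })
  names(specs) <- names(profiles)
  specs
}
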