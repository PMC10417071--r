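#' Generate one synthetic trial arm
#'
#' Draws `profile$n` patient records whose distribution is calibrated to the
#' arm profile: covariates (age, sex, stage, ECOG), percent weight change
#' with its gain/unchanged/loss category, binary nutrition indicators,
#' tumour response, event times, itemised costs (gamma with coefficient of
#' variation 0.3) and hospital days.
#'
#' Event times follow constant hazards calibrated to the profile's printed
#' 1-year rates: the all-cause death hazard is `-log(os_1yr)` and the
#' loco-regional progression hazard is `-log(lrfs_1yr) + log(os_1yr)`, so
#' that `lrfs_time = min(progression, death)` has 1-year survival
#' `lrfs_1yr` and `os_time` has 1-year survival `os_1yr`. Both endpoints
#' are administratively censored at `censor_horizon`. With a 1-year rate of
#' 1 the hazard is 0 and every subject is censored at the horizon.
#'
#' The same `seed` always yields an identical cohort; the caller's RNG
#' state is left untouched.
#'
#' @param profile an [arm_profile()].
#' @param seed integer seed for this arm.
#' @param censor_horizon administrative censoring time in years (default 3,
#'   matching a maximum follow-up of about 32 months).
#' @return a `data.frame` (class `nutricea_cohort`) with one row per
#'   subject and columns `subject_id`, `arm_label`, `age`, `sex`, `stage`,
#'   `ecog`, `baseline_weight`, `weight_change_pct`, `weight_category`,
#'   `albumin_ge35`, `crp_lt15`, `lymph_ge1`, `response`, `lrfs_time`,
#'   `lrfs_event`, `os_time`, `os_event`, one `cost_<item>` column per cost
#'   item, and `hospital_days`.
#' @seealso [generate_trial()], [default_arm_profiles()]
#' @export
generate_cohort <- function(profile, seed, censor_horizon = 3) {
  assert_that(inherits(profile, "arm_profile"), "profile must be an arm_profile")
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single number")
  assert_that(is.numeric(censor_horizon) && censor_horizon > 0,
              "censor_horizon must be > 0")
  n <- profile$n
  with_seed(seed, {
    age <- sample(seq(profile$age_range[1], profile$age_range[2]), n,
                  replace = TRUE)
    sex <- ifelse(runif(n) < profile$sex_male_prob, "male", "female")
    stage <- sample(names(profile$stage_probs), n, replace = TRUE,
                    prob = profile$stage_probs)
    ecog <- sample(names(profile$ecog_probs), n, replace = TRUE,
                   prob = profile$ecog_probs)
    baseline_weight <- rtruncnorm(n, profile$baseline_weight_mean,
                                  max(profile$baseline_weight_sd, 1e-12),
                                  30, 90)

    bands <- weight_bands()
    weight_category <- sample(names(bands), n, replace = TRUE,
                              prob = profile$weight_category_probs)
    lat <- profile$weight_latent
    weight_change_pct <- numeric(n)
    for (cat in names(bands)) {
      idx <- which(weight_category == cat)
      if (!length(idx)) next
      if (lat$sd == 0) {
        weight_change_pct[idx] <- lat$mu
      } else {
        weight_change_pct[idx] <- rtruncnorm(length(idx), lat$mu, lat$sd,
                                             bands[[cat]][1], bands[[cat]][2])
      }
    }

    albumin_ge35 <- runif(n) < profile$albumin_ge35_prob
    crp_lt15 <- runif(n) < profile$crp_lt15_prob
    lymph_ge1 <- runif(n) < profile$lymph_ge1_prob
    response <- sample(names(profile$response_probs), n, replace = TRUE,
                       prob = profile$response_probs)

    h_death <- -log(profile$os_1yr)
    h_prog <- -log(profile$lrfs_1yr) - h_death
    t_death <- if (h_death > 0) rexp(n, h_death) else rep(Inf, n)
    t_prog <- if (h_prog > 0) rexp(n, h_prog) else rep(Inf, n)
    lrfs_raw <- pmin(t_prog, t_death)
    lrfs_event <- lrfs_raw <= censor_horizon
    lrfs_time <- pmin(lrfs_raw, censor_horizon)
    os_event <- t_death <= censor_horizon
    os_time <- pmin(t_death, censor_horizon)

    costs <- vapply(profile$cost_means,
                    function(m) rgamma_cv(n, m, 0.3), numeric(n))
    if (n == 1) costs <- matrix(costs, nrow = 1,
                                dimnames = list(NULL, names(profile$cost_means)))
    colnames(costs) <- paste0("cost_", colnames(costs))
    hospital_days <- rgamma_cv(n, profile$hospital_days_mean, 0.3)

    out <- data.frame(
      subject_id = sprintf("%s-%03d", profile$arm_label, seq_len(n)),
      arm_label = profile$arm_label,
      age = age, sex = sex, stage = stage, ecog = ecog,
      baseline_weight = baseline_weight,
      weight_change_pct = weight_change_pct,
      weight_category = weight_category,
      albumin_ge35 = albumin_ge35, crp_lt15 = crp_lt15,
      lymph_ge1 = lymph_ge1, response = response,
      lrfs_time = lrfs_time, lrfs_event = lrfs_event,
      os_time = os_time, os_event = os_event,
      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(costs))
    out$hospital_days <- hospital_days
    class(out) <- c("nutricea_cohort", "data.frame")
    out
  })
}

#' Generate a full multi-arm synthetic trial
#'
#' Concatenates per-arm cohorts generated by [generate_cohort()]. Each arm
#' draws from its own RNG stream whose seed is derived deterministically
#' from the master seed and the arm label, so the records of an arm do not
#' depend on the order in which profiles are listed.
#'
#' @param profiles list of [arm_profile()] objects with distinct labels
#'   (at least two).
#' @param seed master integer seed.
#' @param censor_horizon administrative censoring time in years.
#' @return a `nutricea_cohort` data frame with all arms stacked.
#' @export
generate_trial <- function(profiles, seed, censor_horizon = 3) {
  assert_that(is.list(profiles) && length(profiles) >= 2,
              "at least two arm profiles are required")
  assert_that(all(vapply(profiles, inherits, logical(1), "arm_profile")),
              "profiles must be arm_profile objects")
  labels <- vapply(profiles, `[[`, character(1), "arm_label")
  assert_that(!anyDuplicated(labels), "duplicate arm labels: ",
              paste(labels[duplicated(labels)], collapse = ", "))
  arms <- lapply(profiles, function(p)
    generate_cohort(p, derive_seed(seed, p$arm_label), censor_horizon))
  out <- do.call(rbind, arms)
  rownames(out) <- NULL
  class(out) <- c("nutricea_cohort", "data.frame")
  out
}

#' Write / read a cohort CSV
#'
#' One header row, one row per subject, columns exactly as produced by
#' [generate_cohort()].
#'
#' @param cohort a cohort data frame.
#' @param path output (or input) CSV path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `nutricea_cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "arm_label", "weight_change_pct", "lrfs_time",
              "lrfs_event", "os_time", "os_event")
  missing <- setdiff(needed, names(out))
  assert_that(length(missing) == 0, "cohort CSV lacks columns: ",
              paste(missing, collapse = ", "))
  class(out) <- c("nutricea_cohort", "data.frame")
  out
}

cost_columns <- function(cohort) grep("^cost_", names(cohort), value = TRUE)
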