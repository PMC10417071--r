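#' Define the generating profile of one trial arm
#'
#' An `arm_profile` bundles everything the cohort simulator needs to emulate
#' one enteral nutrition-support arm: sample size, the weight-change
#' distribution (mean, SD and the three-way gain/unchanged/loss split),
#' post-treatment nutrition indicator rates, tumour-response probabilities,
#' 1-year loco-regional progression-free survival (LRFS) and overall survival
#' (OS), itemised mean costs, hospital days, and baseline covariate
#' distributions (age range, sex, stage, ECOG performance status).
#'
#' Weight change is generated hierarchically: a category is drawn from
#' `weight_category_probs`, then a continuous percentage from a normal
#' distribution truncated to that category's band (gain > +1\%, unchanged
#' within ±1\%, loss < −1\%). The latent normal parameters are solved at
#' construction time so that the resulting mixture has exactly
#' `weight_change_mean` and `weight_change_sd` while the category
#' frequencies keep their configured values (see the methods vignette).
#'
#' @param arm_label arm name, e.g. `"PEG"`, `"NTF"` or `"ONS"`.
#' @param n number of subjects in the arm.
#' @param weight_change_mean,weight_change_sd mean and SD of percent weight
#'   change during treatment (negative = loss).
#' @param weight_category_probs length-3 probability vector
#'   (gain/unchanged/loss), summing to 1.
#' @param albumin_ge35_prob,crp_lt15_prob,lymph_ge1_prob probabilities of
#'   post-treatment albumin >= 35 g/L, CRP < 15 mg/L and lymphocytes
#'   >= 1.0e9/L.
#' @param response_probs length-4 probability vector over loco-regional
#'   response categories CR/PR/SD/PD, summing to 1.
#' @param lrfs_1yr,os_1yr 1-year LRFS and OS proportions in (0, 1];
#'   `lrfs_1yr <= os_1yr` is required since LRFS events include death.
#' @param cost_means named numeric vector or list of mean costs (USD) per
#'   cost item.
#' @param hospital_days_mean mean hospital days during treatment.
#' @param age_range length-2 integer vector of admissible ages (years).
#' @param sex_male_prob probability of male sex.
#' @param stage_probs named probability vector over tumour stages
#'   (default names IIA/IIB/III/IVA/IVB).
#' @param ecog_probs named probability vector over ECOG strata
#'   (default names `"0-1"`, `"2"`).
#' @param baseline_weight_mean,baseline_weight_sd baseline body-weight
#'   distribution (kg), truncated to (30, 90) at generation time.
#' @return an object of class `arm_profile`.
#' @seealso [generate_cohort()], [default_arm_profiles()]
#' @export
arm_profile <- function(arm_label, n,
                        weight_change_mean, weight_change_sd,
                        weight_category_probs,
                        albumin_ge35_prob, crp_lt15_prob, lymph_ge1_prob,
                        response_probs, lrfs_1yr, os_1yr,
                        cost_means, hospital_days_mean,
                        age_range, sex_male_prob,
                        stage_probs = c(IIA = 0.05, IIB = 0.05, III = 0.55,
                                        IVA = 0.30, IVB = 0.05),
                        ecog_probs = c(`0-1` = 1, `2` = 0),
                        baseline_weight_mean = 58.4,
                        baseline_weight_sd = 9) {
  assert_that(is.character(arm_label) && length(arm_label) == 1 &&
                nzchar(arm_label), "arm_label must be a non-empty string")
  assert_that(is.numeric(n) && length(n) == 1 && n >= 1 && n == floor(n),
              "n must be a positive integer")
  assert_that(is.finite(weight_change_mean), "weight_change_mean must be finite")
  assert_that(is.finite(weight_change_sd) && weight_change_sd >= 0,
              "weight_change_sd must be >= 0")
  assert_that(length(weight_category_probs) == 3,
              "weight_category_probs must have 3 entries (gain/unchanged/loss)")
  assert_prob_vector(weight_category_probs, "weight_category_probs")
  assert_prob(albumin_ge35_prob, "albumin_ge35_prob")
  assert_prob(crp_lt15_prob, "crp_lt15_prob")
  assert_prob(lymph_ge1_prob, "lymph_ge1_prob")
  assert_that(length(response_probs) == 4,
              "response_probs must have 4 entries (CR/PR/SD/PD)")
  assert_prob_vector(response_probs, "response_probs")
  assert_that(is.numeric(lrfs_1yr) && lrfs_1yr > 0 && lrfs_1yr <= 1,
              "lrfs_1yr must lie in (0, 1]")
  assert_that(is.numeric(os_1yr) && os_1yr > 0 && os_1yr <= 1,
              "os_1yr must lie in (0, 1]")
  assert_that(lrfs_1yr <= os_1yr,
              "lrfs_1yr cannot exceed os_1yr (LRFS events include death)")
  cost_means <- unlist(cost_means)
  assert_that(length(cost_means) >= 1 && !is.null(names(cost_means)) &&
                all(nzchar(names(cost_means))), "cost_means must be named")
  assert_that(all(cost_means >= 0), "cost_means must be non-negative")
  assert_that(hospital_days_mean >= 0, "hospital_days_mean must be >= 0")
  assert_that(length(age_range) == 2 && age_range[1] <= age_range[2],
              "age_range must be c(min, max)")
  assert_prob(sex_male_prob, "sex_male_prob")
  assert_prob_vector(stage_probs, "stage_probs")
  assert_prob_vector(ecog_probs, "ecog_probs")
  assert_that(baseline_weight_sd >= 0, "baseline_weight_sd must be >= 0")

  names(weight_category_probs) <- c("gain", "unchanged", "loss")
  names(response_probs) <- c("CR", "PR", "SD", "PD")

  p <- structure(class = "arm_profile", list(
    arm_label = arm_label, n = as.integer(n),
    weight_change_mean = weight_change_mean,
    weight_change_sd = weight_change_sd,
    weight_category_probs = weight_category_probs,
    albumin_ge35_prob = albumin_ge35_prob,
    crp_lt15_prob = crp_lt15_prob,
    lymph_ge1_prob = lymph_ge1_prob,
    response_probs = response_probs,
    lrfs_1yr = lrfs_1yr, os_1yr = os_1yr,
    cost_means = cost_means,
    hospital_days_mean = hospital_days_mean,
    age_range = as.integer(round(age_range)),
    sex_male_prob = sex_male_prob,
    stage_probs = stage_probs, ecog_probs = ecog_probs,
    baseline_weight_mean = baseline_weight_mean,
    baseline_weight_sd = baseline_weight_sd))
  p$weight_latent <- solve_weight_latent(weight_change_mean, weight_change_sd,
                                         weight_category_probs)
  p
}

#' @export
print.arm_profile <- function(x, ...) {
  cat("Arm profile:", x$arm_label, " (n =", x$n, ")\n")
  cat(sprintf("  weight change %% : %.1f +/- %.1f (gain/unch/loss %s)\n",
              x$weight_change_mean, x$weight_change_sd,
              paste(round(x$weight_category_probs, 3), collapse = "/")))
  cat(sprintf("  1-yr LRFS %.3f, 1-yr OS %.3f\n", x$lrfs_1yr, x$os_1yr))
  cat("  cost items:", paste(names(x$cost_means), collapse = ", "), "\n")
  invisible(x)
}

# Weight categories as truncation bands on the percent scale.
# "unchanged" is within +/- 1 percentage point (a package convention; the
# source tables define no tolerance), gain above, loss below.
weight_bands <- function() {
  list(gain = c(1, Inf), unchanged = c(-1, 1), loss = c(-Inf, -1))
}

# Mean and variance of N(mu, sd) truncated to (a, b).
truncnorm_moments <- function(mu, sd, a, b) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  z <- pnorm(be) - pnorm(al)
  e <- mu + sd * (dnorm(al) - dnorm(be)) / z
  ta <- if (is.finite(al)) al * dnorm(al) else 0
  tb <- if (is.finite(be)) be * dnorm(be) else 0
  v <- sd^2 * (1 + (ta - tb) / z - ((dnorm(al) - dnorm(be)) / z)^2)
  c(mean = e, var = v)
}

# Mean and sd of the category-weighted truncated-normal mixture.
weight_mixture_moments <- function(mu, sd, probs) {
  bands <- weight_bands()
  m1 <- 0
  m2 <- 0
  for (k in seq_along(bands)) {
    if (probs[k] <= 0) next
    mo <- truncnorm_moments(mu, sd, bands[[k]][1], bands[[k]][2])
    m1 <- m1 + probs[k] * mo["mean"]
    m2 <- m2 + probs[k] * (mo["var"] + mo["mean"]^2)
  }
  c(mean = unname(m1), sd = sqrt(max(unname(m2) - unname(m1)^2, 0)))
}

# Solve for latent normal (mu, sd) so the truncated mixture reproduces the
# target mean and sd exactly. Degenerate sd = 0 falls back to a point mass.
solve_weight_latent <- function(mean, sd, probs) {
  if (sd == 0) return(list(mu = mean, sd = 0))
  obj <- function(par) {
    mo <- weight_mixture_moments(par[1], exp(par[2]), probs)
    (mo["mean"] - mean)^2 + (mo["sd"] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj,
               control = list(reltol = 1e-15, maxit = 10000))
  if (fit$value > 1e-6)
    warning("weight-change mixture calibration residual ", signif(fit$value, 3),
            "; generated moments may deviate from the profile")
  list(mu = fit$par[1], sd = exp(fit$par[2]))
}

#' Arm profiles of the shipped three-arm study configuration
#'
#' Reads the packaged default configuration and returns the three calibrated
#' arm profiles (PEG, NTF, ONS; 63 subjects each).
#'
#' @return named list of [arm_profile()] objects.
#' @export
default_arm_profiles <- function() {
  read_arm_profiles(default_config_path())
}

default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "nutricea",
              mustWork = TRUE)
}

read_config_file <- function(path) {
  assert_that(file.exists(path), "config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Read arm profiles from a YAML or JSON configuration file
#'
#' The file must contain an `arms` list whose entries carry the
#' [arm_profile()] fields. Probability vectors may be given as counts; they
#' are normalised to sum to 1.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return named list of [arm_profile()] objects.
#' @export
read_arm_profiles <- function(path) {
  cfg <- read_config_file(path)
  assert_that(!is.null(cfg$arms) && length(cfg$arms) > 0,
              "config has no 'arms' section")
  profiles <- lapply(cfg$arms, function(a) {
    norm <- function(p) unlist(p) / sum(unlist(p))
    sp <- norm(a$stage_probs)
    names(sp) <- c("IIA", "IIB", "III", "IVA", "IVB")[seq_along(sp)]
    ep <- norm(a$ecog_probs)
    names(ep) <- c("0-1", "2")[seq_along(ep)]
    arm_profile(
      arm_label = a$arm_label, n = a$n_subjects %||% a$n,
      weight_change_mean = a$weight_change_mean,
      weight_change_sd = a$weight_change_sd,
      weight_category_probs = norm(a$weight_category_probs),
      albumin_ge35_prob = a$albumin_ge35_prob,
      crp_lt15_prob = a$crp_lt15_prob,
      lymph_ge1_prob = a$lymph_ge1_prob,
      response_probs = norm(a$response_probs),
      lrfs_1yr = a$lrfs_1yr, os_1yr = a$os_1yr,
      cost_means = a$cost_means,
      hospital_days_mean = a$hospital_days_mean,
      age_range = unlist(a$age_range),
      sex_male_prob = a$sex_male_prob,
      stage_probs = sp, ecog_probs = ep,
      baseline_weight_mean = a$baseline_weight_mean %||% 58.4,
      baseline_weight_sd = a$baseline_weight_sd %||% 9)
  })
  names(profiles) <- vapply(profiles, `[[`, character(1), "arm_label")
  profiles
}
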