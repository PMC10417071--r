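#' Matching configuration
#'
#' Parameters of the three-group propensity-score match: the covariates
#' entering the multinomial model, the caliper as a multiple of the SD of
#' the logit propensity score (0.6 by convention), and the reference arm
#' whose membership probability supplies the matching scalar.
#'
#' @param covariates character vector of cohort column names.
#' @param caliper_multiplier caliper width as a fraction of the SD of the
#'   logit propensity score.
#' @param replacement currently only matching without replacement is
#'   supported.
#' @param reference_arm label of the arm whose subjects anchor each
#'   triplet.
#' @return object of class `match_config`.
#' @export
match_config <- function(covariates = c("age", "sex", "stage", "ecog"),
                         caliper_multiplier = 0.6, replacement = FALSE,
                         reference_arm = "PEG") {
  assert_that(length(covariates) >= 1, "covariates must be non-empty")
  assert_that(caliper_multiplier > 0, "caliper_multiplier must be > 0")
  assert_that(identical(replacement, FALSE),
              "matching with replacement is not supported")
  structure(class = "match_config",
            list(covariates = covariates,
                 caliper_multiplier = caliper_multiplier,
                 replacement = FALSE, reference_arm = reference_arm))
}

#' Fit a multinomial propensity-score model
#'
#' Regresses arm membership on clinical covariates with multinomial
#' logistic regression ([nnet::multinom()], tight convergence tolerance)
#' and returns each subject's fitted arm-membership probabilities.
#' Covariates that are constant in the cohort are dropped with a message
#' (the fit then degenerates gracefully towards the intercept-only model,
#' whose fitted probabilities are the arm frequencies). Coefficients larger
#' than 15 in absolute value — the signature of (quasi-)separation — are
#' capped at +/-15 with a warning and the probabilities recomputed, keeping
#' all logits finite.
#'
#' @param cohort a cohort data frame with `arm_label` plus the covariates.
#' @param covariates character vector of covariate column names.
#' @param reference_arm the baseline outcome category of the model and the
#'   arm whose membership probability is later used as the matching scalar.
#' @return object of class `ps_fit`: list with `probabilities` (n x arms
#'   matrix, rows summing to 1), `coefficients`, `reference_arm`,
#'   `covariates`, and `logit` (logit of the reference-arm probability).
#' @export
fit_multinomial_ps <- function(cohort, covariates,
                               reference_arm = "PEG") {
  assert_that(all(covariates %in% names(cohort)),
              "missing covariates: ",
              paste(setdiff(covariates, names(cohort)), collapse = ", "))
  arm <- factor(cohort$arm_label)
  assert_that(nlevels(arm) >= 3, "need at least three arms")
  assert_that(reference_arm %in% levels(arm),
              "reference arm not present: ", reference_arm)
  arm <- stats::relevel(arm, ref = reference_arm)

  dat <- cohort[, covariates, drop = FALSE]
  constant <- vapply(dat, function(v) length(unique(v)) < 2, logical(1))
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(covariates[constant], collapse = ", "))
    dat <- dat[, !constant, drop = FALSE]
  }
  dat$.arm <- arm
  fit <- nnet::multinom(.arm ~ ., data = dat, trace = FALSE,
                        reltol = 1e-12, maxit = 1000)
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(levels(arm)[2],
                                                     names(cf)))
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), dat)
  if (any(abs(cf) > 15)) {
    warning("possible separation in the propensity model; ",
            "coefficients capped at +/-15")
    cf <- pmin(pmax(cf, -15), 15)
  }
  eta <- cbind(0, X %*% t(cf))          # reference category has linear score 0
  eta <- eta - apply(eta, 1, max)       # stabilised softmax
  pr <- exp(eta) / rowSums(exp(eta))
  colnames(pr) <- levels(arm)
  rownames(pr) <- NULL

  p_ref <- pmin(pmax(pr[, reference_arm], 1e-12), 1 - 1e-12)
  structure(class = "ps_fit", list(
    probabilities = pr, coefficients = cf,
    reference_arm = reference_arm,
    covariates = colnames(dat)[colnames(dat) != ".arm"],
    logit = qlogis(p_ref)))
}

#' Greedy 1:1:1 caliper matching on the logit propensity score
#'
#' For every reference-arm subject, finds the nearest unused subject in
#' each of the other two arms by absolute difference of the logit of the
#' reference-arm membership probability. A triplet is kept only when both
#' distances are within the caliper,
#' `caliper_multiplier x SD(logit)` with the SD pooled over all subjects;
#' matching is without replacement. Reference subjects are processed in
#' ascending order of their worst-case nearest-candidate distance
#' (computed before any consumption), which makes the pass deterministic
#' and lets easy matches consume scarce candidates last.
#'
#' @param cohort a cohort data frame (exactly three arms).
#' @param ps a [fit_multinomial_ps()] result for the same cohort.
#' @param config a [match_config()].
#' @return object of class `match_result`: `triplets` (data frame with
#'   `reference_id`, `arm2_id`, `arm3_id`), `arm_labels`, `caliper`,
#'   `logit_sd`, `ps_model_coefficients`, `n_unmatched`, and
#'   `max_distance` (largest within-triplet logit distance).
#' @export
match_triplets <- function(cohort, ps, config = match_config()) {
  assert_that(inherits(ps, "ps_fit"), "ps must be a ps_fit")
  assert_that(nrow(cohort) == length(ps$logit),
              "cohort and propensity fit sizes differ")
  arms <- unique(cohort$arm_label)
  assert_that(length(arms) == 3, "exactly three arms are required")
  ref <- config$reference_arm
  assert_that(ref %in% arms, "reference arm not present: ", ref)
  others <- setdiff(arms, ref)
  idx <- split(seq_len(nrow(cohort)), cohort$arm_label)
  assert_that(all(lengths(idx) > 0), "every arm needs at least one subject")

  logit <- ps$logit
  logit_sd <- sd(logit)
  caliper <- config$caliper_multiplier * logit_sd

  ref_ids <- idx[[ref]]
  # worst-case nearest-candidate distance per reference subject, pre-pass
  worst <- vapply(ref_ids, function(i) {
    max(vapply(others, function(a) min(abs(logit[idx[[a]]] - logit[i])),
               numeric(1)))
  }, numeric(1))
  order_ids <- ref_ids[order(worst, ref_ids)]

  used <- lapply(others, function(a) rep(FALSE, length(idx[[a]])))
  names(used) <- others
  triplets <- vector("list", nrow(cohort))
  n_unmatched <- 0L
  max_dist <- 0
  for (i in order_ids) {
    pick <- integer(0)
    dists <- numeric(0)
    ok <- TRUE
    for (a in others) {
      cand <- which(!used[[a]])
      if (!length(cand)) { ok <- FALSE; break }
      dd <- abs(logit[idx[[a]][cand]] - logit[i])
      j <- cand[which.min(dd)]
      if (min(dd) > caliper) { ok <- FALSE; break }
      pick <- c(pick, j)
      dists <- c(dists, min(dd))
    }
    if (!ok) { n_unmatched <- n_unmatched + 1L; next }
    for (k in seq_along(others)) used[[others[k]]][pick[k]] <- TRUE
    max_dist <- max(max_dist, dists)
    triplets[[i]] <- data.frame(
      reference_id = cohort$subject_id[i],
      arm2_id = cohort$subject_id[idx[[others[1]]][pick[1]]],
      arm3_id = cohort$subject_id[idx[[others[2]]][pick[2]]],
      stringsAsFactors = FALSE)
  }
  triplets <- do.call(rbind, triplets[!vapply(triplets, is.null, logical(1))])
  if (is.null(triplets))
    triplets <- data.frame(reference_id = character(0),
                           arm2_id = character(0), arm3_id = character(0))
  rownames(triplets) <- NULL
  structure(class = "match_result", list(
    triplets = triplets,
    arm_labels = c(ref, others),
    caliper = caliper, logit_sd = logit_sd,
    ps_model_coefficients = ps$coefficients,
    n_unmatched = n_unmatched, max_distance = max_dist))
}

#' @export
print.match_result <- function(x, ...) {
  cat("1:1:1 propensity match (", paste(x$arm_labels, collapse = "/"), ")\n",
      sep = "")
  cat(sprintf("  %d triplets, %d unmatched reference subjects\n",
              nrow(x$triplets), x$n_unmatched))
  cat(sprintf("  caliper %.4f (0.6 x logit SD %.4f), max distance %.4f\n",
              x$caliper, x$logit_sd, x$max_distance))
  invisible(x)
}

#' Subjects retained by a match
#'
#' @param cohort the cohort passed to [match_triplets()].
#' @param result a [match_result].
#' @return the matched subset of `cohort`.
#' @export
matched_cohort <- function(cohort, result) {
  ids <- unlist(result$triplets, use.names = FALSE)
  cohort[cohort$subject_id %in% ids, , drop = FALSE]
}

#' Standardized mean difference between two groups
#'
#' Continuous: difference in means over the pooled SD
#' `sqrt((v1 + v2) / 2)`; a zero pooled SD with equal means gives 0.
#' Logical/binary input is treated as 0/1.
#'
#' @param x_a,x_b values in the two groups.
#' @return signed standardized difference (a minus b).
#' @export
smd <- function(x_a, x_b) {
  x_a <- as.numeric(x_a)
  x_b <- as.numeric(x_b)
  s <- sqrt((stats::var(x_a) + stats::var(x_b)) / 2)
  d <- mean(x_a) - mean(x_b)
  if (s == 0) return(ifelse(d == 0, 0, Inf * sign(d)))
  d / s
}

#' Covariate balance before and after matching
#'
#' For every covariate and every ordered arm pair, the standardized mean
#' difference in the full and in the matched cohort. Categorical
#' covariates are expanded into per-level indicators and reported as
#' proportion differences standardised by the pooled binary SD.
#'
#' @param cohort the cohort passed to [match_triplets()].
#' @param result a [match_result].
#' @param covariates covariate columns to assess.
#' @return data frame with columns `covariate`, `level`, `pair`,
#'   `smd_before`, `smd_after`.
#' @export
balance_table <- function(cohort, result,
                          covariates = c("age", "sex", "stage", "ecog")) {
  assert_that(inherits(result, "match_result"), "result must be a match_result")
  after <- matched_cohort(cohort, result)
  arms <- result$arm_labels
  pairs <- utils::combn(arms, 2, simplify = FALSE)
  rows <- list()
  for (cv in covariates) {
    x <- cohort[[cv]]
    levels_cv <- if (is.numeric(x)) NA_character_ else sort(unique(x))
    for (lv in levels_cv) {
      val <- function(d) {
        v <- d[[cv]]
        if (is.na(lv)) as.numeric(v) else as.numeric(v == lv)
      }
      for (pr in pairs) {
        sub <- function(d, a) d[d$arm_label == a, , drop = FALSE]
        rows[[length(rows) + 1]] <- data.frame(
          covariate = cv, level = lv,
          pair = paste(pr, collapse = "-"),
          smd_before = smd(val(sub(cohort, pr[1])), val(sub(cohort, pr[2]))),
          smd_after = smd(val(sub(after, pr[1])), val(sub(after, pr[2]))),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
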