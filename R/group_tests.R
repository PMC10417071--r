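#' Compare a variable across trial arms
#'
#' Categorical variables are tested with Pearson's chi-square (no
#' continuity correction) on the arm-by-category contingency table;
#' continuous variables with a classical one-way ANOVA F-test (equal
#' variances). Categories observed zero times in every arm are dropped
#' before testing.
#'
#' @param cohort a cohort data frame with an `arm_label` column.
#' @param variable name of the column to compare.
#' @param kind `"categorical"` or `"continuous"`.
#' @return object of class `group_comparison`: a list with
#'   `statistic_name`, `statistic_value`, `degrees_of_freedom` and
#'   `p_value`.
#' @export
compare_groups <- function(cohort, variable,
                           kind = c("categorical", "continuous")) {
  kind <- match.arg(kind)
  assert_that(variable %in% names(cohort), "variable not found: ", variable)
  assert_that("arm_label" %in% names(cohort), "cohort lacks arm_label")
  arm <- factor(cohort$arm_label)
  x <- cohort[[variable]]
  keep <- !is.na(x) & !is.na(arm)
  arm <- droplevels(arm[keep])
  x <- x[keep]
  assert_that(nlevels(arm) >= 2, "need at least two non-degenerate arms")
  if (kind == "categorical") {
    tab <- table(arm, factor(x))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    assert_that(nrow(tab) >= 2 && ncol(tab) >= 2,
                "contingency table is degenerate for ", variable)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    out <- list(statistic_name = "Pearson chi-square",
                statistic_value = unname(ht$statistic),
                degrees_of_freedom = unname(ht$parameter),
                p_value = unname(ht$p.value))
  } else {
    assert_that(is.numeric(x), variable, " is not numeric")
    fit <- stats::aov(x ~ arm)
    s <- summary(fit)[[1]]
    out <- list(statistic_name = "one-way ANOVA F",
                statistic_value = s[["F value"]][1],
                degrees_of_freedom = s[["Df"]],
                p_value = s[["Pr(>F)"]][1])
  }
  # A statistic of exactly 0 (identical groups) has p = 1
  if (!is.finite(out$p_value)) out$p_value <- 1
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s = %.4g, df = %s, p = %.4g\n", x$statistic_name,
              x$statistic_value,
              paste(x$degrees_of_freedom, collapse = ", "), x$p_value))
  invisible(x)
}

#' Per-arm nutrition and cost summary
#'
#' Reproduces the outcome-table layout of a three-arm nutrition-support
#' study: per arm, the mean and SD of percent weight change, the
#' gain/unchanged/loss proportions, the proportions with albumin >= 35 g/L,
#' CRP < 15 mg/L and lymphocytes >= 1.0e9/L after treatment, response
#' proportions, mean itemised costs and mean hospital days.
#'
#' @param cohort a cohort data frame.
#' @return a data frame with one row per arm.
#' @export
nutrition_summary <- function(cohort) {
  assert_that(nrow(cohort) > 0, "cohort is empty")
  arms <- unique(cohort$arm_label)
  prop <- function(x) mean(as.logical(x))
  rows <- lapply(arms, function(a) {
    g <- cohort[cohort$arm_label == a, , drop = FALSE]
    sdv <- if (nrow(g) > 1) sd(g$weight_change_pct) else 0
    row <- data.frame(
      arm_label = a, n = nrow(g),
      weight_change_mean = mean(g$weight_change_pct),
      weight_change_sd = sdv,
      prop_weight_gain = mean(g$weight_category == "gain"),
      prop_weight_unchanged = mean(g$weight_category == "unchanged"),
      prop_weight_loss = mean(g$weight_category == "loss"),
      prop_albumin_ge35 = prop(g$albumin_ge35),
      prop_crp_lt15 = prop(g$crp_lt15),
      prop_lymph_ge1 = prop(g$lymph_ge1),
      prop_response_cr = mean(g$response == "CR"),
      prop_orr = mean(g$response %in% c("CR", "PR")),
      hospital_days_mean = mean(g$hospital_days),
      stringsAsFactors = FALSE)
    for (cc in cost_columns(cohort)) row[[paste0(cc, "_mean")]] <- mean(g[[cc]])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
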