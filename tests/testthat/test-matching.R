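# identical-covariate arms reduce the PS model to intercept-only
test_that("identical covariates give arm-frequency propensity scores", {
  coh <- rbind(
    do.call(rbind, replicate(10, cohort_row("A"), simplify = FALSE)),
    do.call(rbind, replicate(20, cohort_row("B"), simplify = FALSE)),
    do.call(rbind, replicate(30, cohort_row("C"), simplify = FALSE)))
  coh$subject_id <- sprintf("S%03d", seq_len(nrow(coh)))
  expect_message(ps <- fit_multinomial_ps(coh, c("age", "sex"), "A"),
                 "constant")
  expect_equal(unname(ps$probabilities[1, c("A", "B", "C")]),
               c(10, 20, 30) / 60, tolerance = 1e-6)
  expect_equal(max(abs(ps$probabilities - rep(ps$probabilities[1, ],
                                              each = 60))), 0,
               tolerance = 1e-6)
})

test_that("propensity probabilities sum to 1 and match an optim oracle", {
  set.seed(21)
  n <- 9
  coh <- do.call(rbind, lapply(seq_len(n), function(i)
    cohort_row(c("A", "B", "C")[1 + (i - 1) %% 3], id = paste0("S", i))))
  coh$age <- c(55, 62, 70, 48, 66, 59, 72, 50, 63)
  coh$baseline_weight <- c(52, 61, 58, 66, 49, 55, 63, 57, 60)
  ps <- fit_multinomial_ps(coh, c("age", "baseline_weight"), "A")
  expect_equal(rowSums(ps$probabilities), rep(1, n), tolerance = 1e-12)

  # independent maximization of the hand-written multinomial likelihood
  X <- cbind(1, coh$age, coh$baseline_weight)
  y <- as.integer(factor(coh$arm_label, levels = c("A", "B", "C")))
  best <- -Inf
  for (s in 1:5) {
    set.seed(s)
    o <- optim(rnorm(6, sd = 0.1), multinom_loglik, X = X, y = y, K = 3,
               method = "BFGS",
               control = list(fnscale = -1, maxit = 500, reltol = 1e-12))
    best <- max(best, o$value)
  }
  fit_ll <- multinom_loglik(as.vector(ps$coefficients), X, y, 3)
  expect_equal(fit_ll, best, tolerance = 1e-4)
})

test_that("identical arms match fully: 63 triplets, none unmatched", {
  profs <- default_arm_profiles()
  same <- lapply(c("PEG", "NTF", "ONS"), function(lab) {
    p <- profs$PEG
    p$arm_label <- lab
    p
  })
  coh <- generate_trial(same, seed = 5)
  coh$age <- 60; coh$sex <- "male"; coh$stage <- "III"; coh$ecog <- "0-1"
  ps <- suppressMessages(fit_multinomial_ps(coh, c("age", "sex")))
  mr <- match_triplets(coh, ps)
  expect_equal(nrow(mr$triplets), 63)
  expect_equal(mr$n_unmatched, 0L)
})

test_that("subjects beyond the caliper are counted unmatched", {
  # hand-built matching scalar: one reference subject is an outlier
  coh <- rbind(cohort_row("PEG", id = "P1"), cohort_row("PEG", id = "P2"),
               cohort_row("NTF", id = "N1"), cohort_row("NTF", id = "N2"),
               cohort_row("ONS", id = "O1"), cohort_row("ONS", id = "O2"))
  ps <- structure(class = "ps_fit", list(
    logit = c(0, 50, 0.01, 0.02, -0.01, 0.03),
    coefficients = matrix(0, 2, 1), reference_arm = "PEG",
    probabilities = NULL, covariates = "age"))
  mr <- match_triplets(coh, ps, match_config(reference_arm = "PEG"))
  expect_equal(nrow(mr$triplets), 1)
  expect_equal(mr$n_unmatched, 1L)
  expect_equal(mr$triplets$reference_id, "P1")
  expect_lte(mr$max_distance, mr$caliper)
})

test_that("greedy matching is optimal on well-separated toy clusters", {
  # four clusters far apart, one subject of each arm per cluster: the
  # exhaustive minimal-total-distance assignment must coincide with greedy
  centers <- c(0, 10, 20, 30)
  ref <- centers + 0.01
  arm2 <- centers + 0.02
  arm3 <- centers - 0.015
  coh <- do.call(rbind, lapply(1:4, function(i)
    rbind(cohort_row("PEG", id = paste0("P", i)),
          cohort_row("NTF", id = paste0("N", i)),
          cohort_row("ONS", id = paste0("O", i)))))
  logit <- numeric(12)
  logit[seq(1, 12, 3)] <- ref
  logit[seq(2, 12, 3)] <- arm2
  logit[seq(3, 12, 3)] <- arm3
  ps <- structure(class = "ps_fit", list(
    logit = logit, coefficients = matrix(0, 2, 1), reference_arm = "PEG",
    probabilities = NULL, covariates = "age"))
  mr <- match_triplets(coh, ps, match_config(reference_arm = "PEG"))
  expect_equal(nrow(mr$triplets), 4)
  greedy_total <- sum(vapply(seq_len(4), function(k) {
    i <- match(mr$triplets$reference_id[k], coh$subject_id)
    j2 <- match(mr$triplets$arm2_id[k], coh$subject_id)
    j3 <- match(mr$triplets$arm3_id[k], coh$subject_id)
    abs(logit[j2] - logit[i]) + abs(logit[j3] - logit[i])
  }, numeric(1)))
  oracle <- exhaustive_triplet_oracle(ref, arm2, arm3, mr$caliper)
  expect_equal(greedy_total, oracle, tolerance = 1e-12)
})

test_that("matches never reuse subjects and never violate the caliper", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- c(15, 18, 20)
    coh <- do.call(rbind, lapply(seq_along(n), function(a)
      do.call(rbind, lapply(seq_len(n[a]), function(i)
        cohort_row(c("PEG", "NTF", "ONS")[a],
                   id = sprintf("%s%02d", c("P", "N", "O")[a], i))))))
    ps <- structure(class = "ps_fit", list(
      logit = rnorm(sum(n)), coefficients = matrix(0, 2, 1),
      reference_arm = "PEG", probabilities = NULL, covariates = "age"))
    mr <- match_triplets(coh, ps, match_config(reference_arm = "PEG"))
    ids <- c(mr$triplets$reference_id, mr$triplets$arm2_id,
             mr$triplets$arm3_id)
    expect_equal(anyDuplicated(ids), 0L)
    expect_equal(nrow(mr$triplets) + mr$n_unmatched, n[1])
    logit <- ps$logit
    for (k in seq_len(nrow(mr$triplets))) {
      i <- match(mr$triplets$reference_id[k], coh$subject_id)
      for (cc in c("arm2_id", "arm3_id")) {
        j <- match(mr$triplets[[cc]][k], coh$subject_id)
        expect_lte(abs(logit[j] - logit[i]), mr$caliper)
      }
    }
  }
})

test_that("standardized mean differences behave and flip sign on swap", {
  expect_equal(smd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(smd(c(1, 2, 3), c(2, 3, 4)), -smd(c(2, 3, 4), c(1, 2, 3)))
  expect_equal(smd(c(TRUE, FALSE), c(TRUE, FALSE)), 0)
})

test_that("matching balances arms drawn from one covariate distribution", {
  profs <- default_arm_profiles()
  same <- lapply(c("PEG", "NTF", "ONS"), function(lab) {
    p <- profs$PEG
    p$arm_label <- lab
    p$n <- 400L
    p
  })
  coh <- generate_trial(same, seed = 1)
  ps <- suppressWarnings(suppressMessages(
    fit_multinomial_ps(coh, c("age", "sex", "stage", "ecog"))))
  mr <- match_triplets(coh, ps)
  bal <- balance_table(coh, mr)
  expect_lte(max(abs(bal$smd_after)), 0.25)
  # identical arms in expectation: SMDs are pure noise both sides
  expect_lte(mean(abs(bal$smd_after)), 0.15)
})

test_that("matching improves balance on the heterogeneous default arms", {
  coh <- generate_trial(default_arm_profiles(), seed = 42)
  ps <- suppressWarnings(fit_multinomial_ps(coh, c("age", "sex", "stage",
                                                   "ecog")))
  mr <- match_triplets(coh, ps)
  bal <- balance_table(coh, mr)
  expect_lt(mean(abs(bal$smd_after)), mean(abs(bal$smd_before)))
  expect_lte(mr$max_distance, mr$caliper)
})
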