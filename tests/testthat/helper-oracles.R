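# Shared fixtures and independent oracles used across test files.

# A compact generic arm profile; override fields as needed.
small_profile <- function(arm_label = "A", n = 20,
                          weight_change_mean = -1.4, weight_change_sd = 4.4,
                          weight_category_probs = c(18, 7, 38) / 63,
                          lrfs_1yr = 0.883, os_1yr = 0.886, ...) {
  arm_profile(
    arm_label = arm_label, n = n,
    weight_change_mean = weight_change_mean,
    weight_change_sd = weight_change_sd,
    weight_category_probs = weight_category_probs,
    albumin_ge35_prob = 0.9, crp_lt15_prob = 0.6, lymph_ge1_prob = 0.2,
    response_probs = c(0.6, 0.3, 0.08, 0.02),
    lrfs_1yr = lrfs_1yr, os_1yr = os_1yr,
    cost_means = c(radiotherapy = 10000, chemotherapy = 700),
    hospital_days_mean = 11,
    age_range = c(40, 80), sex_male_prob = 0.8, ...)
}

# Minimal hand-built cohort rows for summary/comparison tests.
cohort_row <- function(arm, weight = -2, category = "loss", response = "CR",
                       id = paste0(arm, "-", sample.int(1e6, 1))) {
  data.frame(subject_id = id, arm_label = arm, age = 60, sex = "male",
             stage = "III", ecog = "0-1", baseline_weight = 58,
             weight_change_pct = weight, weight_category = category,
             albumin_ge35 = TRUE, crp_lt15 = TRUE, lymph_ge1 = FALSE,
             response = response, lrfs_time = 1, lrfs_event = FALSE,
             os_time = 1, os_event = FALSE, cost_radiotherapy = 10000,
             hospital_days = 11, stringsAsFactors = FALSE)
}

# Expand a contingency table of arm x category counts into cohort rows.
cohort_from_counts <- function(counts, categories, column = "weight_category") {
  rows <- list()
  for (a in rownames(counts)) {
    for (j in seq_along(categories)) {
      k <- counts[a, j]
      if (k == 0) next
      r <- do.call(rbind, replicate(k, cohort_row(a), simplify = FALSE))
      r[[column]] <- categories[j]
      rows[[length(rows) + 1]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$subject_id <- sprintf("S%04d", seq_len(nrow(out)))
  out
}

# Per-individual Monte Carlo microsimulation of a 3-state Markov spec:
# an independent oracle for the cohort engine's totals. Returns means and
# Monte Carlo standard errors of discounted cost and QALYs.
microsim_markov <- function(spec, n_paths = 1e5, seed = 1) {
  stopifnot(length(dim(spec$transitions)) == 2)
  withr_seed <- function(code) { # local seed, restore caller RNG
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed); code
  }
  withr_seed({
    cum <- t(apply(spec$transitions, 1, cumsum))
    state <- sample.int(3, n_paths, replace = TRUE,
                        prob = spec$initial_distribution)
    cost <- rep(spec$one_time_cost, n_paths)
    qaly <- numeric(n_paths)
    for (t in seq_len(spec$horizon_cycles)) {
      disc <- (1 + spec$discount_rate)^(-(t - 1) * spec$cycle_length)
      cost <- cost + spec$state_costs[state] * spec$cycle_length * disc
      qaly <- qaly + spec$utilities[state] * spec$cycle_length * disc
      u <- runif(n_paths)
      state <- 1L + (u > cum[cbind(state, 1)]) + (u > cum[cbind(state, 2)])
      if (all(state == 3L)) {
        # everyone dead and death carries zero reward: remaining cycles add 0
        if (spec$state_costs[3] == 0 && spec$utilities[3] == 0) break
      }
    }
    list(cost = mean(cost), qaly = mean(qaly),
         se_cost = sd(cost) / sqrt(n_paths),
         se_qaly = sd(qaly) / sqrt(n_paths))
  })
}

# Brute-force NMB frontier oracle: a strategy is on the efficiency
# frontier iff it uniquely maximizes net monetary benefit for some
# willingness-to-pay lambda >= 0. Candidate lambdas are the midpoints
# between all pairwise slopes (which is exhaustive: the argmax can only
# change at a pairwise slope), plus 0 and a dominating large value.
nmb_frontier_oracle <- function(cost, qaly, labels) {
  slopes <- c()
  n <- length(cost)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dq <- qaly[j] - qaly[i]
    if (dq != 0) {
      s <- (cost[j] - cost[i]) / dq
      if (s >= 0) slopes <- c(slopes, s)
    }
  }
  slopes <- sort(unique(slopes))
  mids <- if (length(slopes) > 1)
    (slopes[-1] + slopes[-length(slopes)]) / 2 else numeric(0)
  lambdas <- c(0, slopes / 2, mids, max(slopes, 1) * 2 + 1)
  best <- unique(vapply(lambdas, function(l) {
    nmb <- l * qaly - cost
    which(nmb == max(nmb))[1]
  }, integer(1)))
  sort(labels[best])
}

# Exhaustive minimal-total-distance 1:1:1 assignment over all
# permutations (small instances only); distances on a matching scalar.
exhaustive_triplet_oracle <- function(ref, arm2, arm3, caliper) {
  n <- length(ref)
  p2 <- gtools_permutations(n)
  best <- Inf
  for (i in seq_len(nrow(p2))) for (j in seq_len(nrow(p2))) {
    d2 <- abs(arm2[p2[i, ]] - ref)
    d3 <- abs(arm3[p2[j, ]] - ref)
    if (any(d2 > caliper) || any(d3 > caliper)) next
    tot <- sum(d2) + sum(d3)
    if (tot < best) best <- tot
  }
  best
}

# all permutations of 1..n (n small), base R
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], ncol = n - 1)))
  }
  unname(out)
}

# Hand-written multinomial logistic log-likelihood (reference category =
# first factor level), for the grid/optim oracle in the matching tests.
multinom_loglik <- function(beta_vec, X, y, K) {
  p <- ncol(X)
  B <- matrix(beta_vec, nrow = K - 1, ncol = p)
  eta <- cbind(0, X %*% t(B))
  eta <- eta - apply(eta, 1, max)
  logp <- eta - log(rowSums(exp(eta)))
  sum(logp[cbind(seq_along(y), y)])
}
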