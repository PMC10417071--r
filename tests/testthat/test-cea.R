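table3 <- data.frame(label = c("ONS", "NTF", "PEG"),
                     cost = c(27753, 28691, 35148),
                     qaly = c(4.53, 5.06, 6.93))

test_that("the three-strategy frontier yields the sequential ICERs", {
  fr <- icer_frontier(table3)
  tab <- fr$table
  expect_equal(tab$label, c("ONS", "NTF", "PEG"))
  expect_true(all(tab$on_frontier))
  expect_true(is.na(tab$icer[1]))
  expect_equal(tab$icer[2], (28691 - 27753) / (5.06 - 4.53), tolerance = 1e-12)
  expect_equal(tab$icer[3], (35148 - 28691) / (6.93 - 5.06), tolerance = 1e-12)
  expect_true(all(diff(na.omit(tab$icer)) > 0))
})

test_that("strong and extended dominance are flagged", {
  df <- rbind(table3,
              data.frame(label = "X", cost = 36000, qaly = 4.0))
  fr <- icer_frontier(df)
  x <- fr$table[fr$table$label == "X", ]
  expect_true(x$strongly_dominated)
  expect_true(is.na(x$icer))
  # a middle strategy with a worse sequential ICER than its successor
  df2 <- data.frame(label = c("A", "B", "C"),
                    cost = c(0, 900, 1000), qaly = c(0, 0.5, 1))
  fr2 <- icer_frontier(df2)
  b <- fr2$table[fr2$table$label == "B", ]
  expect_true(b$extendedly_dominated)
  expect_false(b$strongly_dominated)
  expect_equal(fr2$table$icer[fr2$table$label == "C"], 1000)
})

test_that("exact ties are broken by label order with a warning", {
  df <- data.frame(label = c("B", "A", "C"),
                   cost = c(100, 100, 200), qaly = c(1, 1, 2))
  expect_warning(fr <- icer_frontier(df), "tie")
  tab <- fr$table
  expect_equal(tab$label[1], "A")
  expect_true(tab$strongly_dominated[tab$label == "B"])
})

test_that("frontier equals the brute-force NMB oracle on random instances", {
  set.seed(99)
  for (i in 1:100) {
    n <- 5
    cost <- round(runif(n, 1e3, 5e4), 2)
    qaly <- round(runif(n, 0.5, 8), 3)
    labels <- LETTERS[1:n]
    fr <- icer_frontier(data.frame(label = labels, cost = cost, qaly = qaly))
    got <- sort(fr$table$label[fr$table$on_frontier])
    expect_equal(got, nmb_frontier_oracle(cost, qaly, labels))
  }
})

test_that("net monetary benefit is linear with slope QALYs", {
  strat <- strategy_result("PEG", 35148, 6.93)
  expect_equal(unname(net_monetary_benefit(strat, 0)), -35148)
  w <- c(2000, 7000, 31000)
  vals <- sapply(w, function(x) unname(net_monetary_benefit(strat, x)))
  expect_equal(diff(vals) / diff(w), rep(6.93, 2), tolerance = 1e-12)
  expect_error(net_monetary_benefit(strat, -5), "wtp")
})

test_that("PEG attains maximal NMB from the $5,000/QALY threshold onward", {
  grid <- seq(0, 50000, by = 5000)
  nmb <- sapply(grid, function(w) net_monetary_benefit(table3, w))
  best <- rownames(nmb)[apply(nmb, 2, which.max)]
  expect_equal(unname(nmb[, grid == 5000]),
               c(-5103, -3391, -498), tolerance = 1e-12)
  first_peg <- grid[min(which(best == "PEG"))]
  expect_equal(first_peg, 5000)
  expect_true(all(best[grid >= 5000] == "PEG"))
  expect_equal(best[1], "ONS")  # least costly wins at wtp 0
})

base_specs <- default_markov_specs()

test_that("one-way sensitivity follows closed-form ICER arithmetic", {
  pair <- c("ONS", "PEG")
  base <- sapply(base_specs[pair], function(s)
    unlist(run_markov(s)[c("total_cost", "total_qalys")]))
  base_icer <- (base[1, 2] - base[1, 1]) / (base[2, 2] - base[2, 1])
  c0 <- base_specs$ONS$one_time_cost
  tor <- one_way_sensitivity(
    base_specs,
    ranges = list("ONS/one_time_cost" = c(c0, 2 * c0),
                  "NTF/one_time_cost" = c(0.5 * base_specs$NTF$one_time_cost,
                                          2 * base_specs$NTF$one_time_cost)),
    pair = pair)
  expect_equal(attr(tor, "base_icer"), base_icer, tolerance = 1e-9)
  row <- tor[tor$parameter == "ONS/one_time_cost", ]
  # doubling the reference one-time cost shifts the ICER by -c0 / dQ
  dq <- base[2, 2] - base[2, 1]
  expect_equal(row$icer_high, base_icer - c0 / dq, tolerance = 1e-9)
  expect_equal(row$icer_low, base_icer, tolerance = 1e-12)
  # a parameter of a strategy outside the pair does not move the ICER
  ntf_row <- tor[tor$parameter == "NTF/one_time_cost", ]
  expect_equal(ntf_row$icer_range, 0, tolerance = 1e-12)
})

test_that("tornado rows come sorted by impact, whatever the input order", {
  rng <- list(
    "PEG/one_time_cost" = c(1e4, 2e4),
    "*/utilities/1" = c(0.7, 0.9),
    "ONS/transitions/1/1" = c(0.7, 0.85))
  t1 <- one_way_sensitivity(base_specs, rng, c("ONS", "PEG"))
  t2 <- one_way_sensitivity(base_specs, rev(rng), c("ONS", "PEG"))
  expect_equal(t1$parameter, t2$parameter)
  expect_true(all(diff(t1$icer_range) <= 1e-12))
  expect_error(one_way_sensitivity(base_specs,
                                   list("PEG/bogus_field" = c(0, 1)),
                                   c("ONS", "PEG")),
               "unknown field")
  expect_error(one_way_sensitivity(base_specs,
                                   list("PEG/one_time_cost" = c(1, 2)),
                                   c("ONS", "PEG")),
               "contain the base value")
})

test_that("fixed distributions collapse the PSA onto the base case", {
  dists <- list(
    param_distribution("*/utilities/1", "fixed", 0.8),
    param_distribution("PEG/one_time_cost", "fixed",
                       base_specs$PEG$one_time_cost))
  cfg <- cea_config(psa_draws = 25, seed = 3)
  psa <- run_psa(base_specs, dists, cfg)
  det <- sapply(base_specs, function(s)
    unlist(run_markov(s)[c("total_cost", "total_qalys")]))
  for (lab in colnames(psa$cost)) {
    expect_equal(unname(psa$cost[, lab]), rep(det[1, lab], 25),
                 tolerance = 1e-12)
    expect_equal(unname(psa$qaly[, lab]), rep(det[2, lab], 25),
                 tolerance = 1e-12)
  }
  # degenerate CEAC: all mass on the NMB maximizer at every threshold
  expect_true(all(psa$ceac %in% c(0, 1)))
  best <- colnames(det)[which.max(50000 * det[2, ] - det[1, ])]
  expect_equal(unname(psa$ceac[nrow(psa$ceac), best]), 1)
})

test_that("CEAC rows partition the draws and the PSA is seed-stable", {
  cfg <- cea_config(psa_draws = 120, seed = 11)
  psa1 <- run_psa(base_specs, config = cfg)
  psa2 <- run_psa(base_specs, config = cfg)
  expect_identical(psa1$cost, psa2$cost)
  expect_identical(psa1$ceac, psa2$ceac)
  expect_equal(unname(rowSums(psa1$ceac)),
               rep(1, length(cfg$wtp_grid)), tolerance = 1e-12)
  psa3 <- run_psa(base_specs, config = cea_config(psa_draws = 120, seed = 12))
  expect_false(identical(psa1$cost, psa3$cost))
})

test_that("CEAC estimates are stable within binomial noise when halving draws", {
  psa_big <- run_psa(base_specs, config = cea_config(psa_draws = 400, seed = 5))
  psa_half <- run_psa(base_specs, config = cea_config(psa_draws = 200, seed = 6))
  p <- psa_big$ceac
  se <- sqrt(pmax(p * (1 - p), 0.25 / 400) / 200)
  expect_true(all(abs(psa_half$ceac - p) <= 3 * se + 1e-12))
})

test_that("beta and gamma PSA distributions hit their moments", {
  set.seed(4)
  b <- param_distribution("*/utilities/1", "beta", 0.8, rel_sd = 0.1)
  draws <- nutricea:::sample_param(b, 2e4)
  expect_lt(abs(mean(draws) - 0.8), 0.002)
  expect_lt(abs(sd(draws) - 0.08), 0.002)
  g <- param_distribution("PEG/one_time_cost", "gamma", 1000, rel_sd = 0.3)
  gd <- nutricea:::sample_param(g, 2e4)
  expect_lt(abs(mean(gd) - 1000) / 1000, 0.01)
  expect_lt(abs(sd(gd) - 300) / 300, 0.05)
  expect_error(param_distribution("*/utilities/1", "beta", 1.2), "mean in")
  expect_error(param_distribution("*/utilities/1", "beta", 0.99,
                                  rel_sd = 0.5), "variance")
})

test_that("acceptability report identifies the preferred strategy", {
  # strategies engineered to reproduce the published cost/QALY triple:
  # 10 undiscounted cycles of an absorbing alive state
  mk <- function(lab, cost, qaly) {
    markov_spec(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                state_costs = c(0, 0, 0), one_time_cost = cost,
                utilities = c(qaly / 10, 0.5, 0), discount_rate = 0,
                horizon_cycles = 10, label = lab)
  }
  specs <- list(ONS = mk("ONS", 27753, 4.53), NTF = mk("NTF", 28691, 5.06),
                PEG = mk("PEG", 35148, 6.93))
  dists <- list(
    param_distribution("ONS/utilities/1", "beta", 0.453, rel_sd = 0.02),
    param_distribution("NTF/utilities/1", "beta", 0.506, rel_sd = 0.02),
    param_distribution("PEG/utilities/1", "beta", 0.693, rel_sd = 0.02),
    param_distribution("PEG/one_time_cost", "gamma", 35148, rel_sd = 0.02))
  cfg <- cea_config(psa_draws = 200, seed = 8)
  psa <- run_psa(specs, dists, cfg)
  rep <- acceptability_report(psa, cfg)
  expect_equal(sum(rep$table[, "wtp_10000"]), 1, tolerance = 1e-12)
  expect_equal(sum(rep$table[, "wtp_50000"]), 1, tolerance = 1e-12)
  # with small noise around the published values PEG dominates at $10,000
  expect_equal(rep$preferred, "PEG")
  expect_gt(rep$table["PEG", "wtp_10000"], 0.95)
  # degenerate PSA: the preferred strategy has probability 1
  fixed <- list(param_distribution("PEG/one_time_cost", "fixed", 35148))
  psa0 <- run_psa(specs, fixed, cea_config(psa_draws = 10, seed = 1))
  rep0 <- acceptability_report(psa0, cfg)
  expect_equal(max(rep0$table[, "wtp_10000"]), 1)
})
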