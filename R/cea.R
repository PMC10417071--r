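# Normalise heterogeneous strategy inputs (markov_result, strategy_result,
# or a data.frame with label/cost/qaly columns) to one data frame.
strategy_table <- function(results) {
  if (is.data.frame(results)) {
    nm <- names(results)
    lab <- results[[intersect(c("label", "strategy", "strategy_label"), nm)[1]]]
    cost <- results[[intersect(c("cost", "total_cost"), nm)[1]]]
    qaly <- results[[intersect(c("qaly", "qalys", "total_qalys"), nm)[1]]]
    return(data.frame(label = as.character(lab), cost = cost, qaly = qaly,
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(results, function(r) {
    if (inherits(r, "markov_result"))
      data.frame(label = r$label %||% "strategy", cost = r$total_cost,
                 qaly = r$total_qalys, stringsAsFactors = FALSE)
    else if (inherits(r, "strategy_result"))
      data.frame(label = r$strategy_label, cost = r$total_cost,
                 qaly = r$total_qalys, stringsAsFactors = FALSE)
    else
      data.frame(label = as.character(r[["label"]]), cost = r[["cost"]],
                 qaly = r[["qaly"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' ICER efficiency frontier with dominance handling
#'
#' Orders strategies by ascending cost, removes strongly dominated
#' strategies (at least as costly and no more effective than another, with
#' one inequality strict), then iteratively removes extendedly dominated
#' strategies (those whose sequential incremental cost-effectiveness ratio
#' exceeds that of the next, more effective frontier member) until the
#' sequential ICERs strictly increase. The cheapest frontier member is the
#' reference and carries no ICER. Exact cost-and-QALY ties are broken by
#' label order and flagged.
#'
#' @param results list of [run_markov()] / [strategy_result()] objects, or
#'   a data frame with label/cost/qaly columns.
#' @return object of class `frontier_result`: a data frame `table` (label,
#'   cost, qaly, strongly_dominated, extendedly_dominated, on_frontier,
#'   icer) sorted by ascending cost, plus `tie_flag`.
#' @examples
#' tab <- data.frame(label = c("ONS", "NTF", "PEG"),
#'                   cost = c(27753, 28691, 35148),
#'                   qaly = c(4.53, 5.06, 6.93))
#' icer_frontier(tab)
#' @export
icer_frontier <- function(results) {
  df <- strategy_table(results)
  assert_that(nrow(df) >= 2, "need at least two strategies")
  assert_that(!anyDuplicated(df$label), "strategy labels must be distinct")
  assert_that(all(is.finite(df$cost)) && all(is.finite(df$qaly)),
              "costs and QALYs must be finite")
  tie_flag <- anyDuplicated(df[, c("cost", "qaly")]) > 0
  if (tie_flag) warning("exact cost-and-QALY ties; broken by label order")
  df <- df[order(df$cost, -df$qaly, df$label), , drop = FALSE]
  n <- nrow(df)
  strongly <- vapply(seq_len(n), function(i) {
    any(df$cost <= df$cost[i] & df$qaly >= df$qaly[i] &
          (df$cost < df$cost[i] | df$qaly > df$qaly[i]))
  }, logical(1))
  # exact duplicates: the label-later copy is treated as dominated
  strongly <- strongly | duplicated(df[, c("cost", "qaly")])
  extendedly <- rep(FALSE, n)
  repeat {
    cand <- which(!strongly & !extendedly)
    if (length(cand) < 3) break
    icers <- diff(df$cost[cand]) / diff(df$qaly[cand])
    worse <- which(diff(icers) <= 0)   # ICER not strictly increasing
    if (!length(worse)) break
    extendedly[cand[worse[1] + 1]] <- TRUE
  }
  on_frontier <- !strongly & !extendedly
  icer <- rep(NA_real_, n)
  fr <- which(on_frontier)
  if (length(fr) > 1)
    icer[fr[-1]] <- diff(df$cost[fr]) / diff(df$qaly[fr])
  out <- data.frame(df, strongly_dominated = strongly,
                    extendedly_dominated = extendedly,
                    on_frontier = on_frontier, icer = icer,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(class = "frontier_result", list(table = out, tie_flag = tie_flag))
}

#' @export
print.frontier_result <- function(x, ...) {
  cat("Cost-effectiveness frontier\n")
  tab <- x$table
  tab$cost <- round(tab$cost, 2)
  tab$qaly <- round(tab$qaly, 4)
  tab$icer <- round(tab$icer, 2)
  tab$status <- ifelse(tab$on_frontier, "frontier",
                       ifelse(tab$strongly_dominated, "dominated",
                              "ext. dominated"))
  print(tab[, c("label", "cost", "qaly", "status", "icer")],
        row.names = FALSE)
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = wtp x QALYs - cost` for one or several strategies at a
#' willingness-to-pay threshold.
#'
#' @param result a single [strategy_result()]/[run_markov()] result, a
#'   list of them, or a data frame with label/cost/qaly columns.
#' @param wtp willingness to pay (USD per QALY), `>= 0`.
#' @return named numeric vector of NMB values (USD).
#' @export
net_monetary_benefit <- function(result, wtp) {
  assert_that(is.numeric(wtp) && length(wtp) == 1 && wtp >= 0,
              "wtp must be a single value >= 0")
  if (inherits(result, c("strategy_result", "markov_result")))
    result <- list(result)
  df <- strategy_table(result)
  stats::setNames(wtp * df$qaly - df$cost, df$label)
}

# --- parameter paths -------------------------------------------------------
# "<strategy|*>/<field>[/i[/j]]", e.g. "PEG/one_time_cost",
# "*/utilities/2", "NTF/transitions/1/3". Transition entries are reset and
# the rest of the row rebalanced proportionally (death row untouched).

parse_param_path <- function(path) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  assert_that(length(parts) >= 2, "bad parameter path: ", path)
  list(strategy = parts[1], field = parts[2],
       index = if (length(parts) > 2) as.integer(parts[-(1:2)]) else NULL)
}

get_param <- function(specs, path) {
  p <- parse_param_path(path)
  labs <- if (p$strategy == "*") names(specs) else p$strategy
  assert_that(all(labs %in% names(specs)),
              "unknown strategy in parameter path: ", path)
  spec <- specs[[labs[1]]]
  assert_that(p$field %in% names(spec), "unknown field in path: ", path)
  v <- spec[[p$field]]
  if (p$field == "transitions" && length(p$index) == 2)
    return(v[p$index[1], p$index[2]])
  if (!is.null(p$index)) return(v[[p$index[1]]])
  v
}

# clamp an entry into [0,1] and rebalance the remainder of its row over the
# other entries, proportionally to their current values. Returns list(m,
# clamped) where clamped flags an out-of-range draw.
set_transition_entry <- function(m, i, j, value) {
  clamped <- value < 0 || value > 1
  v <- min(max(value, 0), 1)
  other <- setdiff(1:3, j)
  rest <- m[i, other]
  if (sum(rest) > 0) {
    m[i, other] <- rest / sum(rest) * (1 - v)
  } else {
    m[i, other] <- (1 - v) / length(other)
  }
  m[i, j] <- v
  list(m = m, clamped = clamped)
}

apply_param <- function(specs, path, value) {
  p <- parse_param_path(path)
  labs <- if (p$strategy == "*") names(specs) else p$strategy
  assert_that(all(labs %in% names(specs)),
              "unknown strategy in parameter path: ", path)
  clamped <- FALSE
  for (lab in labs) {
    spec <- specs[[lab]]
    assert_that(p$field %in% names(spec), "unknown field in path: ", path)
    if (p$field == "transitions" && length(p$index) == 2) {
      res <- set_transition_entry(spec$transitions, p$index[1], p$index[2],
                                  value)
      spec$transitions <- res$m
      clamped <- clamped || res$clamped
    } else if (!is.null(p$index)) {
      spec[[p$field]][p$index[1]] <- value
    } else {
      spec[[p$field]] <- value
    }
    specs[[lab]] <- spec
  }
  attr(specs, "clamped") <- clamped
  specs
}

#' One-way (tornado) sensitivity analysis of an ICER
#'
#' Recomputes the pairwise ICER of two strategies with each parameter set
#' to its lower and upper bound in turn, all other parameters held at
#' base-case values. Rows are sorted by descending ICER range, the order
#' used in a tornado diagram.
#'
#' Parameter paths take the form `"<strategy|*>/<field>[/i[/j]]"`, e.g.
#' `"PEG/one_time_cost"`, `"*/utilities/1"` (all strategies' disease-free
#' utility) or `"NTF/transitions/1/3"` (a transition entry; its row is
#' rebalanced proportionally).
#'
#' @param base_specs named list of [markov_spec()] objects.
#' @param ranges named list: names are parameter paths, values are
#'   `c(low, high)` bounds containing the base value.
#' @param pair length-2 character vector `c(reference, comparator)`; the
#'   ICER is (comparator - reference) cost over QALYs.
#' @return object of class `tornado`: data frame with `parameter`, `base`,
#'   `low`, `high`, `icer_low`, `icer_high`, `icer_range`, plus
#'   `base_icer`.
#' @export
one_way_sensitivity <- function(base_specs, ranges, pair) {
  assert_that(length(pair) == 2 && all(pair %in% names(base_specs)),
              "pair must name two strategies in base_specs")
  assert_that(length(ranges) >= 1 && !is.null(names(ranges)),
              "ranges must be a named list of c(low, high)")
  pair_icer <- function(specs) {
    a <- markov_totals(specs[[pair[1]]])
    b <- markov_totals(specs[[pair[2]]])
    unname((b["cost"] - a["cost"]) / (b["qaly"] - a["qaly"]))
  }
  base_icer <- pair_icer(base_specs)
  rows <- lapply(names(ranges), function(path) {
    r <- ranges[[path]]
    assert_that(length(r) == 2 && all(is.finite(r)) && r[1] <= r[2],
                "range for ", path, " must be finite c(low, high)")
    base <- get_param(base_specs, path)
    assert_that(base >= r[1] && base <= r[2],
                "range for ", path, " must contain the base value ", base)
    lo <- pair_icer(apply_param(base_specs, path, r[1]))
    hi <- pair_icer(apply_param(base_specs, path, r[2]))
    data.frame(parameter = path, base = base, low = r[1], high = r[2],
               icer_low = lo, icer_high = hi,
               icer_range = abs(hi - lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$icer_range, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  structure(class = c("tornado", "data.frame"), out,
            base_icer = base_icer, pair = pair)
}

#' @export
plot.tornado <- function(x, ...) {
  n <- nrow(x)
  ord <- rev(seq_len(n))          # widest bar on top
  lo <- pmin(x$icer_low, x$icer_high)
  hi <- pmax(x$icer_low, x$icer_high)
  graphics::plot(NULL, xlim = range(c(lo, hi, attr(x, "base_icer"))),
                 ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "ICER (USD/QALY)", ylab = "", ...)
  graphics::axis(2, at = seq_len(n), labels = x$parameter[ord], las = 1,
                 cex.axis = 0.7)
  graphics::rect(lo[ord], seq_len(n) - 0.35, hi[ord], seq_len(n) + 0.35,
                 col = "steelblue", border = NA)
  graphics::abline(v = attr(x, "base_icer"), lty = 2)
  invisible(x)
}
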