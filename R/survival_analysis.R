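#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function from right-censored
#' times, computed with [survival::survfit()]. Ties between events and
#' censorings at the same time are handled in the conventional way: events
#' precede censorings. The returned object keeps only the event times (the
#' step locations) together with the post-jump survival, the number at risk
#' and the number of events at each.
#'
#' @param times non-negative follow-up times (years).
#' @param events logical (or 0/1) event indicators, `TRUE` = event.
#' @return object of class `km_estimate` with fields `event_times`,
#'   `survival_probs`, `at_risk`, `events`, `n`.
#' @seealso [survival_at()]
#' @export
km_estimate <- function(times, events) {
  assert_that(length(times) > 0, "times must be non-empty")
  assert_that(length(times) == length(events),
              "times and events must have equal length")
  assert_that(is.numeric(times) && all(is.finite(times)) && all(times >= 0),
              "times must be finite and >= 0")
  events <- as.logical(events)
  assert_that(!anyNA(events), "events must be logical")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  structure(class = "km_estimate", list(
    event_times = fit$time[keep],
    survival_probs = fit$surv[keep],
    at_risk = fit$n.risk[keep],
    events = fit$n.event[keep],
    n = length(times)))
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate, n =", x$n, ",",
      sum(x$events), "events at", length(x$event_times), "distinct times\n")
  if (length(x$event_times)) {
    df <- data.frame(time = x$event_times, n.risk = x$at_risk,
                     n.event = x$events, survival = x$survival_probs)
    print(utils::head(df, 10), row.names = FALSE)
    if (nrow(df) > 10) cat("  ...", nrow(df) - 10, "more rows\n")
  }
  invisible(x)
}

#' @export
plot.km_estimate <- function(x, xlab = "Years", ylab = "Survival", ...) {
  tt <- c(0, x$event_times)
  ss <- c(1, x$survival_probs)
  plot(tt, ss, type = "s", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function evaluation: `S(0) = 1`, the value at an
#' event time is the post-jump survival, and the curve extends flat beyond
#' the last event.
#'
#' @param est a [km_estimate()].
#' @param t non-negative evaluation times (vectorised).
#' @return survival probabilities at `t`.
#' @export
survival_at <- function(est, t) {
  assert_that(inherits(est, "km_estimate"), "est must be a km_estimate")
  assert_that(is.numeric(t) && all(is.finite(t)) && all(t >= 0),
              "t must be finite and >= 0")
  c(1, est$survival_probs)[findInterval(t, est$event_times) + 1]
}
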