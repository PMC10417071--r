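#' Power of a one-sample t-test
#'
#' Exact power of the one-sided one-sample t-test of H0: mu = `null_mean`
#' against the alternative mu = `alt_mean`, computed from the noncentral t
#' distribution: with effect d = |alt - null| / sd and critical value
#' t* = qt(1 - alpha, n - 1), power = P(T > t*) for T noncentral t with
#' n - 1 degrees of freedom and noncentrality sqrt(n) d. Setting
#' `exact = FALSE` uses the normal approximation
#' power = Phi(sqrt(n) d - z_(1-alpha)) instead, which is useful as an
#' independent cross-check (it typically understates the required n by 1-2
#' subjects).
#'
#' @param n sample size (may be a vector).
#' @param null_mean,alt_mean null and alternative means (any unit; the
#'   trial design uses percent weight change).
#' @param sd assumed standard deviation (same unit).
#' @param alpha_one_sided one-sided significance level.
#' @param exact use the noncentral-t computation (default) or the normal
#'   approximation.
#' @return power in `[0, 1]`, vectorised over `n`.
#' @export
power_one_sample_t <- function(n, null_mean, alt_mean, sd,
                               alpha_one_sided = 0.025, exact = TRUE) {
  assert_that(all(n >= 2), "n must be >= 2")
  assert_that(sd > 0, "sd must be > 0")
  assert_that(alpha_one_sided > 0 && alpha_one_sided < 0.5,
              "alpha_one_sided must lie in (0, 0.5)")
  assert_that(null_mean != alt_mean, "null_mean and alt_mean must differ")
  d <- abs(alt_mean - null_mean) / sd
  if (exact) {
    pt(qt(1 - alpha_one_sided, n - 1), n - 1, ncp = sqrt(n) * d,
       lower.tail = FALSE)
  } else {
    pnorm(sqrt(n) * d - qnorm(1 - alpha_one_sided))
  }
}

#' Required sample size for the weight-change endpoint
#'
#' Smallest n at which the one-sided one-sample t-test of the null mean
#' against the alternative attains the requested power (see
#' [power_one_sample_t()]). The shipped trial design — detecting a mean
#' weight change of −3\% against a null of −5\% with SD 5\%, one-sided
#' alpha 0.025 and power 0.80 — requires 52 evaluable patients.
#'
#' @inheritParams power_one_sample_t
#' @param power target power in (0, 1).
#' @return integer sample size.
#' @examples
#' required_sample_size(-5, -3, 5)                  # 52
#' planned_enrollment(required_sample_size(-5, -3, 5), 0.15)  # 62
#' @export
required_sample_size <- function(null_mean = -5, alt_mean = -3, sd = 5,
                                 alpha_one_sided = 0.025, power = 0.80,
                                 exact = TRUE) {
  assert_that(power > 0 && power < 1, "power must lie in (0, 1)")
  pw <- function(n) power_one_sample_t(n, null_mean, alt_mean, sd,
                                       alpha_one_sided, exact)
  n <- 2
  while (pw(n) < power) {
    assert_that(n < 1e7, "sample size search exceeded 1e7")
    n <- n + 1
  }
  as.integer(n)
}

#' Inflate a sample size for anticipated dropout
#'
#' `ceiling(n / (1 - dropout_rate))`: the planned enrollment needed so that
#' `n` evaluable patients remain after losing a fraction `dropout_rate`.
#'
#' @param n evaluable sample size.
#' @param dropout_rate anticipated dropout fraction in `[0, 1)`.
#' @return integer planned enrollment.
#' @export
planned_enrollment <- function(n, dropout_rate) {
  assert_that(is.numeric(n) && n >= 0 && n == floor(n),
              "n must be a non-negative integer")
  assert_that(is.numeric(dropout_rate) && dropout_rate >= 0 &&
                dropout_rate < 1, "dropout_rate must lie in [0, 1)")
  as.integer(ceiling(n / (1 - dropout_rate)))
}
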