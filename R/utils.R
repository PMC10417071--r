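# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("nutricea_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_invalid(...)
  invisible(TRUE)
}

assert_prob <- function(x, name, lo = 0, hi = 1) {
  assert_that(is.numeric(x) && all(is.finite(x)) && all(x >= lo) && all(x <= hi),
              name, " must lie in [", lo, ", ", hi, "]")
}

assert_prob_vector <- function(p, name, tol = 1e-9) {
  assert_prob(p, name)
  assert_that(abs(sum(p) - 1) <= tol, name, " must sum to 1 (got ", sum(p), ")")
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-seed for a labelled stream, invariant to calling order.
# Polynomial string hash folded into the master seed, kept below 2^31.
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 31 + k) %% 2147483587L
  as.integer((as.numeric(seed) %% 2147483587 * 69621 + h) %% 2147483587 + 1)
}

# Inverse-CDF sampler for a normal truncated to (lo, hi); vectorised in n.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# Gamma draws parameterised by mean and coefficient of variation.
rgamma_cv <- function(n, mean, cv) {
  if (mean <= 0) return(rep(0, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, rate = shape / mean)
}
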