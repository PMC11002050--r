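# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# session RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage-specific seed from a global one, kept within 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nutrispec <- function(...) stop(..., call. = FALSE)

assert_matrix_like <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_nutrispec(sprintf("`%s` must be a numeric matrix", what))
  }
  if (anyNA(x)) stop_nutrispec(sprintf("`%s` contains missing values", what))
  invisible(x)
}

# Mean of a normal(mu, sd) truncated to [lo, hi].
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  if (z < .Machine$double.eps) {
    # Entire mass outside the window: collapse to nearest bound.
    return(if (mu < lo) lo else hi)
  }
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Quantile function of the truncated normal, vectorised over p.
truncnorm_quantile <- function(p, mu, sd, lo, hi) {
  pa <- stats::pnorm(lo, mean = mu, sd = sd)
  pb <- stats::pnorm(hi, mean = mu, sd = sd)
  q <- stats::qnorm(pa + p * (pb - pa), mean = mu, sd = sd)
  pmin(pmax(q, lo), hi)
}

# Gauss-Hermite nodes/weights rescaled for expectations under N(0, 1),
# via the Golub-Welsch eigenvalue construction (no tables).
gauss_hermite_normal <- function(n = 24L) {
  k <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- sqrt(k / 2)
  J[cbind(k + 1, k)] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = sqrt(2) * e$values, weights = e$vectors[1, ]^2)
}

# Solve for the location parameter mu such that the [lo, hi]-truncated
# normal with scale `sd` has expectation `target`.
truncnorm_calibrate <- function(target, sd, lo, hi) {
  if (target <= lo || target >= hi) {
    stop_nutrispec("target mean must lie strictly inside (lo, hi)")
  }
  f <- function(mu) truncnorm_mean(mu, sd, lo, hi) - target
  span <- hi - lo
  lower <- lo - 12 * sd - span
  upper <- hi + 12 * sd + span
  stats::uniroot(f, lower = lower, upper = upper, tol = 1e-10)$root
}
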