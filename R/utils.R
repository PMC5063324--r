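# Internal helpers shared across modules.

# Draw from an inverse-gamma(shape, scale) distribution, parameterized so that
# the density is proportional to x^-(shape+1) exp(-scale/x) and the mean is
# scale / (shape - 1) for shape > 1.
rinvgamma <- function(n, shape, scale) {
  1 / stats::rgamma(n, shape = shape, rate = scale)
}

# Cholesky factor with a relative diagonal jitter; errors if the matrix cannot
# be factorized even after jitter (typically duplicated sites).
chol_jitter <- function(m, jitter = 1e-8) {
  eps <- jitter * mean(diag(m))
  out <- tryCatch(chol(m + diag(eps, nrow(m))), error = function(e) NULL)
  if (is.null(out)) {
    abort(paste0(
      "Covariance matrix is not positive definite even after jitter; ",
      "check for duplicated (coincident) sites."
    ))
  }
  out
}

# Draw from N(mean, cov) given the upper Cholesky factor of cov.
rmvnorm_chol <- function(chol_upper, mean = 0) {
  drop(mean + crossprod(chol_upper, stats::rnorm(nrow(chol_upper))))
}

# Split-chain potential scale reduction factor for a single scalar chain.
split_rhat <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  chains <- cbind(x[seq_len(half)], x[(n - half + 1):n])
  m <- ncol(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w <= 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# Month-day ("MM-DD") helpers for the seasonal filter.
month_day <- function(date) format(date, "%m-%d")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %g is outside its allowed range.", name, x))
  }
  invisible(x)
}
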