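#' Power of the fixed-effects F test for multiple regression
#'
#' Statistical power for testing that a set of predictors explains no
#' variance, using the noncentral F distribution with numerator degrees of
#' freedom equal to the number of predictors, denominator degrees of
#' freedom `N - n_predictors - 1`, and noncentrality `lambda = f2 * N`
#' (the fixed-model "R-squared deviation from zero" convention, matching
#' G*Power; other lambda conventions exist and can shift the required N by
#' one or two).
#'
#' @param n_predictors number of predictors.
#' @param f2 Cohen's effect size f-squared (> 0 for a noncentral test).
#' @param alpha significance level.
#' @param N total sample size; must exceed `n_predictors + 1`.
#' @return the power (probability of rejecting the null).
#' @export
power_at <- function(n_predictors, f2, alpha, N) {
  stopifnot(f2 >= 0, alpha > 0, alpha < 1, N > n_predictors + 1)
  df1 <- n_predictors
  df2 <- N - n_predictors - 1
  crit <- qf(1 - alpha, df1, df2)
  1 - pf(crit, df1, df2, ncp = f2 * N)
}

#' Minimum sample size for target power
#'
#' Smallest integer N for which [power_at()] reaches the target power; the
#' power curve is non-decreasing in N, so the minimum is found by doubling
#' then bisection.
#'
#' @inheritParams power_at
#' @param power target power in (0, 1).
#' @param n_cap search ceiling; an error is raised if the target is not
#'   reachable below it.
#' @return the minimum required N.
#' @export
required_sample_size <- function(n_predictors, f2, alpha = 0.05,
                                 power = 0.95, n_cap = 1e6) {
  stopifnot(f2 > 0, power > 0, power < 1)
  lo <- as.integer(n_predictors + 2)
  if (power_at(n_predictors, f2, alpha, lo) >= power) return(lo)
  hi <- lo
  repeat {
    hi <- min(hi * 2, n_cap)
    if (power_at(n_predictors, f2, alpha, hi) >= power) break
    if (hi >= n_cap) stop("target power not reachable below n_cap = ", n_cap)
  }
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (power_at(n_predictors, f2, alpha, mid) >= power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}
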