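# Effect-size conversions and noncentral-F power machinery for the
# within-between interaction family of repeated-measures designs.

#' Convert between Cohen's f and eta squared
#'
#' `eta2 = f^2 / (1 + f^2)` and `f = sqrt(eta2 / (1 - eta2))`; exact
#' round-trip inverses.
#'
#' @param f Cohen's f, nonnegative.
#' @return `eta2_from_f`: eta squared in `[0, 1)`.
#' @export
eta2_from_f <- function(f) {
  stopifnot(all(f >= 0))
  f^2 / (1 + f^2)
}

#' @rdname eta2_from_f
#' @param eta2 eta squared in `[0, 1)`.
#' @return `f_from_eta2`: Cohen's f.
#' @export
f_from_eta2 <- function(eta2) {
  if (any(eta2 < 0 | eta2 >= 1)) stop("eta2 must be in [0, 1)", call. = FALSE)
  sqrt(eta2 / (1 - eta2))
}

#' Partial eta squared from an F statistic
#'
#' `etap2 = F * df1 / (F * df1 + df2)`, the standard recovery of partial eta
#' squared from a printed F ratio and its degrees of freedom.
#'
#' @param F_value F statistic, nonnegative.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return Partial eta squared.
#' @export
partial_eta_sq_from_F <- function(F_value, df1, df2) {
  stopifnot(all(F_value >= 0), all(df1 >= 1), all(df2 >= 1))
  F_value * df1 / (F_value * df1 + df2)
}

#' Correlation effect size from a single-df F statistic
#'
#' `r = sqrt(F / (F + df2))`, valid only for `df1 = 1` designs (where F is a
#' squared t).
#'
#' @param F_value F statistic with one numerator degree of freedom.
#' @param df2 denominator degrees of freedom.
#' @param df1 numerator df; anything but 1 is rejected.
#' @return Effect-size r.
#' @export
r_from_F <- function(F_value, df2, df1 = 1) {
  if (any(df1 != 1)) stop("r_from_F supports df1 = 1 designs only", call. = FALSE)
  stopifnot(all(F_value >= 0), all(df2 >= 1))
  sqrt(F_value / (F_value + df2))
}

#' Specification of a repeated-measures interaction power problem
#'
#' Describes the within-between interaction design used when a sensitivity
#' analysis treats one repeated-measures factor as between-groups: `k`
#' groups, `m` repeated measurements, total `N`, mean correlation `rho`
#' among the repeated measures, type-I rate `alpha`, target power, and
#' nonsphericity `epsilon` (fixed at 1 for two-level factors).
#'
#' @param N total sample size (`N > k`).
#' @param k number of groups (default 2).
#' @param m number of repeated measurements (default 2).
#' @param rho mean correlation among repeated measures, in `(-1, 1)`.
#' @param alpha type-I error rate (default 0.05).
#' @param power target power (default 0.80).
#' @param epsilon nonsphericity correction (default 1).
#' @return List of class `power_spec`.
#' @export
power_spec <- function(N, k = 2, m = 2, rho, alpha = 0.05, power = 0.80,
                       epsilon = 1) {
  stopifnot(N > k, m >= 2, k >= 2,
            rho > -1, rho < 1,
            alpha > 0, alpha < 1, power > 0, power < 1,
            epsilon > 0, epsilon <= 1)
  structure(
    list(N = N, k = k, m = m, rho = rho, alpha = alpha, power = power,
         epsilon = epsilon),
    class = "power_spec"
  )
}

#' Power of the within-between interaction test
#'
#' Noncentral-F power under the G*Power repeated-measures convention:
#' noncentrality `lambda = f^2 * N * m / (1 - rho) * epsilon`,
#' `df1 = (k - 1)(m - 1)`, `df2 = (N - k)(m - 1)`, and
#' `power = P(F' > F_crit)` for `F' ~ F(df1, df2, lambda)`. The
#' `"spss"` convention treats f as already folding in the correlation
#' structure (`lambda = f^2 * N * epsilon`).
#'
#' @param f Cohen's f for the interaction.
#' @param spec a [power_spec()].
#' @param convention `"gpower"` (default) or `"spss"`.
#' @return Achieved power.
#' @export
rm_interaction_power <- function(f, spec, convention = c("gpower", "spss")) {
  convention <- match.arg(convention)
  stopifnot(inherits(spec, "power_spec"), all(f >= 0))
  df1 <- (spec$k - 1) * (spec$m - 1)
  df2 <- (spec$N - spec$k) * (spec$m - 1)
  lambda <- switch(convention,
    gpower = f^2 * spec$N * spec$m / (1 - spec$rho) * spec$epsilon,
    spss = f^2 * spec$N * spec$epsilon
  )
  f_crit <- stats::qf(1 - spec$alpha, df1, df2)
  stats::pf(f_crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Minimal detectable effect size (sensitivity analysis)
#'
#' Solves `rm_interaction_power(f) = power` for f by bisection to a power
#' residual below `tol`. Power is strictly increasing in f, so the root is
#' unique.
#'
#' @param spec a [power_spec()] with the target `power` set.
#' @param convention passed to [rm_interaction_power()].
#' @param f_max upper end of the search bracket (default 5).
#' @param tol power-residual tolerance (default 1e-8).
#' @return The minimal Cohen's f detectable at the requested power.
#' @export
sensitivity_f <- function(spec, convention = "gpower", f_max = 5, tol = 1e-8) {
  stopifnot(inherits(spec, "power_spec"))
  target <- spec$power
  lo <- 0
  hi <- f_max
  p_lo <- rm_interaction_power(lo, spec, convention)  # = alpha
  p_hi <- rm_interaction_power(hi, spec, convention)
  if (p_lo > target || p_hi < target) {
    stop(sprintf("search range [0, %g] does not bracket power %.3f", f_max, target),
         call. = FALSE)
  }
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    p_mid <- rm_interaction_power(mid, spec, convention)
    if (abs(p_mid - target) < tol) return(mid)
    if (p_mid < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Required sample size for the interaction test
#'
#' Smallest integer N (multiple of nothing; groups assumed equal-n in spirit
#' only) achieving the spec's target power at effect size `f`.
#'
#' @param f assumed Cohen's f.
#' @param spec a [power_spec()]; its `N` is ignored.
#' @param convention passed to [rm_interaction_power()].
#' @param n_max search ceiling.
#' @return Integer sample size.
#' @export
required_n <- function(f, spec, convention = "gpower", n_max = 100000L) {
  stopifnot(f > 0)
  for (N in seq.int(spec$k + 1L, n_max)) {
    s <- power_spec(N, spec$k, spec$m, spec$rho, spec$alpha, spec$power, spec$epsilon)
    if (rm_interaction_power(f, s, convention) >= spec$power) return(N)
  }
  stop("no N below n_max reaches the target power", call. = FALSE)
}
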