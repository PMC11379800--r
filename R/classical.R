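#' Power of the fixed-N two-sample t test
#'
#' Exact power of the equal-allocation, pooled-variance two-sample t test at
#' two-sided level `alpha`, from the noncentral-t distribution with
#' noncentrality `d * sqrt(n / 2)` and `2n - 2` degrees of freedom.
#'
#' @param n Per-arm sample size.
#' @param d True standardized effect (Cohen's d).
#' @param alpha Two-sided significance level.
#' @return Power (fraction).
#' @export
power_two_sample_t <- function(n, d, alpha = 0.05) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  df <- 2 * n - 2
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n / 2)
  stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
}

#' Fixed-N per-arm sample size for a two-arm trial
#'
#' Smallest integer per-arm n giving the two-sample pooled t test at two-sided
#' level `alpha` power at least `power` for effect size `d`, by direct
#' noncentral-t iteration (not the Normal approximation, which can be off by
#' one). This is the classical benchmark a leapfrog design's expected sample
#' sizes are compared against: e.g. detecting d = 0.2 with 80% power at
#' alpha = 0.05 needs 394 per arm.
#'
#' @param d Target effect size (nonzero).
#' @param power Target power (fraction).
#' @param alpha Two-sided significance level.
#' @return Integer per-arm sample size.
#' @examples
#' sample_size_two_arm(0.2)        # 394
#' sample_size_two_arm(0.5)        # 64
#' @export
sample_size_two_arm <- function(d, power = 0.80, alpha = 0.05) {
  if (!is.numeric(d) || length(d) != 1L || d == 0 || !is.finite(d)) {
    stop_leapfrog("validation", "d must be a single nonzero effect size")
  }
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1) {
    stop_leapfrog("validation", "power and alpha must lie strictly in (0, 1)")
  }
  d <- abs(d)
  # Normal-approximation start, then exact noncentral-t adjustment
  n <- max(2, floor(2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 /
                      d^2) - 5)
  while (power_two_sample_t(n, d, alpha) < power) n <- n + 1
  while (n > 2 && power_two_sample_t(n - 1, d, alpha) >= power) n <- n - 1
  as.integer(n)
}

#' Total participants across a sequence of fixed-N trials
#'
#' Arithmetic for the classical treatment-development route: the total number
#' randomized across a series of fixed-N trials, each arm at `per_arm_n`.
#' Testing five challengers as a series of two-arm trials at 394/arm costs
#' 3,940 participants; as a 4-arm plus a 3-arm trial, 2,758.
#'
#' @param arms_per_trial Integer vector, number of arms in each trial.
#' @param per_arm_n Per-arm sample size.
#' @return Total participants.
#' @examples
#' cumulative_cost(2, 394)          # 788
#' cumulative_cost(c(4, 3), 394)    # 2758
#' cumulative_cost(rep(2, 5), 394)  # 3940
#' @export
cumulative_cost <- function(arms_per_trial, per_arm_n) {
  stopifnot(is.numeric(arms_per_trial), all(arms_per_trial >= 1),
            is.numeric(per_arm_n), length(per_arm_n) == 1L, per_arm_n >= 1)
  as.integer(sum(arms_per_trial * per_arm_n))
}
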