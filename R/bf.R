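#' Pooled-variance two-sample t statistic
#'
#' Computes the equal-variance two-sample t statistic for `mean(a) - mean(b)`,
#' together with its degrees of freedom and the effective sample size
#' `n1 * n2 / (n1 + n2)` that scales the noncentrality parameter in the
#' Bayes-factor model. The pooled (not Welch) form is used throughout the
#' package: the sequential design analysis treats outcomes as standardized
#' with a common unit SD, so equal variances are part of the design model.
#'
#' @param a,b Numeric outcome vectors, one per group (challenger first).
#' @return An object of class `leapfrog_tstat` with fields `t`, `df`,
#'   `n1`, `n2` and `n_eff`.
#' @seealso [t_stat()] to build the same object from a reported summary,
#'   [jzs_bf()] for the Bayes factor computed from it.
#' @examples
#' two_sample_t(rnorm(20, 0.2), rnorm(20))
#' @export
two_sample_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (anyNA(a) || anyNA(b)) {
    stop_leapfrog("insufficient_data", "outcome vectors must not contain NA")
  }
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) {
    stop_leapfrog("insufficient_data", sprintf(
      "each group needs at least 2 observations (got n1 = %d, n2 = %d)", n1, n2))
  }
  df <- n1 + n2 - 2L
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  if (pooled_var <= 0) {
    stop_leapfrog("degenerate_data", "pooled variance is zero; t is undefined")
  }
  tval <- (mean(a) - mean(b)) / sqrt(pooled_var * (1 / n1 + 1 / n2))
  t_stat(tval, n1, n2)
}

#' Build a t-statistic summary object
#'
#' The Bayes-factor engine is parameterized by the `(t, n1, n2)` summary so it
#' accepts both simulated summaries and raw data (via [two_sample_t()]).
#'
#' @param t Pooled-variance two-sample t statistic.
#' @param n1,n2 Per-group sample sizes.
#' @return An object of class `leapfrog_tstat`.
#' @export
t_stat <- function(t, n1, n2) {
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t))
  n1 <- as.numeric(n1); n2 <- as.numeric(n2)
  stopifnot(length(n1) == 1L, length(n2) == 1L, n1 >= 1, n2 >= 1)
  df <- n1 + n2 - 2
  if (df < 1) stop_leapfrog("insufficient_data", "df = n1 + n2 - 2 must be >= 1")
  structure(
    list(t = as.numeric(t), df = df, n1 = n1, n2 = n2,
         n_eff = n1 * n2 / (n1 + n2)),
    class = "leapfrog_tstat")
}

#' @export
print.leapfrog_tstat <- function(x, ...) {
  cat(sprintf("two-sample t = %.4f (df = %g, n1 = %g, n2 = %g, n_eff = %.2f)\n",
              x$t, x$df, x$n1, x$n2, x$n_eff))
  invisible(x)
}

#' Cauchy analysis-prior specification
#'
#' Under the alternative, the standardized effect `delta` (challenger minus
#' comparator, in SD units) has a Cauchy prior with scale `rscale`, truncated
#' to `delta > 0` (`"greater"`), `delta < 0` (`"less"`), or left untruncated
#' (`"two_sided"`). The directional prior is what makes the sequential Bayes
#' factor one-sided: superiority means `delta > 0` when a higher outcome is
#' better; flip `direction` for lower-is-better measures.
#'
#' @param rscale Cauchy prior scale (> 0) on `delta`, in SD units.
#' @param direction One of `"greater"`, `"less"`, `"two_sided"`.
#' @return An object of class `leapfrog_prior`.
#' @export
prior_spec <- function(rscale = 0.5,
                       direction = c("greater", "less", "two_sided")) {
  direction <- match.arg(direction)
  if (!is.numeric(rscale) || length(rscale) != 1L || !is.finite(rscale) ||
      rscale <= 0) {
    stop_leapfrog("invalid_prior", "rscale must be a single positive number")
  }
  structure(list(rscale = as.numeric(rscale), direction = direction),
            class = "leapfrog_prior")
}

#' @export
print.leapfrog_prior <- function(x, ...) {
  cat(sprintf("Cauchy prior on delta: rscale = %g, direction = %s\n",
              x$rscale, x$direction))
  invisible(x)
}

# Marginal likelihood of t under the (truncated-)Cauchy prior on delta, by
# adaptive quadrature on the prior's quantile scale: with u = F(delta) the
# integral of dt(t; df, ncp = delta*sqrt(n_eff)) against the prior becomes an
# integral of the likelihood over u in (0, 1), so the Cauchy tails (which
# carry prior mass to +-Inf) are compressed into a bounded, well-scaled
# domain. The likelihood peaks sharply near delta = t/sqrt(n_eff) at large n,
# so the domain is split at the peak's u before handing each piece to
# stats::integrate. Truncation to one sign of delta simply rescales the
# retained region's mass by 2.
jzs_marginal <- function(t, df, n_eff, rscale, direction, rel.tol = 1e-8) {
  lik_u <- function(u) {
    delta <- stats::qcauchy(u, 0, rscale)
    suppressWarnings(stats::dt(t, df, ncp = delta * sqrt(n_eff)))
  }
  peak <- t / sqrt(n_eff)
  u_cuts <- stats::pcauchy(c(-abs(peak), abs(peak)), 0, rscale)
  lims <- switch(direction,
    greater   = c(0.5, 1),
    less      = c(0, 0.5),
    two_sided = c(0, 1))
  cuts <- sort(unique(c(lims, 0.5, u_cuts)))
  cuts <- cuts[cuts >= lims[1L] & cuts <= lims[2L]]
  scale_p <- if (direction == "two_sided") 1 else 2
  lo <- cuts[-length(cuts)]; hi <- cuts[-1L]
  # sum pieces nearest the likelihood peak first, so far-tail pieces (where
  # the noncentral-t density underflows into rounding noise) can be accepted
  # against an absolute tolerance that is negligible relative to the total
  u_peak <- stats::pcauchy(peak, 0, rscale)
  dist <- pmax(lo - u_peak, u_peak - hi, 0)
  ord <- order(dist)
  # the noncentral-t density far from its bulk is computed (by R) through a
  # difference formula whose rounding noise defeats a pure relative
  # tolerance; pieces that fail it are re-integrated against an absolute
  # tolerance negligible at Bayes-factor precision (rel.tol on the BF scale,
  # i.e. relative to the central-t density at t)
  m0 <- stats::dt(t, df)
  total <- 0; abs_err <- 0
  for (i in ord) {
    res <- tryCatch(
      stats::integrate(lik_u, lo[i], hi[i], rel.tol = rel.tol, abs.tol = 0,
                       stop.on.error = FALSE),
      error = function(e) e)
    ok <- !inherits(res, "error") && identical(res$message, "OK")
    if (!ok) {
      floor_tol <- rel.tol * max(total, m0)
      res <- tryCatch(
        stats::integrate(lik_u, lo[i], hi[i], rel.tol = rel.tol,
                         abs.tol = floor_tol, stop.on.error = FALSE),
        error = function(e) e)
      ok <- !inherits(res, "error") &&
        (identical(res$message, "OK") ||
           (is.finite(res$value) && abs(res$value) <= floor_tol))
      # deep-tail regime: the density values themselves carry relative
      # rounding noise, so 1e-8 is unattainable; accept when the estimated
      # error is still negligible at decision precision (1e-4 of the BF)
      if (!ok && !inherits(res, "error") && is.finite(res$value) &&
          res$abs.error <= 1e-4 * max(total + abs(res$value), m0)) {
        ok <- TRUE
      }
    }
    if (!ok) {
      msg <- if (inherits(res, "error")) conditionMessage(res) else res$message
      stop_leapfrog("numerical", sprintf(
        "quadrature failed on u in [%g, %g] (t = %g, df = %g, n_eff = %g): %s",
        lo[i], hi[i], t, df, n_eff, msg))
    }
    total <- total + max(res$value, 0)
    abs_err <- abs_err + res$abs.error
  }
  list(value = scale_p * max(total, .Machine$double.xmin),
       abs.error = scale_p * abs_err)
}

#' Directional JZS two-sample Bayes factor
#'
#' Computes the Bayes factor for the alternative (standardized effect `delta`
#' following the stated truncated Cauchy prior) against the point null
#' `delta = 0`, from a two-sample t summary. The marginal likelihood of `t`
#' under the alternative is the noncentral-t density with noncentrality
#' `delta * sqrt(n_eff)` integrated over the prior on `delta`; the null
#' likelihood is the central-t density at `t`. Directional ("one-sided")
#' factors simply truncate the prior to one sign of `delta`.
#'
#' Quadrature is adaptive with relative tolerance `rel.tol` (default `1e-8`):
#' the sequential boundaries of a leapfrog design (e.g. 1/5 and 3) need far
#' less than 1% numerical error, and the Monte-Carlo oracle [oracle_bf_mc()]
#' provides an independent check of the quadrature.
#'
#' @param tstat A `leapfrog_tstat` from [two_sample_t()] or [t_stat()].
#' @param prior A `leapfrog_prior` from [prior_spec()].
#' @param rel.tol Relative quadrature tolerance.
#' @return An object of class `leapfrog_bf`: fields `bf`, `tstat`, `prior`,
#'   `method = "quadrature"` and the quadrature's absolute error estimate.
#' @examples
#' jzs_bf(t_stat(2.5, 200, 200), prior_spec(0.5, "greater"))
#' @export
jzs_bf <- function(tstat, prior = prior_spec(), rel.tol = 1e-8) {
  stopifnot(inherits(tstat, "leapfrog_tstat"), inherits(prior, "leapfrog_prior"))
  m1 <- jzs_marginal(tstat$t, tstat$df, tstat$n_eff, prior$rscale,
                     prior$direction, rel.tol)
  m0 <- stats::dt(tstat$t, tstat$df)
  bf <- m1$value / m0
  if (!is.finite(bf) || bf <= 0) {
    stop_leapfrog("numerical", sprintf(
      "Bayes factor is not a finite positive number (got %g)", bf))
  }
  structure(list(bf = bf, tstat = tstat, prior = prior,
                 method = "quadrature", abs.error = m1$abs.error / m0),
            class = "leapfrog_bf")
}

#' @export
print.leapfrog_bf <- function(x, ...) {
  cat(sprintf("BF (%s, rscale = %g) = %.6g   [%s]\n",
              x$prior$direction, x$prior$rscale, x$bf, x$method))
  if (!is.null(x$se)) cat(sprintf("  Monte-Carlo SE: %.3g\n", x$se))
  invisible(x)
}

#' Monte-Carlo verification oracle for the JZS Bayes factor
#'
#' Estimates the same marginal-likelihood ratio as [jzs_bf()] by averaging the
#' noncentral-t density over draws from the (truncated) Cauchy prior, via the
#' inverse-CDF transform of uniforms. Entirely independent of the quadrature
#' path, so it serves as the numerical cross-check for the engine.
#'
#' @inheritParams jzs_bf
#' @param ndraws Number of prior draws (>= 1e4).
#' @param seed Integer seed for the draws.
#' @return A `leapfrog_bf` with `method = "montecarlo"` and a Monte-Carlo
#'   standard error in field `se`.
#' @export
oracle_bf_mc <- function(tstat, prior = prior_spec(), ndraws = 1e5,
                         seed = 1L) {
  stopifnot(inherits(tstat, "leapfrog_tstat"), inherits(prior, "leapfrog_prior"))
  if (ndraws < 1e4) stop_leapfrog("validation", "ndraws must be >= 1e4")
  u <- with_seed(seed, stats::runif(ndraws))
  delta <- switch(prior$direction,
    greater   = prior$rscale * tan(pi * u / 2),
    less      = -prior$rscale * tan(pi * u / 2),
    two_sided = prior$rscale * tan(pi * (u - 0.5)))
  w <- suppressWarnings(stats::dt(tstat$t, tstat$df,
                                  ncp = delta * sqrt(tstat$n_eff)))
  m0 <- stats::dt(tstat$t, tstat$df)
  structure(list(bf = mean(w) / m0, tstat = tstat, prior = prior,
                 method = "montecarlo",
                 se = stats::sd(w) / sqrt(ndraws) / m0,
                 ndraws = ndraws, seed = seed),
            class = "leapfrog_bf")
}

#' Map a Bayes-factor boundary to a t-statistic threshold
#'
#' For fixed sample sizes and prior, the directional Bayes factor is a strictly
#' monotone (increasing for `direction = "greater"`) function of `t`. Decision
#' boundaries on the BF scale therefore correspond to exact thresholds on the
#' t scale, which is what makes large Monte-Carlo operating-characteristic runs
#' cheap: outcome paths only need running t statistics, not one quadrature per
#' look. The threshold is found by root-finding `log BF(t) = log bf`.
#'
#' @param n1,n2 Per-group sample sizes at the look.
#' @param prior A `leapfrog_prior` (must be directional for a decision rule).
#' @param bf The Bayes-factor boundary (> 0).
#' @param guess Optional starting value for the root search (warm start).
#' @return The t value at which the BF equals `bf`.
#' @export
bf_threshold_t <- function(n1, n2, prior, bf, guess = NULL) {
  stopifnot(inherits(prior, "leapfrog_prior"), is.numeric(bf), bf > 0)
  if (prior$direction == "two_sided") {
    stop_leapfrog("validation",
                  "two-sided BFs are not monotone in t; no unique threshold")
  }
  sgn <- if (prior$direction == "less") -1 else 1
  f <- function(t) log(jzs_bf(t_stat(sgn * t, n1, n2), prior)$bf) - log(bf)
  lo <- -1; hi <- 1
  if (!is.null(guess) && is.finite(guess)) {
    lo <- sgn * guess - 0.05; hi <- sgn * guess + 0.05
  }
  # the directional BF is bounded below in t (both marginals have polynomial
  # Cauchy-induced tails), so boundaries below that floor -- or absurdly high
  # ones -- can be unreachable: the bracket search is capped and an
  # unreachable boundary maps to an infinite threshold (never crossed)
  tcap <- 100
  f_try <- function(t) tryCatch(f(t), leapfrog_error = function(e) NA_real_)
  flo <- f(lo); fhi <- f(hi)
  width <- hi - lo
  while (flo > 0) {
    if (lo <= -tcap) return(sgn * -Inf)
    lo <- max(lo - width, -tcap); flo <- f_try(lo); width <- 2 * width
    # quadrature breakdown this deep in the tail means the BF has flattened
    # onto its lower asymptote without reaching the boundary
    if (is.na(flo)) return(sgn * -Inf)
  }
  width <- hi - lo
  while (fhi < 0) {
    if (hi >= tcap) return(sgn * Inf)
    hi <- min(hi + width, tcap); fhi <- f_try(hi); width <- 2 * width
    if (is.na(fhi)) return(sgn * Inf)
  }
  root <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                         tol = 1e-7)$root
  sgn * root
}
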