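#' Leapfrog trial analysis parameters
#'
#' Bundles the sequential analysis parameters of a leapfrog design: the per-arm
#' sample size at which looks begin (`n_min`), the per-arm cap at which an
#' undecided arm is dropped (`n_max`), the absorbing Bayes-factor boundaries
#' (`bf_fail` for dropping, `bf_success` for promotion), the Cauchy analysis
#' prior scale, and the look cadence. Defaults are the calibrated example
#' design for detecting a standardized effect of d = 0.2 with roughly 80%
#' power and a pairwise false-positive rate below 5%:
#' `n_min = 150`, `n_max = 450`, `bf_fail = 1/5`, `bf_success = 3`,
#' `rscale = 0.5`.
#'
#' @param n_min Minimum per-arm sample size before sequential analyses start.
#' @param n_max Per-arm sample-size cap.
#' @param bf_fail Lower BF boundary (0 < bf_fail < 1): drop the challenger.
#' @param bf_success Upper BF boundary (> 1): promote the challenger.
#' @param rscale Cauchy prior scale for the analysis prior.
#' @param direction `"greater"` if higher outcomes are better (superiority is
#'   `delta > 0`), `"less"` for lower-is-better outcome scales.
#' @param step Analysis cadence: participants per arm between looks. The
#'   default 1 is the finest (fully sequential) cadence; later-checkpoint
#'   operating characteristics depend on this, first-look ones do not.
#' @param allocation Integer challenger:comparator accrual per round,
#'   default `c(1, 1)`.
#' @return An object of class `leapfrog_design`.
#' @examples
#' trial_design()                      # the calibrated d = 0.2 example design
#' trial_design(n_min = 75, n_max = 300, bf_fail = 1/6, bf_success = 6)
#' @export
trial_design <- function(n_min = 150, n_max = 450, bf_fail = 1 / 5,
                         bf_success = 3, rscale = 0.5,
                         direction = c("greater", "less"), step = 1,
                         allocation = c(1, 1)) {
  direction <- match.arg(direction)
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(n_min) && length(n_min) == 1L && n_min >= 2 &&
        n_min == floor(n_min), "n_min: must be an integer >= 2")
  chk(is.numeric(n_max) && length(n_max) == 1L && n_max == floor(n_max) &&
        n_max >= n_min, "n_max: must be an integer >= n_min")
  chk(is.numeric(bf_fail) && length(bf_fail) == 1L && bf_fail > 0 &&
        bf_fail < 1, "bf_fail: must satisfy 0 < bf_fail < 1")
  chk(is.numeric(bf_success) && length(bf_success) == 1L && bf_success > 1,
      "bf_success: must be > 1")
  chk(is.numeric(rscale) && length(rscale) == 1L && rscale > 0,
      "rscale: must be > 0")
  chk(is.numeric(step) && length(step) == 1L && step >= 1 &&
        step == floor(step), "step: must be an integer >= 1")
  chk(is.numeric(allocation) && length(allocation) == 2L &&
        all(allocation >= 1) && all(allocation == floor(allocation)),
      "allocation: must be two positive integers (challenger:comparator)")
  if (length(problems)) {
    stop_leapfrog("validation",
                  paste0("invalid trial design:\n  ",
                         paste(problems, collapse = "\n  ")))
  }
  structure(
    list(n_min = as.integer(n_min), n_max = as.integer(n_max),
         bf_fail = bf_fail, bf_success = bf_success,
         prior = prior_spec(rscale, direction),
         step = as.integer(step), allocation = as.integer(allocation)),
    class = "leapfrog_design")
}

#' @export
print.leapfrog_design <- function(x, ...) {
  cat("Leapfrog trial design\n")
  cat(sprintf("  N_min = %d, N_max = %d per arm (looks every %d)\n",
              x$n_min, x$n_max, x$step))
  cat(sprintf("  BF_fail = %.4g (drop), BF_success = %.4g (promote)\n",
              x$bf_fail, x$bf_success))
  cat(sprintf("  analysis prior: Cauchy rscale = %g, direction = %s\n",
              x$prior$rscale, x$prior$direction))
  if (any(x$allocation != 1L)) {
    cat(sprintf("  allocation %d:%d (challenger:comparator)\n",
                x$allocation[1L], x$allocation[2L]))
  }
  invisible(x)
}

#' Outcome model for one challenger-vs-comparator comparison
#'
#' The generative model for the design analysis, and the only statistical
#' structure it assumes: each participant contributes one continuous outcome,
#' Normal with common SD; the challenger mean exceeds the comparator mean by
#' `effect * sd` (Cohen's d on the standardized scale).
#'
#' @param effect True standardized effect (Cohen's d) of challenger vs
#'   comparator.
#' @param sd Outcome standard deviation (default 1: standardized scale).
#' @param comparator_mean Comparator location (default 0).
#' @return An object of class `leapfrog_model`.
#' @export
outcome_model <- function(effect, sd = 1, comparator_mean = 0) {
  stopifnot(is.numeric(effect), length(effect) == 1L, is.finite(effect))
  if (!is.numeric(sd) || length(sd) != 1L || sd <= 0) {
    stop_leapfrog("validation", "sd: must be > 0")
  }
  structure(list(effect = effect, sd = sd,
                 comparator_mean = comparator_mean),
            class = "leapfrog_model")
}

# Per-arm look sizes of a design: n_min, n_min + step, ..., always
# including n_max as the final look.
design_looks <- function(design) {
  looks <- seq(design$n_min, design$n_max, by = design$step)
  if (looks[length(looks)] != design$n_max) looks <- c(looks, design$n_max)
  as.integer(looks)
}

# t-scale decision thresholds at every look of a design, canonicalized to
# direction "greater" (a lower-is-better design flips the sign of t instead).
# Cached across calls; warm-started along the look grid.
design_threshold_table <- function(design) {
  key <- paste("tab", design$n_min, design$n_max, design$step,
               design$bf_fail, design$bf_success, design$prior$rscale,
               paste(design$allocation, collapse = ":"), sep = "|")
  hit <- .leapfrog_cache[[key]]
  if (!is.null(hit)) return(hit)
  looks <- design_looks(design)
  canon <- prior_spec(design$prior$rscale, "greater")
  a <- design$allocation[1L]; b <- design$allocation[2L]
  tf <- ts <- numeric(length(looks))
  for (i in seq_along(looks)) {
    thr <- decision_thresholds(looks[i] * a, looks[i] * b, canon,
                               design$bf_fail, design$bf_success)
    tf[i] <- thr[["t_fail"]]; ts[i] <- thr[["t_success"]]
  }
  out <- data.frame(n = looks, t_fail = tf, t_success = ts)
  .leapfrog_cache[[key]] <- out
  out
}

# Vectorized Monte-Carlo engine behind the pairwise design analysis.
# Draws full outcome paths to n_max for both arms, forms running pooled-t
# statistics at every look from cumulative sums, and finds each replication's
# first boundary crossing against the cached t thresholds (exact by
# monotonicity of the directional BF in t). Returns one row per replication.
simulate_crossings <- function(design, model, n_reps, seed, chunk = 5000L) {
  thr <- design_threshold_table(design)
  looks <- thr$n
  a <- design$allocation[1L]; b <- design$allocation[2L]
  nmax <- design$n_max
  mu_c <- model$comparator_mean + model$effect * model$sd
  sgn <- if (design$prior$direction == "less") -1 else 1
  reason <- character(n_reps); stop_n <- integer(n_reps)
  done <- 0L
  with_seed(seed, {
    while (done < n_reps) {
      m <- min(chunk, n_reps - done)
      A <- matrix(stats::rnorm(a * nmax * m, mu_c, model$sd), a * nmax, m)
      B <- matrix(stats::rnorm(b * nmax * m, model$comparator_mean, model$sd),
                  b * nmax, m)
      r1 <- a * looks; r2 <- b * looks
      S1 <- apply(A, 2L, cumsum)[r1, , drop = FALSE]
      Q1 <- apply(A * A, 2L, cumsum)[r1, , drop = FALSE]
      S2 <- apply(B, 2L, cumsum)[r2, , drop = FALSE]
      Q2 <- apply(B * B, 2L, cumsum)[r2, , drop = FALSE]
      n1 <- a * looks; n2 <- b * looks
      md <- S1 / n1 - S2 / n2
      pv <- (Q1 - S1^2 / n1 + Q2 - S2^2 / n2) / (n1 + n2 - 2)
      tmat <- sgn * md / sqrt(pv * (1 / n1 + 1 / n2))
      hit_f <- tmat <= thr$t_fail
      hit_s <- tmat >= thr$t_success
      any_hit <- hit_f | hit_s
      for (j in seq_len(m)) {
        k <- which.max(any_hit[, j])
        if (any_hit[k, j]) {
          reason[done + j] <- if (hit_f[k, j]) "fail" else "success"
          stop_n[done + j] <- looks[k]
        } else {
          reason[done + j] <- "nmax"
          stop_n[done + j] <- nmax
        }
      }
      done <- done + m
    }
  })
  data.frame(rep = seq_len(n_reps), stop_reason = reason, stop_n = stop_n)
}

#' Simulate one sequential challenger-vs-comparator comparison
#'
#' Draws outcomes for both arms under the outcome model, runs the sequential
#' directional Bayes-factor analysis from `n_min` per arm at the design's
#' cadence, and stops at the first absorbing boundary crossing, or at `n_max`
#' if neither boundary is reached.
#'
#' @param design A [trial_design()].
#' @param model An [outcome_model()].
#' @param seed Integer seed; the same seed reproduces the trace exactly.
#' @param compute_bf If `TRUE` (default) the Bayes factor at every look up to
#'   the stop is computed by quadrature and returned in the trace; boundary
#'   decisions themselves use the exact t-scale thresholds either way.
#' @return An object of class `leapfrog_trace`: `looks` (data frame with
#'   `n`, `t`, `bf`), `stop_reason` (`"fail"`, `"success"` or `"nmax"`) and
#'   `stop_n` (per-arm n at stopping).
#' @examples
#' simulate_pairwise_trace(trial_design(n_min = 20, n_max = 40, step = 5),
#'                         outcome_model(0.5), seed = 7)
#' @export
simulate_pairwise_trace <- function(design, model, seed, compute_bf = TRUE) {
  stopifnot(inherits(design, "leapfrog_design"), inherits(model, "leapfrog_model"))
  thr <- design_threshold_table(design)
  looks <- thr$n
  a <- design$allocation[1L]; b <- design$allocation[2L]
  mu_c <- model$comparator_mean + model$effect * model$sd
  xs <- with_seed(seed, {
    list(A = stats::rnorm(a * design$n_max, mu_c, model$sd),
         B = stats::rnorm(b * design$n_max, model$comparator_mean, model$sd))
  })
  sgn <- if (design$prior$direction == "less") -1 else 1
  n1 <- a * looks; n2 <- b * looks
  S1 <- cumsum(xs$A)[n1]; Q1 <- cumsum(xs$A^2)[n1]
  S2 <- cumsum(xs$B)[n2]; Q2 <- cumsum(xs$B^2)[n2]
  pv <- (Q1 - S1^2 / n1 + Q2 - S2^2 / n2) / (n1 + n2 - 2)
  tvals <- (S1 / n1 - S2 / n2) / sqrt(pv * (1 / n1 + 1 / n2))
  s <- sgn * tvals
  hit_f <- s <= thr$t_fail
  hit_s <- s >= thr$t_success
  k <- which.max(hit_f | hit_s)
  if (hit_f[k] || hit_s[k]) {
    stop_reason <- if (hit_f[k]) "fail" else "success"
    stop_idx <- k
  } else {
    stop_reason <- "nmax"
    stop_idx <- length(looks)
  }
  idx <- seq_len(stop_idx)
  bf <- rep(NA_real_, stop_idx)
  if (compute_bf) {
    for (i in idx) {
      bf[i] <- jzs_bf(t_stat(tvals[i], n1[i], n2[i]), design$prior)$bf
    }
  }
  structure(
    list(looks = data.frame(n = looks[idx], t = tvals[idx], bf = bf),
         stop_reason = stop_reason, stop_n = looks[stop_idx],
         design = design, model = model, seed = seed),
    class = "leapfrog_trace")
}

#' @export
print.leapfrog_trace <- function(x, ...) {
  cat(sprintf(
    "Sequential pairwise trace (d = %g): stopped '%s' at n = %d per arm after %d look(s)\n",
    x$model$effect, x$stop_reason, x$stop_n, nrow(x$looks)))
  if (!all(is.na(x$looks$bf))) {
    last <- x$looks[nrow(x$looks), ]
    cat(sprintf("  final BF = %.4g at n = %d\n", last$bf, last$n))
  }
  invisible(x)
}

#' Operating characteristics of a leapfrog design over an effect-size grid
#'
#' Runs `n_reps` independent sequential pairwise comparisons per true effect
#' size and reports, for each checkpoint sample size, the cumulative
#' probability (in percent) of having been absorbed at the failure or success
#' boundary by that per-arm n. This is the table a design-analysis run
#' produces when calibrating a leapfrog design: the success column at the
#' target effect and `n_max` is the design's power, and at effect 0 its
#' pairwise false-positive rate.
#'
#' @param design A [trial_design()].
#' @param effect_grid Numeric vector of true standardized effects.
#' @param checkpoints Per-arm sample sizes within `[n_min, n_max]`.
#' @param n_reps Replications per effect (>= 100).
#' @param seed Integer seed.
#' @param sd,comparator_mean Passed to [outcome_model()].
#' @return An object of class `leapfrog_oc`: matrices `p_fail`, `p_success`
#'   (effects x checkpoints, percent), matching Monte-Carlo standard errors
#'   `mc_se_fail`/`mc_se_success`, plus the grid, design, `n_reps` and seed.
#' @examples
#' \donttest{
#' estimate_oc(trial_design(), effect_grid = c(0, 0.2),
#'             checkpoints = c(150, 450), n_reps = 200, seed = 1)
#' }
#' @export
estimate_oc <- function(design, effect_grid, checkpoints, n_reps, seed,
                        sd = 1, comparator_mean = 0) {
  stopifnot(inherits(design, "leapfrog_design"))
  if (n_reps < 100) stop_leapfrog("validation", "n_reps must be >= 100")
  checkpoints <- as.integer(sort(unique(checkpoints)))
  if (any(checkpoints < design$n_min) || any(checkpoints > design$n_max)) {
    stop_leapfrog("validation", sprintf(
      "checkpoints must lie within [n_min, n_max] = [%d, %d]",
      design$n_min, design$n_max))
  }
  nd <- length(effect_grid); nc <- length(checkpoints)
  p_fail <- p_success <- se_fail <- se_success <-
    matrix(NA_real_, nd, nc,
           dimnames = list(format(effect_grid), as.character(checkpoints)))
  stop_ns <- vector("list", nd)
  for (i in seq_len(nd)) {
    cr <- simulate_crossings(design,
                             outcome_model(effect_grid[i], sd, comparator_mean),
                             n_reps, seed = seed + i - 1L)
    stop_ns[[i]] <- cr
    for (j in seq_len(nc)) {
      pf <- mean(cr$stop_reason == "fail" & cr$stop_n <= checkpoints[j])
      ps <- mean(cr$stop_reason == "success" & cr$stop_n <= checkpoints[j])
      p_fail[i, j] <- 100 * pf
      p_success[i, j] <- 100 * ps
      se_fail[i, j] <- 100 * sqrt(pf * (1 - pf) / n_reps)
      se_success[i, j] <- 100 * sqrt(ps * (1 - ps) / n_reps)
    }
  }
  structure(
    list(effect_grid = effect_grid, checkpoints = checkpoints,
         p_fail = p_fail, p_success = p_success,
         mc_se_fail = se_fail, mc_se_success = se_success,
         n_reps = n_reps, seed = seed, design = design,
         crossings = stop_ns),
    class = "leapfrog_oc")
}

#' @export
print.leapfrog_oc <- function(x, digits = 1, ...) {
  cat(sprintf(
    "Operating characteristics (%d reps/effect, looks every %d from %d to %d per arm)\n",
    x$n_reps, x$design$step, x$design$n_min, x$design$n_max))
  cat(sprintf("  BF_fail = %.4g, BF_success = %.4g, rscale = %g\n\n",
              x$design$bf_fail, x$design$bf_success, x$design$prior$rscale))
  wide <- cbind(round(x$p_fail, digits), round(x$p_success, digits))
  colnames(wide) <- c(paste0("fail@", x$checkpoints),
                      paste0("success@", x$checkpoints))
  print(data.frame(d = x$effect_grid, wide, check.names = FALSE,
                   row.names = NULL))
  invisible(x)
}

#' First-look boundary-crossing probabilities
#'
#' Fast path for the probabilities of crossing either boundary at exactly
#' `n_min` per arm (the first sequential look), computing a single t statistic
#' per replication. Matches the first checkpoint of [estimate_oc()] within
#' Monte-Carlo error.
#'
#' @inheritParams estimate_oc
#' @param model An [outcome_model()].
#' @return A list with `p_fail`, `p_success` (percent), their binomial
#'   standard errors, and `n_reps`.
#' @export
first_look_probabilities <- function(design, model, n_reps, seed) {
  stopifnot(inherits(design, "leapfrog_design"), inherits(model, "leapfrog_model"))
  if (n_reps < 100) stop_leapfrog("validation", "n_reps must be >= 100")
  a <- design$allocation[1L]; b <- design$allocation[2L]
  n1 <- a * design$n_min; n2 <- b * design$n_min
  canon <- prior_spec(design$prior$rscale, "greater")
  thr <- decision_thresholds(n1, n2, canon, design$bf_fail, design$bf_success)
  mu_c <- model$comparator_mean + model$effect * model$sd
  sgn <- if (design$prior$direction == "less") -1 else 1
  tvals <- with_seed(seed, {
    A <- matrix(stats::rnorm(n1 * n_reps, mu_c, model$sd), n1, n_reps)
    B <- matrix(stats::rnorm(n2 * n_reps, model$comparator_mean, model$sd),
                n2, n_reps)
    s1 <- colSums(A); q1 <- colSums(A * A)
    s2 <- colSums(B); q2 <- colSums(B * B)
    pv <- (q1 - s1^2 / n1 + q2 - s2^2 / n2) / (n1 + n2 - 2)
    (s1 / n1 - s2 / n2) / sqrt(pv * (1 / n1 + 1 / n2))
  })
  s <- sgn * tvals
  pf <- mean(s <= thr[["t_fail"]]); ps <- mean(s >= thr[["t_success"]])
  list(p_fail = 100 * pf, p_success = 100 * ps,
       se_fail = 100 * sqrt(pf * (1 - pf) / n_reps),
       se_success = 100 * sqrt(ps * (1 - ps) / n_reps),
       n_reps = n_reps)
}

#' Search candidate designs for target operating characteristics
#'
#' Evaluates each candidate design's cumulative success probability by `n_max`
#' at the target effect (power) and at effect 0 (pairwise false-positive
#' rate), filters to candidates meeting `power >= power_floor` and
#' `false positive <= alpha_ceiling`, and ranks survivors by expected per-arm
#' sample size at the target effect. This is the simulation-first calibration
#' workflow used to arrive at an analysis-parameter set before a trial starts.
#'
#' @param target_d Target standardized effect size the design must detect.
#' @param power_floor Minimum acceptable power (fraction).
#' @param alpha_ceiling Maximum acceptable pairwise false-positive rate
#'   (fraction).
#' @param candidates List of [trial_design()] objects.
#' @param n_reps Replications per candidate and effect.
#' @param seed Integer seed.
#' @return A data frame of class `leapfrog_search` with one row per passing
#'   candidate, ranked by expected per-arm sample size at `target_d`;
#'   the full evaluation (including filtered-out candidates) is in
#'   `attr(, "evaluated")`. An empty surviving set yields a zero-row frame.
#' @export
search_parameters <- function(target_d, power_floor, alpha_ceiling,
                              candidates, n_reps, seed) {
  if (!length(candidates)) {
    stop_leapfrog("validation", "candidate grid must be non-empty")
  }
  if (inherits(candidates, "leapfrog_design")) candidates <- list(candidates)
  stopifnot(all(vapply(candidates, inherits, TRUE, "leapfrog_design")))
  rows <- lapply(seq_along(candidates), function(i) {
    des <- candidates[[i]]
    at_d <- simulate_crossings(des, outcome_model(target_d), n_reps,
                               seed = seed + 2L * (i - 1L))
    at_0 <- simulate_crossings(des, outcome_model(0), n_reps,
                               seed = seed + 2L * (i - 1L) + 1L)
    data.frame(
      candidate = i,
      n_min = des$n_min, n_max = des$n_max,
      bf_fail = des$bf_fail, bf_success = des$bf_success,
      rscale = des$prior$rscale, step = des$step,
      power = mean(at_d$stop_reason == "success"),
      false_positive = mean(at_0$stop_reason == "success"),
      expected_n = mean(at_d$stop_n))
  })
  evaluated <- do.call(rbind, rows)
  pass <- evaluated[evaluated$power >= power_floor &
                      evaluated$false_positive <= alpha_ceiling, , drop = FALSE]
  pass <- pass[order(pass$expected_n), , drop = FALSE]
  rownames(pass) <- NULL
  structure(pass, evaluated = evaluated, target_d = target_d,
            n_reps = n_reps, seed = seed,
            class = c("leapfrog_search", "data.frame"))
}
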