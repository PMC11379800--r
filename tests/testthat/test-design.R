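test_that("trial design invariants are enforced at construction", {
  expect_error(trial_design(bf_fail = 1.5), class = "leapfrog_validation_error")
  expect_error(trial_design(bf_success = 0.5),
               class = "leapfrog_validation_error")
  expect_error(trial_design(n_min = 500, n_max = 450),
               class = "leapfrog_validation_error")
  expect_error(trial_design(step = 0), class = "leapfrog_validation_error")
  expect_error(outcome_model(0.2, sd = 0), class = "leapfrog_validation_error")
  d <- trial_design()
  expect_identical(c(d$n_min, d$n_max), c(150L, 450L))
  expect_equal(c(d$bf_fail, d$bf_success, d$prior$rscale), c(0.2, 3, 0.5))
})

test_that("pairwise traces stop consistently with their boundaries", {
  des <- small_design()
  for (seed in 1:6) {
    tr <- simulate_pairwise_trace(des, outcome_model(0.3), seed = seed)
    expect_identical(tr$looks$n[1L], des$n_min)
    expect_lte(tr$stop_n, des$n_max)
    last_bf <- tr$looks$bf[nrow(tr$looks)]
    inner <- tr$looks$bf[-nrow(tr$looks)]
    # absorbing boundaries: exactly one crossing, at the final look
    expect_true(all(inner > des$bf_fail & inner < des$bf_success))
    if (tr$stop_reason == "fail") expect_lte(last_bf, des$bf_fail)
    if (tr$stop_reason == "success") expect_gte(last_bf, des$bf_success)
    if (tr$stop_reason == "nmax") expect_identical(tr$stop_n, des$n_max)
  }
})

test_that("unreachable boundaries force every trace to the sample-size cap", {
  des <- small_design(bf_fail = 1e-12, bf_success = 1e12)
  for (seed in 1:3) {
    tr <- simulate_pairwise_trace(des, outcome_model(0.4), seed = seed,
                                  compute_bf = FALSE)
    expect_identical(tr$stop_reason, "nmax")
    expect_identical(tr$stop_n, des$n_max)
  }
  fl <- first_look_probabilities(des, outcome_model(0.4), 500, seed = 3)
  expect_identical(c(fl$p_fail, fl$p_success), c(0, 0))
})

test_that("a fixed seed reproduces traces and OC tables exactly", {
  des <- small_design()
  tr1 <- simulate_pairwise_trace(des, outcome_model(0.2), seed = 42)
  tr2 <- simulate_pairwise_trace(des, outcome_model(0.2), seed = 42)
  expect_identical(tr1$looks, tr2$looks)
  oc1 <- estimate_oc(des, c(0, 0.3), c(20, 60), 150, seed = 9)
  oc2 <- estimate_oc(des, c(0, 0.3), c(20, 60), 150, seed = 9)
  expect_identical(oc1$p_success, oc2$p_success)
})

test_that("an overwhelming effect is promoted at the first look", {
  fl <- first_look_probabilities(trial_design(), outcome_model(3.0), 1000,
                                 seed = 21)
  expect_gte(fl$p_success, 99)
})

test_that("OC tables are monotone, absorbing and ordered in effect size", {
  des <- small_design()
  oc <- estimate_oc(des, c(-0.2, 0, 0.25, 0.5), c(20, 30, 40, 60),
                    n_reps = 600, seed = 31)
  # cumulative crossing probabilities cannot decrease with n
  expect_true(all(apply(oc$p_fail, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(apply(oc$p_success, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(oc$p_fail + oc$p_success <= 100))
  expect_true(all(oc$p_fail >= 0 & oc$p_success >= 0))
  # stochastic ordering in d, tolerating 2 MC SE per comparison
  for (j in seq_along(oc$checkpoints)) {
    ps <- oc$p_success[, j]; ses <- oc$mc_se_success[, j]
    pf <- oc$p_fail[, j]; sef <- oc$mc_se_fail[, j]
    for (i in seq_len(length(ps) - 1L)) {
      expect_gte(ps[i + 1L], ps[i] - 2 * (ses[i] + ses[i + 1L]))
      expect_lte(pf[i + 1L], pf[i] + 2 * (sef[i] + sef[i + 1L]))
    }
  }
  expect_error(estimate_oc(des, 0, checkpoints = 10, n_reps = 200, seed = 1),
               class = "leapfrog_validation_error")
  expect_error(estimate_oc(des, 0, checkpoints = 30, n_reps = 50, seed = 1),
               class = "leapfrog_validation_error")
})

test_that("first-look fast path matches the OC table's first checkpoint", {
  des <- small_design()
  fl <- first_look_probabilities(des, outcome_model(0.2), 2000, seed = 51)
  oc <- estimate_oc(des, 0.2, des$n_min, n_reps = 2000, seed = 151)
  tol <- 3 * (fl$se_fail + oc$mc_se_fail[1, 1]) + 1e-9
  expect_lt(abs(fl$p_fail - oc$p_fail[1, 1]), tol)
  tol_s <- 3 * (fl$se_success + oc$mc_se_success[1, 1]) + 1e-9
  expect_lt(abs(fl$p_success - oc$p_success[1, 1]), tol_s)
})

test_that("single-look designs match the analytic noncentral-t probability", {
  des <- trial_design(n_min = 40, n_max = 40, bf_fail = 1 / 5, bf_success = 3)
  for (d in c(0, 0.4)) {
    oc <- estimate_oc(des, d, 40, n_reps = 4000, seed = 61 + round(10 * d))
    ref <- analytic_single_look(des, d)
    expect_lt(abs(oc$p_success[1, 1] - ref[["p_success"]]),
              3 * oc$mc_se_success[1, 1] + 1e-9)
    expect_lt(abs(oc$p_fail[1, 1] - ref[["p_fail"]]),
              3 * oc$mc_se_fail[1, 1] + 1e-9)
  }
})

test_that("parameter search filters and ranks candidate designs", {
  cands <- list(small_design(),
                small_design(bf_success = 1e12, bf_fail = 1e-12),
                small_design(n_min = 30, n_max = 60, step = 10))
  res <- search_parameters(0.6, power_floor = 0.70, alpha_ceiling = 0.10,
                           candidates = cands, n_reps = 400, seed = 71)
  expect_s3_class(res, "leapfrog_search")
  # unreachable-boundary candidate has ~zero power and is filtered out
  expect_false(2 %in% res$candidate)
  expect_true(all(res$power >= 0.70 & res$false_positive <= 0.10))
  expect_true(!is.unsorted(res$expected_n))
  # same seed reproduces the ranking
  res2 <- search_parameters(0.6, 0.70, 0.10, cands, n_reps = 400, seed = 71)
  expect_identical(as.data.frame(res), as.data.frame(res2))
  expect_error(search_parameters(0.2, 0.8, 0.05, list(), 200, 1),
               class = "leapfrog_validation_error")
  # an impossible constraint yields an empty result, not an error
  res3 <- search_parameters(0.6, power_floor = 0.9999, alpha_ceiling = 1e-6,
                            candidates = cands[3], n_reps = 400, seed = 72)
  expect_identical(nrow(res3), 0L)
})
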