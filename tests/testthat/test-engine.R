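test_that("arm schedules are validated", {
  expect_error(arm_schedule(c("C", "C"), c(0, 0)),
               class = "leapfrog_validation_error")
  expect_error(arm_schedule("C", 0), class = "leapfrog_validation_error")
  expect_error(arm_schedule(c("C", "a"), c(0, 0), entry = c("on_drop", "start"),
                            comparator = "C"),
               class = "leapfrog_validation_error")
  expect_error(arm_schedule(c("C", "a"), c(0, 0), entry = "whenever"),
               class = "leapfrog_validation_error")
})

test_that("unreachable boundaries drive a lone challenger to the cap", {
  des <- trial_design(n_min = 10, n_max = 30, bf_fail = 1e-12,
                      bf_success = 1e12, step = 1)
  h <- run_trial(des, arm_schedule(c("C", "a1"), c(0, 0)), seed = 3,
                 log_looks = FALSE)
  expect_identical(h$total_n, 2L * des$n_max)
  expect_identical(unname(h$per_arm_n), c(30L, 30L))
  expect_identical(h$arms$status[h$arms$arm_id == "a1"], "dropped_nmax")
  h2 <- run_trial(des, arm_schedule(c("C", "a1"), c(0, 0)), seed = 3,
                  log_looks = FALSE)
  expect_identical(h$events, h2$events)
})

test_that("a toy multi-arm trial reproduces the hand-enumerated bookkeeping", {
  # n_min = 4, n_max = 8; A overwhelmingly better, B and D overwhelmingly
  # worse; D queued to enter on the first arm leaving the trial. With
  # outcomes fixed per (arm, within-arm index), the history is
  # allocation-order invariant: generations advance one participant per
  # recruiting arm, so every count below is hand-derivable.
  des <- trial_design(n_min = 4, n_max = 8, bf_fail = 1 / 3, bf_success = 3,
                      step = 1)
  sch <- arm_schedule(c("C", "A", "B", "D"), c(0, 2, -2, -2),
                      entry = c("start", "start", "start", "on_drop"))
  h <- run_trial(des, sch, seed = 1, outcome_fn = toy_outcome_fn)

  # independent brute-force enumeration of the same decisions:
  # generation 4 (g = 12): A vs C at (4, 4) must promote; C's retirement
  # releases D (entry index 13); B's evaluation is deferred to the next
  # look against the new comparator A
  bf_A <- jzs_bf(two_sample_t(toy_outcomes$A[1:4], toy_outcomes$C[1:4]),
                 des$prior)$bf
  expect_gte(bf_A, des$bf_success)
  # generation 5 (g = 15, block {A, B, D}): B vs A at (5, 5) must fail
  bf_B <- jzs_bf(two_sample_t(toy_outcomes$B[1:5], toy_outcomes$A[1:5]),
                 des$prior)$bf
  expect_lte(bf_B, des$bf_fail)
  # D's contemporaneous comparator data are A's participants 5-8 (indices
  # >= 13), so its first look is at (4, 4) in generation 8 and must fail
  bf_D <- jzs_bf(two_sample_t(toy_outcomes$D[1:4], toy_outcomes$A[5:8]),
                 des$prior)$bf
  expect_lte(bf_D, des$bf_fail)

  # totals: C 4, A 4 + 1 + 3, B 5, D 1 + 3 -> 21 participants
  expect_identical(h$per_arm_n, c(C = 4L, A = 8L, B = 5L, D = 4L))
  expect_identical(h$total_n, 21L)
  expect_identical(h$final_comparator, "A")
  st <- setNames(h$arms$status, h$arms$arm_id)
  expect_identical(st[["C"]], "retired")
  expect_identical(st[["A"]], "promoted")
  expect_identical(st[["B"]], "dropped_fail")
  expect_identical(st[["D"]], "dropped_fail")
  expect_identical(h$arms$entry_index[h$arms$arm_id == "D"], 13L)
  ev <- h$events
  expect_identical(
    ev$event[ev$event != "look_evaluated"],
    c("arm_entered", "arm_entered", "arm_entered", "comparator_retired",
      "arm_promoted", "arm_entered", "arm_dropped_fail", "arm_dropped_fail"))
  # logged BFs at decision events match the brute-force values (the toy's
  # extreme t values sit on the BF's deep-tail asymptote, where quadrature
  # is accurate to ~1e-3 rather than full precision)
  expect_equal(ev$bf[ev$event == "arm_promoted"], bf_A, tolerance = 1e-6)
  expect_equal(ev$bf[ev$event == "arm_dropped_fail"], c(bf_B, bf_D),
               tolerance = 2e-3)
})

test_that("contemporaneous subsets filter on the entry index", {
  comp <- list(idx = 1:10, y = (1:10) / 10, entry_index = 1L,
               promoted_at = NA_integer_)
  ch_start <- list(entry_index = 1L)
  expect_identical(contemporaneous_subset(comp, ch_start), comp$y)
  ch_late <- list(entry_index = 6L)
  expect_identical(contemporaneous_subset(comp, ch_late), comp$y[6:10])
  ch_later <- list(entry_index = 11L)
  expect_identical(contemporaneous_subset(comp, ch_later), numeric(0))
  # a promoted comparator's challenger-phase outcomes can be excluded
  comp2 <- list(idx = 1:10, y = comp$y, entry_index = 1L, promoted_at = 4L)
  expect_identical(contemporaneous_subset(comp2, ch_start,
                                          all_phases = FALSE), comp$y[5:10])
})

test_that("scripted replay audits narrated trajectories exactly", {
  sc <- leapfrog_demo_scenario()
  h <- replay_scenario(sc$script, sc$design, sc$schedule)
  expect_identical(h$total_n, 1250L)
  expect_identical(h$per_arm_n,
                   c(C = 200L, arm1 = 150L, arm2 = 200L, arm3 = 350L,
                     arm4 = 200L, arm5 = 150L))
  expect_identical(h$final_comparator, "arm4")
  # five challenger methods were tested
  expect_identical(sum(h$arms$arm_id != "C"), 5L)

  # a single immediate failure costs 2 * n_min
  des <- trial_design(n_min = 10, n_max = 30)
  sch <- arm_schedule(c("C", "x"), c(0, 0))
  h2 <- replay_scenario(data.frame(arm_id = "x", action = "fail", at_n = 10),
                        des, sch)
  expect_identical(h2$total_n, 2L * des$n_min)

  # infeasible steps are named
  expect_error(
    replay_scenario(data.frame(arm_id = "x", action = "promote", at_n = 5),
                    des, sch),
    class = "leapfrog_script_error")
  expect_error(
    replay_scenario(data.frame(arm_id = "x", action = "fail", at_n = 31),
                    des, sch),
    class = "leapfrog_script_error")
  # a step that can never fire (arm drops at the cap first) is reported
  expect_error(
    replay_scenario(data.frame(arm_id = "ghost", action = "fail", at_n = 10),
                    des, sch),
    class = "leapfrog_script_error")
})

test_that("the two-arm engine reduces to the pairwise design analysis", {
  des <- trial_design(n_min = 25, n_max = 75, step = 5)
  n_sim <- 400
  eng <- vapply(seq_len(n_sim), function(i) {
    h <- run_trial(des, arm_schedule(c("C", "x"), c(0, 0.4)), seed = 1000 + i,
                   log_looks = FALSE)
    c(h$arms$status[h$arms$arm_id == "x"] == "promoted",
      h$per_arm_n[["x"]])
  }, numeric(2))
  pw <- vapply(seq_len(n_sim), function(i) {
    tr <- simulate_pairwise_trace(des, outcome_model(0.4), seed = 50000 + i,
                                  compute_bf = FALSE)
    c(tr$stop_reason == "success", tr$stop_n)
  }, numeric(2))
  p1 <- mean(eng[1, ]); p2 <- mean(pw[1, ])
  se_p <- sqrt(p1 * (1 - p1) / n_sim + p2 * (1 - p2) / n_sim)
  expect_lt(abs(p1 - p2), 3 * se_p + 1e-9)
  se_n <- sqrt(stats::var(eng[2, ]) / n_sim + stats::var(pw[2, ]) / n_sim)
  expect_lt(abs(mean(eng[2, ]) - mean(pw[2, ])), 3 * se_n)
})

test_that("the better challenger wins the promotion race", {
  des <- trial_design(n_min = 20, n_max = 60, step = 5)
  sch <- arm_schedule(c("C", "null", "good"), c(0, 0, 0.5))
  promoted <- vapply(seq_len(500), function(i) {
    h <- run_trial(des, sch, seed = 3000 + i, log_looks = FALSE)
    pr <- h$arms$arm_id[h$arms$status == "promoted"]
    if (length(pr)) pr[1L] else NA_character_
  }, "")
  expect_gt(sum(promoted == "good", na.rm = TRUE), 250)
  expect_gt(sum(promoted == "good", na.rm = TRUE),
            2 * sum(promoted == "null", na.rm = TRUE))
})

test_that("randomized scenarios conserve participants and keep one comparator", {
  for (case in 1:12) {
    seed <- 7000 + case
    k <- 2L + (case %% 3L)
    effects <- withr::with_seed(seed, round(stats::runif(k, -0.6, 0.9), 2))
    entries <- withr::with_seed(seed + 1L, {
      c("start", "start",
        if (k > 2L) sample(c("start", "on_drop"), k - 2L, replace = TRUE))
    })
    sch <- arm_schedule(paste0("arm", seq_len(k)), effects, entry = entries)
    des <- trial_design(n_min = 8, n_max = 20, bf_fail = 1 / 3,
                        bf_success = 3, step = 2L)
    h <- run_trial(des, sch, seed = seed, log_looks = FALSE)
    # conservation
    expect_identical(sum(h$per_arm_n), h$total_n)
    expect_identical(sum(vapply(h$arm_data, function(a) a$n, 0L)), h$total_n)
    # exactly one comparator at the end, and it is the reported one
    comps <- names(Filter(function(a) a$role == "comparator", h$arm_data))
    expect_identical(comps, h$final_comparator)
    # no resurrection: terminal arms recruit nothing after their drop event
    ev <- h$events
    for (kind in c("arm_dropped_fail", "arm_dropped_nmax")) {
      for (i in which(ev$event == kind)) {
        a <- h$arm_data[[ev$arm_id[i]]]
        expect_true(all(a$idx <= ev$index[i]))
      }
    }
    # challengers never exceed the cap; every arm entered exactly once
    for (a in h$arm_data) {
      if (a$role != "comparator") expect_lte(a$n, des$n_max)
    }
    expect_identical(sum(ev$event == "arm_entered"), length(h$arm_data))
    # single-comparator invariant holds through time: promotions pair with
    # retirements, in order
    pr <- ev$index[ev$event == "arm_promoted"]
    rt <- ev$index[ev$event == "comparator_retired"]
    expect_identical(pr, rt)
  }
})
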