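# shared fixtures: small designs and deterministic outcome tables

# compact design used where only the machinery (not the calibrated
# operating characteristics) is under test
small_design <- function(...) {
  args <- list(...)
  defaults <- list(n_min = 20, n_max = 60, bf_fail = 1 / 5, bf_success = 3,
                   rscale = 0.5, step = 5)
  do.call(trial_design, utils::modifyList(defaults, args))
}

# deterministic outcome tables for the hand-enumerated 3-challenger toy:
# values are fixed per (arm, participant index within arm), so the trial
# history is invariant to the within-block allocation order
toy_outcomes <- list(
  C = c(0.00, 0.10, -0.10, 0.05, 0.00, 0.10, -0.05, 0.00,
        0.05, -0.05, 0.10, 0.00, -0.10, 0.05, 0.00, 0.10),
  A = c(2.10, 1.90, 2.20, 2.00, 2.05, 1.95, 2.10, 2.00,
        1.90, 2.10, 2.00, 2.05, 1.95, 2.00, 2.10, 1.90),
  B = -c(2.00, 2.10, 1.90, 2.05, 2.00, 1.95, 2.10, 2.00,
         2.05, 1.95, 2.00, 2.10, 1.90, 2.00, 2.05, 1.95),
  D = -c(1.80, 2.00, 1.90, 2.10, 1.95, 2.00, 2.05, 1.90,
         2.00, 2.10, 1.95, 2.00, 1.90, 2.05, 2.00, 1.95))

toy_outcome_fn <- function(arm_id, k) toy_outcomes[[arm_id]][k]

# single-look tail probability from the noncentral-t distribution: the
# analytic oracle for a design with n_min = n_max (one look, equal allocation)
analytic_single_look <- function(design, d) {
  n <- design$n_min
  canon <- prior_spec(design$prior$rscale, "greater")
  thr <- leapfrog:::decision_thresholds(n, n, canon, design$bf_fail,
                                        design$bf_success)
  ncp <- d * sqrt(n / 2)
  df <- 2 * n - 2
  c(p_fail = 100 * stats::pt(thr[["t_fail"]], df, ncp),
    p_success = 100 * stats::pt(thr[["t_success"]], df, ncp,
                                lower.tail = FALSE))
}
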