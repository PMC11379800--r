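#' Arm schedule for a multi-arm leapfrog trial
#'
#' Declares the arms of a leapfrog trial: each arm has an identifier, a true
#' mean on the standardized outcome scale, and an entry trigger. Triggers are
#' `"start"` (recruiting from the first participant), `"on_drop"` (the arm is
#' queued and enters when an arm leaves the trial -- a failure drop, an
#' `n_max` drop, or the retirement of a replaced comparator; one queued arm
#' enters per such event, in schedule order), or a number (the arm enters once
#' that many participants have been randomized overall).
#'
#' @param arm_id Character vector of unique arm identifiers.
#' @param true_effect Numeric vector of true arm means (SD units); the
#'   comparator's mean is the benchmark the challengers' effects are relative
#'   to in a standardized model (conventionally 0).
#' @param entry Entry triggers, recycled if length 1 (default `"start"`).
#' @param comparator Which `arm_id` starts as the comparator (default the
#'   first); it must have entry `"start"`.
#' @return An object of class `leapfrog_schedule`.
#' @examples
#' arm_schedule(c("C", "a1", "a2", "a3", "a4"),
#'              c(0, 0, 0, 0.2, 0.2),
#'              entry = c("start", "start", "start", "start", "on_drop"))
#' @export
arm_schedule <- function(arm_id, true_effect, entry = "start",
                         comparator = arm_id[1L]) {
  arm_id <- as.character(arm_id)
  if (anyDuplicated(arm_id)) {
    stop_leapfrog("validation", "arm_id values must be unique")
  }
  n <- length(arm_id)
  stopifnot(length(true_effect) == n)
  entry <- rep_len(as.character(entry), n)
  num <- suppressWarnings(as.numeric(entry))
  bad <- is.na(num) & !entry %in% c("start", "on_drop")
  if (any(bad)) {
    stop_leapfrog("validation", sprintf(
      "entry: must be 'start', 'on_drop' or a participant index (bad: %s)",
      paste(entry[bad], collapse = ", ")))
  }
  if (!comparator %in% arm_id) {
    stop_leapfrog("validation", "comparator must be one of arm_id")
  }
  if (entry[match(comparator, arm_id)] != "start") {
    stop_leapfrog("validation", "the comparator arm must enter at trial start")
  }
  if (!any(entry == "start" & arm_id != comparator)) {
    stop_leapfrog("validation",
                  "the schedule needs at least one challenger at trial start")
  }
  structure(
    data.frame(arm_id = arm_id, true_effect = as.numeric(true_effect),
               entry = entry, stringsAsFactors = FALSE),
    comparator = comparator,
    class = c("leapfrog_schedule", "data.frame"))
}

# internal: fresh arm record
new_arm <- function(id, true_effect, entry_index, role) {
  list(id = id, true_effect = true_effect, entry_index = entry_index,
       role = role, status = "active", idx = integer(), y = numeric(),
       n = 0L, sum = 0, sumsq = 0,
       next_look_n = NA_integer_,
       # comparator outcomes contemporaneous with this challenger
       c_n = 0L, c_sum = 0, c_sumsq = 0,
       promoted_at = NA_integer_)
}

#' Contemporaneous comparator outcomes for a challenger
#'
#' Returns the comparator-arm outcomes whose global randomization index is at
#' least the challenger's entry index: the subset a challenger is compared to,
#' so that arms entering mid-trial are only judged against comparator
#' participants randomized during the same period. By default this includes
#' participants the comparator accrued before it was promoted (while still a
#' challenger itself), which is the package's reading of contemporaneity after
#' a promotion; set `all_phases = FALSE` to restrict to participants accrued
#' in the comparator role.
#'
#' @param comparator,challenger Arm records (elements of a trial history's
#'   `arm_data`), each with fields `idx`, `y`, `entry_index`, `promoted_at`.
#' @param all_phases Include the comparator's challenger-phase participants?
#' @return Numeric vector of comparator outcomes.
#' @export
contemporaneous_subset <- function(comparator, challenger, all_phases = TRUE) {
  keep <- comparator$idx >= challenger$entry_index
  if (!all_phases && !is.na(comparator$promoted_at)) {
    keep <- keep & comparator$idx > comparator$promoted_at
  }
  comparator$y[keep]
}

#' Run a multi-arm leapfrog trial
#'
#' Simulates a full leapfrog trial: participants are allocated by permuted
#' blocks over the recruiting arms (block size = number of recruiting arms,
#' re-formed whenever the active set changes), outcomes are drawn Normal with
#' the arm's true mean and common SD, and at each completed block every
#' challenger with at least `n_min` of its own participants and at least
#' `n_min` contemporaneous comparator participants is evaluated on the
#' design's cadence with the directional Bayes factor against the current
#' comparator. A challenger hitting `bf_fail` is dropped; one hitting
#' `bf_success` is promoted to comparator (the previous comparator retires,
#' and remaining challengers are evaluated against the new comparator from
#' their next look); a challenger reaching `n_max` undecided is dropped.
#' Scheduled arms enter on their triggers; the trial ends when no challenger
#' remains and no scheduled arm is left.
#'
#' @param design A [trial_design()].
#' @param schedule An [arm_schedule()].
#' @param seed Integer seed.
#' @param sd Common outcome SD.
#' @param comparator_nmax_exempt If `TRUE` (default) the current comparator
#'   keeps recruiting past `n_max` while it holds the comparator role;
#'   otherwise it stops recruiting at `n_max` (its data remain in use).
#' @param all_phases Contemporaneity rule after promotion; see
#'   [contemporaneous_subset()].
#' @param log_looks If `TRUE` (default) every look's Bayes factor is computed
#'   by quadrature and logged; with `FALSE` only boundary decisions (exact
#'   either way, via t-scale thresholds) are logged, which is much faster for
#'   large simulation studies.
#' @param outcome_fn Optional deterministic outcome generator
#'   `function(arm_id, k)` giving arm `arm_id`'s k-th outcome (testing and
#'   audit hook; replaces the Normal draws).
#' @return An object of class `leapfrog_history`: `events` (data frame with
#'   `index`, `event`, `arm_id`, `bf`, `n_arm`, `n_comparator`), `arms`
#'   (per-arm summary), `per_arm_n`, `total_n`, `final_comparator`, and
#'   `arm_data` (full per-arm records for [contemporaneous_subset()]).
#' @examples
#' \donttest{
#' sched <- arm_schedule(c("C", "a1"), c(0, 0.5))
#' run_trial(trial_design(n_min = 30, n_max = 60, step = 10), sched, seed = 1,
#'           log_looks = FALSE)
#' }
#' @export
run_trial <- function(design, schedule, seed, sd = 1,
                      comparator_nmax_exempt = TRUE, all_phases = TRUE,
                      log_looks = TRUE, outcome_fn = NULL) {
  stopifnot(inherits(design, "leapfrog_design"),
            inherits(schedule, "leapfrog_schedule"))
  with_seed(seed, {
    leapfrog_run(design, schedule, sd, comparator_nmax_exempt, all_phases,
                 log_looks, outcome_fn, script = NULL, seed = seed)
  })
}

#' Replay a scripted leapfrog scenario
#'
#' Deterministic bookkeeping audit of the engine: instead of simulating
#' outcomes and Bayes factors, boundary decisions are forced by a script of
#' `(arm_id, action, at_n)` steps -- arm `arm_id` hits the stated boundary at
#' exactly `at_n` of its own participants. Allocation is deterministic
#' round-robin over recruiting arms (per-arm totals are invariant to
#' within-block order), so the resulting per-arm totals and total sample size
#' audit the engine's accounting of a narrated trajectory.
#'
#' @param script Data frame with columns `arm_id`, `action` (`"fail"` or
#'   `"promote"`), `at_n` (per-arm n at which the decision fires).
#' @param design A [trial_design()].
#' @param schedule An [arm_schedule()].
#' @inheritParams run_trial
#' @return A `leapfrog_history` (Bayes-factor column all `NA`).
#' @examples
#' sc <- leapfrog_demo_scenario()
#' replay_scenario(sc$script, sc$design, sc$schedule)$total_n
#' @export
replay_scenario <- function(script, design, schedule,
                            comparator_nmax_exempt = TRUE, all_phases = TRUE) {
  stopifnot(inherits(design, "leapfrog_design"),
            inherits(schedule, "leapfrog_schedule"))
  script <- as.data.frame(script)
  need <- c("arm_id", "action", "at_n")
  if (!all(need %in% names(script))) {
    stop_leapfrog("script", "script needs columns arm_id, action, at_n")
  }
  if (!all(script$action %in% c("fail", "promote"))) {
    stop_leapfrog("script", "script actions must be 'fail' or 'promote'")
  }
  bad <- script$at_n < design$n_min | script$at_n > design$n_max
  if (any(bad)) {
    stop_leapfrog("script", sprintf(
      "script step %s/%s at_n=%g outside [n_min, n_max]",
      script$arm_id[bad][1L], script$action[bad][1L], script$at_n[bad][1L]))
  }
  leapfrog_run(design, schedule, sd = 1, comparator_nmax_exempt, all_phases,
               log_looks = FALSE, outcome_fn = NULL, script = script,
               seed = NA_integer_)
}

# Shared engine loop for run_trial (script = NULL) and replay_scenario.
leapfrog_run <- function(design, schedule, sd, comparator_nmax_exempt,
                         all_phases, log_looks, outcome_fn, script, seed) {
  canon <- prior_spec(design$prior$rscale, "greater")
  sgn <- if (design$prior$direction == "less") -1 else 1
  scripted <- !is.null(script)
  if (scripted) script$fired <- FALSE

  comp_id <- attr(schedule, "comparator")
  arms <- list()
  entry_order <- character()
  pending_on_drop <- character()
  pending_indexed <- schedule[!(schedule$entry %in% c("start", "on_drop")), ,
                              drop = FALSE]
  g <- 0L
  ev_idx <- integer(); ev_kind <- character(); ev_arm <- character()
  ev_bf <- numeric(); ev_na <- integer(); ev_nc <- integer()
  log_event <- function(kind, arm, bf = NA_real_, n_arm = NA_integer_,
                        n_comp = NA_integer_) {
    ev_idx[length(ev_idx) + 1L] <<- g
    ev_kind[length(ev_kind) + 1L] <<- kind
    ev_arm[length(ev_arm) + 1L] <<- arm
    ev_bf[length(ev_bf) + 1L] <<- bf
    ev_na[length(ev_na) + 1L] <<- n_arm
    ev_nc[length(ev_nc) + 1L] <<- n_comp
  }
  enter_arm <- function(id) {
    row <- schedule[schedule$arm_id == id, ]
    role <- if (id == comp_id) "comparator" else "challenger"
    a <- new_arm(id, row$true_effect, g + 1L, role)
    if (role == "challenger") a$next_look_n <- design$n_min
    arms[[id]] <<- a
    entry_order <<- c(entry_order, id)
    log_event("arm_entered", id)
  }
  fire_entry <- function() {
    if (length(pending_on_drop)) {
      id <- pending_on_drop[1L]
      pending_on_drop <<- pending_on_drop[-1L]
      enter_arm(id)
    }
  }
  current_comparator <- function() {
    for (a in arms) if (a$role == "comparator") return(a$id)
    NA_character_
  }
  active_challengers <- function() {
    ids <- character()
    for (id in entry_order) {
      a <- arms[[id]]
      if (a$role == "challenger" && a$status == "active") ids <- c(ids, id)
    }
    ids
  }
  # rebuild a challenger's contemporaneous accumulators against comparator cid
  rebuild_contemp <- function(ch_id, cid) {
    comp <- arms[[cid]]; ch <- arms[[ch_id]]
    keep <- comp$idx >= ch$entry_index
    if (!all_phases && !is.na(comp$promoted_at)) {
      keep <- keep & comp$idx > comp$promoted_at
    }
    yy <- comp$y[keep]
    arms[[ch_id]]$c_n <<- length(yy)
    arms[[ch_id]]$c_sum <<- sum(yy)
    arms[[ch_id]]$c_sumsq <<- sum(yy^2)
  }

  for (id in schedule$arm_id[schedule$entry == "start"]) enter_arm(id)
  pending_on_drop <- schedule$arm_id[schedule$entry == "on_drop"]
  if (is.na(current_comparator())) {
    stop_leapfrog("validation", "schedule supplies no comparator at start")
  }

  repeat {
    cid <- current_comparator()
    recruiting <- character()
    for (id in entry_order) {
      a <- arms[[id]]
      if (a$status %in% c("active", "promoted")) {
        cap_ok <- if (a$role == "comparator" && comparator_nmax_exempt) TRUE
                  else a$n < design$n_max
        if (cap_ok) recruiting <- c(recruiting, id)
      }
    }
    block <- if (scripted) recruiting
             else recruiting[sample.int(length(recruiting))]
    for (id in block) {
      g <- g + 1L
      yv <- if (!is.null(outcome_fn)) outcome_fn(id, arms[[id]]$n + 1L)
            else stats::rnorm(1L, arms[[id]]$true_effect, sd)
      if (scripted) yv <- 0
      arms[[id]]$idx <- c(arms[[id]]$idx, g)
      arms[[id]]$y <- c(arms[[id]]$y, yv)
      arms[[id]]$n <- arms[[id]]$n + 1L
      arms[[id]]$sum <- arms[[id]]$sum + yv
      arms[[id]]$sumsq <- arms[[id]]$sumsq + yv^2
      if (id == cid) {
        for (chid in active_challengers()) {
          arms[[chid]]$c_n <- arms[[chid]]$c_n + 1L
          arms[[chid]]$c_sum <- arms[[chid]]$c_sum + yv
          arms[[chid]]$c_sumsq <- arms[[chid]]$c_sumsq + yv^2
        }
      }
    }

    # decision sweep at the block boundary, in arm-entry order
    for (chid in active_challengers()) {
      ch <- arms[[chid]]
      decision <- NULL
      bfv <- NA_real_
      if (scripted) {
        hit <- which(!script$fired & script$arm_id == chid &
                       script$at_n == ch$n)
        if (length(hit)) {
          hit <- hit[1L]
          if (ch$c_n < design$n_min) {
            stop_leapfrog("script", sprintf(
              "script step %s/%s at_n=%d infeasible: only %d contemporaneous comparator participants (< n_min = %d)",
              chid, script$action[hit], script$at_n[hit], ch$c_n,
              design$n_min))
          }
          script$fired[hit] <- TRUE
          decision <- script$action[hit]
          log_event("look_evaluated", chid, NA_real_, ch$n, ch$c_n)
        }
      } else if (ch$n >= ch$next_look_n && ch$c_n >= design$n_min) {
        n1 <- ch$n; n2 <- ch$c_n
        pv <- (ch$sumsq - ch$sum^2 / n1 + ch$c_sumsq - ch$c_sum^2 / n2) /
          (n1 + n2 - 2)
        tval <- (ch$sum / n1 - ch$c_sum / n2) / sqrt(pv * (1 / n1 + 1 / n2))
        thr <- decision_thresholds(n1, n2, canon, design$bf_fail,
                                   design$bf_success)
        s <- sgn * tval
        if (log_looks) bfv <- jzs_bf(t_stat(tval, n1, n2), design$prior)$bf
        log_event("look_evaluated", chid, bfv, n1, n2)
        if (s <= thr[["t_fail"]]) decision <- "fail"
        else if (s >= thr[["t_success"]]) decision <- "promote"
        arms[[chid]]$next_look_n <- ch$n + design$step
      }
      if (identical(decision, "fail")) {
        arms[[chid]]$status <- "dropped_fail"
        log_event("arm_dropped_fail", chid, bfv, ch$n, ch$c_n)
        fire_entry()
      } else if (identical(decision, "promote")) {
        arms[[cid]]$status <- "retired"
        arms[[cid]]$role <- "retired"
        log_event("comparator_retired", cid, NA_real_, arms[[cid]]$n)
        arms[[chid]]$role <- "comparator"
        arms[[chid]]$status <- "promoted"
        arms[[chid]]$promoted_at <- g
        log_event("arm_promoted", chid, bfv, ch$n, ch$c_n)
        fire_entry()
        cid <- chid
        for (other in active_challengers()) rebuild_contemp(other, cid)
        # remaining challengers are re-evaluated at their next look against
        # the new comparator; scripted decisions are forced, so a replay
        # sweep continues (simultaneous narrated events stay simultaneous)
        if (!scripted) break
      } else if (arms[[chid]]$status == "active" && ch$n >= design$n_max) {
        arms[[chid]]$status <- "dropped_nmax"
        log_event("arm_dropped_nmax", chid, bfv, ch$n, ch$c_n)
        fire_entry()
      }
    }

    # indexed entries whose trigger has been reached
    if (nrow(pending_indexed)) {
      due <- as.numeric(pending_indexed$entry) <= g + 1L
      for (id in pending_indexed$arm_id[due]) enter_arm(id)
      pending_indexed <- pending_indexed[!due, , drop = FALSE]
    }
    if (!length(active_challengers())) {
      # nothing left under test: release any still-scheduled arm now
      if (length(pending_on_drop)) fire_entry()
      else if (nrow(pending_indexed)) {
        enter_arm(pending_indexed$arm_id[1L])
        pending_indexed <- pending_indexed[-1L, , drop = FALSE]
      } else break
    }
  }

  if (scripted && any(!script$fired)) {
    i <- which(!script$fired)[1L]
    stop_leapfrog("script", sprintf(
      "script step %s/%s at_n=%d never fired (arm never evaluated at that n)",
      script$arm_id[i], script$action[i], script$at_n[i]))
  }

  per_arm_n <- vapply(arms[entry_order], function(a) a$n, integer(1))
  names(per_arm_n) <- entry_order
  summary_df <- data.frame(
    arm_id = entry_order,
    true_effect = vapply(arms[entry_order], function(a) a$true_effect, 0),
    entry_index = vapply(arms[entry_order], function(a) a$entry_index, 0L),
    status = vapply(arms[entry_order], function(a) a$status, ""),
    n = per_arm_n, row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(events = data.frame(index = ev_idx, event = ev_kind, arm_id = ev_arm,
                             bf = ev_bf, n_arm = ev_na, n_comparator = ev_nc,
                             stringsAsFactors = FALSE),
         arms = summary_df, per_arm_n = per_arm_n, total_n = g,
         final_comparator = current_comparator(),
         arm_data = arms, design = design, seed = seed),
    class = "leapfrog_history")
}

#' @export
print.leapfrog_history <- function(x, ...) {
  cat(sprintf("Leapfrog trial history: %d participants, %d arms, final comparator '%s'\n",
              x$total_n, nrow(x$arms), x$final_comparator))
  print(x$arms)
  invisible(x)
}

#' A worked five-challenger leapfrog scenario
#'
#' The package's running example of a full leapfrog trajectory under the
#' default design: three personalization variants (arms 1-3) start against a
#' standard-care comparator C; arm 1 fails at 150/arm and arm 4 enters; at
#' 200/arm arm 3 is promoted (C retires at 200) and arm 2 fails; arm 5 enters;
#' arm 4 is promoted at 200 of its own participants against comparator arm 3,
#' at which point arm 5 fails at 150. Replaying it audits the engine's
#' accounting: 1,250 participants to test five challenger methods.
#'
#' @return A list with elements `design`, `schedule` and `script`, ready for
#'   [replay_scenario()].
#' @examples
#' sc <- leapfrog_demo_scenario()
#' hist <- replay_scenario(sc$script, sc$design, sc$schedule)
#' hist$per_arm_n
#' @export
leapfrog_demo_scenario <- function() {
  list(
    design = trial_design(),
    schedule = arm_schedule(
      arm_id = c("C", "arm1", "arm2", "arm3", "arm4", "arm5"),
      true_effect = c(0, 0, 0, 0.2, 0.4, 0.2),
      entry = c("start", "start", "start", "start", "on_drop", "on_drop"),
      comparator = "C"),
    script = data.frame(
      arm_id = c("arm1", "arm3", "arm2", "arm4", "arm5"),
      action = c("fail", "promote", "fail", "promote", "fail"),
      at_n = c(150, 200, 200, 200, 150),
      stringsAsFactors = FALSE))
}
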