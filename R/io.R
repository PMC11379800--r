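#' Load a run configuration from YAML or JSON
#'
#' Reads and validates a trial-run configuration. The file must contain a
#' `design` block (fields of [trial_design()]); it may contain a `seed`
#' (mandatory for any stochastic command -- there is no default seed, so a
#' published run is always reproducible from its config), an `n_reps` count,
#' an OC `scenario` (`effect_grid` + `checkpoints`) or an arm-schedule
#' `scenario` (`arms` with `arm_id`, `true_effect`, `entry`, plus
#' `comparator`), and an `output` path. Schema violations are reported with
#' their field paths.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An object of class `leapfrog_config`: a list with `design`
#'   ([trial_design()]), and any of `seed`, `n_reps`, `effect_grid`,
#'   `checkpoints`, `schedule` ([arm_schedule()]) and `output` present in the
#'   file.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_leapfrog("validation", sprintf("config file not found: %s", path))
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  problems <- character()
  if (is.null(raw$design)) {
    stop_leapfrog("validation", "design: block is required")
  }
  allowed <- c("n_min", "n_max", "bf_fail", "bf_success", "rscale",
               "direction", "step", "allocation")
  unknown <- setdiff(names(raw$design), allowed)
  if (length(unknown)) {
    problems <- c(problems,
                  paste0("design.", unknown, ": unknown field"))
  }
  design <- tryCatch(do.call(trial_design, raw$design[
    intersect(names(raw$design), allowed)]),
    leapfrog_error = function(e) {
      problems <<- c(problems,
                     paste0("design.", sub("^invalid trial design:\\n\\s*", "",
                                           conditionMessage(e))))
      NULL
    })
  cfg <- list(design = design)
  if (!is.null(raw$seed)) {
    if (!is.numeric(raw$seed) || length(raw$seed) != 1L ||
        raw$seed != floor(raw$seed)) {
      problems <- c(problems, "seed: must be a single integer")
    } else cfg$seed <- as.integer(raw$seed)
  }
  if (!is.null(raw$n_reps)) {
    if (!is.numeric(raw$n_reps) || raw$n_reps < 1) {
      problems <- c(problems, "n_reps: must be a positive count")
    } else cfg$n_reps <- as.integer(raw$n_reps)
  }
  sc <- raw$scenario
  if (!is.null(sc)) {
    if (!is.null(sc$effect_grid)) {
      if (!is.numeric(sc$effect_grid)) {
        problems <- c(problems, "scenario.effect_grid: must be numeric")
      } else cfg$effect_grid <- as.numeric(sc$effect_grid)
      if (is.null(sc$checkpoints) || !is.numeric(sc$checkpoints)) {
        problems <- c(problems,
                      "scenario.checkpoints: required with effect_grid")
      } else cfg$checkpoints <- as.integer(sc$checkpoints)
    } else if (!is.null(sc$arms)) {
      arms <- as.data.frame(sc$arms)
      if (!all(c("arm_id", "true_effect") %in% names(arms))) {
        problems <- c(problems,
                      "scenario.arms: needs arm_id and true_effect")
      } else {
        cfg$schedule <- tryCatch(
          arm_schedule(arms$arm_id, arms$true_effect,
                       entry = if (is.null(arms$entry)) "start" else arms$entry,
                       comparator = if (is.null(sc$comparator)) arms$arm_id[1L]
                                    else sc$comparator),
          leapfrog_error = function(e) {
            problems <<- c(problems,
                           paste0("scenario.arms: ", conditionMessage(e)))
            NULL
          })
      }
    } else {
      problems <- c(problems,
                    "scenario: needs either effect_grid/checkpoints or arms")
    }
  }
  if (!is.null(raw$output)) cfg$output <- as.character(raw$output)
  if (length(problems)) {
    stop_leapfrog("validation",
                  paste0("invalid config '", path, "':\n  ",
                         paste(problems, collapse = "\n  ")))
  }
  structure(cfg, class = "leapfrog_config")
}

# refuse to clobber an existing file unless forced
check_overwrite <- function(paths, overwrite) {
  hit <- paths[file.exists(paths)]
  if (length(hit) && !overwrite) {
    stop_leapfrog("validation", sprintf(
      "output exists (use overwrite = TRUE): %s", paste(hit, collapse = ", ")))
  }
}

#' Write an operating-characteristics report
#'
#' Writes three files for an [estimate_oc()] result: a wide CSV laid out like
#' the calibration table (one row per true effect; failure-boundary columns,
#' then success-boundary columns, one per checkpoint), a tidy long CSV (one
#' row per effect x checkpoint with probabilities and Monte-Carlo standard
#' errors), and a JSON metadata file recording the design, replication count
#' and seed, so the report is regenerable from its metadata alone.
#'
#' @param oc A `leapfrog_oc` from [estimate_oc()].
#' @param dir Output directory (created if missing).
#' @param basename Stem for the three file names.
#' @param overwrite Overwrite existing files? Default `FALSE`.
#' @return Invisibly, the paths written (named `wide`, `long`, `meta`).
#' @export
write_oc_report <- function(oc, dir, basename = "oc", overwrite = FALSE) {
  stopifnot(inherits(oc, "leapfrog_oc"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(wide = file.path(dir, paste0(basename, "_wide.csv")),
             long = file.path(dir, paste0(basename, "_long.csv")),
             meta = file.path(dir, paste0(basename, "_meta.json")))
  check_overwrite(paths, overwrite)
  wide <- data.frame(d = oc$effect_grid, oc$p_fail, oc$p_success,
                     check.names = FALSE)
  names(wide) <- c("d", paste0("p_fail_", oc$checkpoints),
                   paste0("p_success_", oc$checkpoints))
  utils::write.csv(wide, paths[["wide"]], row.names = FALSE)
  grid <- expand.grid(checkpoint = oc$checkpoints, d = oc$effect_grid)
  long <- data.frame(
    d = grid$d, checkpoint = grid$checkpoint,
    p_fail = as.vector(t(oc$p_fail)), p_success = as.vector(t(oc$p_success)),
    mc_se_fail = as.vector(t(oc$mc_se_fail)),
    mc_se_success = as.vector(t(oc$mc_se_success)))
  # full 17-significant-digit decimal so the report round-trips bit-exactly
  long_txt <- long
  for (cl in names(long_txt)) {
    if (is.double(long_txt[[cl]])) {
      long_txt[[cl]] <- sprintf("%.17g", long_txt[[cl]])
    }
  }
  utils::write.csv(long_txt, paths[["long"]], row.names = FALSE,
                   quote = FALSE)
  des <- oc$design
  meta <- list(design = list(n_min = des$n_min, n_max = des$n_max,
                             bf_fail = des$bf_fail,
                             bf_success = des$bf_success,
                             rscale = des$prior$rscale,
                             direction = des$prior$direction,
                             step = des$step, allocation = des$allocation),
               n_reps = oc$n_reps, seed = oc$seed,
               effect_grid = oc$effect_grid, checkpoints = oc$checkpoints)
  jsonlite::write_json(meta, paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read an operating-characteristics report back
#'
#' Rebuilds the `leapfrog_oc` object from the long CSV and JSON metadata
#' written by [write_oc_report()]; a written report round-trips exactly.
#'
#' @inheritParams write_oc_report
#' @return A `leapfrog_oc`.
#' @export
read_oc_report <- function(dir, basename = "oc") {
  long <- utils::read.csv(file.path(dir, paste0(basename, "_long.csv")))
  meta <- jsonlite::read_json(file.path(dir, paste0(basename, "_meta.json")),
                              simplifyVector = TRUE)
  effects <- meta$effect_grid
  checkpoints <- as.integer(meta$checkpoints)
  shape <- function(col) {
    matrix(long[[col]], nrow = length(effects), ncol = length(checkpoints),
           byrow = TRUE,
           dimnames = list(format(effects), as.character(checkpoints)))
  }
  d <- meta$design
  design <- trial_design(d$n_min, d$n_max, d$bf_fail, d$bf_success, d$rscale,
                         d$direction, d$step, d$allocation)
  structure(
    list(effect_grid = effects, checkpoints = checkpoints,
         p_fail = shape("p_fail"), p_success = shape("p_success"),
         mc_se_fail = shape("mc_se_fail"),
         mc_se_success = shape("mc_se_success"),
         n_reps = as.integer(meta$n_reps), seed = as.integer(meta$seed),
         design = design, crossings = NULL),
    class = "leapfrog_oc")
}

#' Write a trial history as an event log and per-arm summary
#'
#' Serializes a [run_trial()]/[replay_scenario()] history as a JSONL event log
#' (one event per line) plus a per-arm summary CSV.
#'
#' @param history A `leapfrog_history`.
#' @inheritParams write_oc_report
#' @return Invisibly, the paths written (named `events`, `arms`).
#' @export
write_history <- function(history, dir, basename = "trial",
                          overwrite = FALSE) {
  stopifnot(inherits(history, "leapfrog_history"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(events = file.path(dir, paste0(basename, "_events.jsonl")),
             arms = file.path(dir, paste0(basename, "_arms.csv")))
  check_overwrite(paths, overwrite)
  lines <- vapply(seq_len(nrow(history$events)), function(i) {
    jsonlite::toJSON(as.list(history$events[i, ]), auto_unbox = TRUE,
                     digits = NA, na = "null")
  }, character(1))
  writeLines(lines, paths[["events"]])
  utils::write.csv(history$arms, paths[["arms"]], row.names = FALSE)
  invisible(paths)
}

#' Read raw trial outcomes from CSV
#'
#' Reads a live-trial outcome file with one row per randomized participant:
#' `participant_index` (global randomization order), `arm_id`, `outcome`.
#'
#' @param path CSV path.
#' @return A validated data frame ordered by `participant_index`.
#' @export
read_outcomes_csv <- function(path) {
  if (!file.exists(path)) {
    stop_leapfrog("validation", sprintf("outcome file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_index", "arm_id", "outcome")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_leapfrog("validation", sprintf(
      "outcome CSV is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!is.numeric(df$participant_index) || anyDuplicated(df$participant_index)) {
    stop_leapfrog("validation",
                  "participant_index: must be unique numeric randomization order")
  }
  if (!is.numeric(df$outcome) || anyNA(df$outcome)) {
    stop_leapfrog("validation", "outcome: must be numeric with no NA")
  }
  df[order(df$participant_index), need]
}

#' Sequential Bayes-factor analysis of raw two-arm outcome data
#'
#' Applies a design's sequential analysis to accumulated real data for one
#' challenger against the comparator: looks start once the challenger and its
#' contemporaneous comparator subset both have `n_min` participants, recur on
#' the design's cadence (per challenger participant), and stop at the first
#' boundary crossing. The comparator subset at a look is restricted to
#' participants randomized at or after the challenger's first participant.
#'
#' @param data Data frame as returned by [read_outcomes_csv()].
#' @param design A [trial_design()].
#' @param challenger,comparator Arm identifiers in `data`.
#' @return A `leapfrog_trace` whose looks carry the observed Bayes factors;
#'   `stop_reason` is `"none"` if the data run out before any boundary or cap
#'   is reached.
#' @export
sequential_bf <- function(data, design, challenger, comparator) {
  stopifnot(inherits(design, "leapfrog_design"))
  ids <- unique(data$arm_id)
  for (a in c(challenger, comparator)) {
    if (!a %in% ids) {
      stop_leapfrog("validation", sprintf("arm '%s' not present in data", a))
    }
  }
  ch <- data[data$arm_id == challenger, ]
  entry <- min(ch$participant_index)
  co <- data[data$arm_id == comparator & data$participant_index >= entry, ]
  sgn <- if (design$prior$direction == "less") -1 else 1
  canon <- prior_spec(design$prior$rscale, "greater")
  look_n <- design_looks(design)
  looks <- list(); stop_reason <- "none"; stop_n <- NA_integer_
  for (n1 in look_n) {
    if (n1 > nrow(ch)) break
    cutoff <- ch$participant_index[n1]
    y2 <- co$outcome[co$participant_index <= cutoff]
    n2 <- length(y2)
    if (n2 < design$n_min) next
    ts <- two_sample_t(ch$outcome[seq_len(n1)], y2)
    bf <- jzs_bf(ts, design$prior)$bf
    looks[[length(looks) + 1L]] <- data.frame(n = n1, t = ts$t, bf = bf)
    thr <- decision_thresholds(n1, n2, canon, design$bf_fail,
                               design$bf_success)
    s <- sgn * ts$t
    if (s <= thr[["t_fail"]]) { stop_reason <- "fail"; stop_n <- n1; break }
    if (s >= thr[["t_success"]]) { stop_reason <- "success"; stop_n <- n1; break }
    if (n1 >= design$n_max) { stop_reason <- "nmax"; stop_n <- n1; break }
  }
  structure(
    list(looks = if (length(looks)) do.call(rbind, looks)
                 else data.frame(n = integer(), t = numeric(), bf = numeric()),
         stop_reason = stop_reason, stop_n = stop_n,
         design = design,
         model = structure(list(effect = NA_real_, sd = NA_real_,
                                comparator_mean = NA_real_),
                           class = "leapfrog_model"),
         seed = NA_integer_),
    class = "leapfrog_trace")
}
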