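# shared helpers: error signalling, seeded RNG scope, threshold cache

.leapfrog_cache <- new.env(parent = emptyenv())

stop_leapfrog <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("leapfrog_", class, "_error"), "leapfrog_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)))
}

# Evaluate expr with a locally-seeded RNG, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (is.null(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_leapfrog("validation", "a finite integer seed is required")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Cached (t_fail, t_success) decision thresholds for one (n1, n2) look.
# Keys the cache on everything the threshold depends on; warm starts from the
# nearest previously-solved look so threshold tables over a whole design cost
# only a few Bayes-factor evaluations per look.
decision_thresholds <- function(n1, n2, prior, bf_fail, bf_success) {
  key <- paste(n1, n2, prior$rscale, prior$direction, bf_fail, bf_success,
               sep = "|")
  hit <- .leapfrog_cache[[key]]
  if (!is.null(hit)) return(hit)
  warm <- .leapfrog_cache[[paste0("warm|", prior$rscale, "|", prior$direction,
                                  "|", bf_fail, "|", bf_success)]]
  gf <- if (!is.null(warm)) warm[1L] else NULL
  gs <- if (!is.null(warm)) warm[2L] else NULL
  tf <- bf_threshold_t(n1, n2, prior, bf_fail, guess = gf)
  ts <- bf_threshold_t(n1, n2, prior, bf_success, guess = gs)
  out <- c(t_fail = tf, t_success = ts)
  .leapfrog_cache[[key]] <- out
  .leapfrog_cache[[paste0("warm|", prior$rscale, "|", prior$direction,
                          "|", bf_fail, "|", bf_success)]] <- c(tf, ts)
  out
}
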