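---
title: "Methods: sequential Bayes-factor design analysis for leapfrog trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential Bayes-factor design analysis for leapfrog trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leapfrog)
```

## The design being analysed

A leapfrog trial keeps one *comparator* arm (the current benchmark
treatment) and any number of *challenger* arms recruiting in parallel.
Once a challenger and its contemporaneous comparator data both reach a
minimum per-arm size `n_min`, the evidence for the challenger's
superiority is re-evaluated sequentially with a directional Bayes factor.
Three absorbing rules then govern the trial:

* **drop**: BF falls to `bf_fail` — the challenger leaves the trial;
* **promote**: BF rises to `bf_success` — the challenger becomes the new
  comparator and the old comparator retires;
* **cap**: a challenger reaching `n_max` undecided is dropped.

New arms may enter an ongoing trial; they are compared only against
comparator participants randomized from their own entry onward, so that
secular drift in the recruited population cannot masquerade as a treatment
difference.

## Outcome model and what the simulator does (and does not) emulate

The generative model behind all simulations is deliberately minimal and is
exactly the model the sequential analysis assumes: one continuous outcome
per participant, Normal with common SD, the challenger's mean shifted by
`effect * sd` (Cohen's d). This is the right granularity for *design
analysis* — choosing boundaries and sample-size limits — because the
operating characteristics of the BF boundaries depend on the data only
through the sequence of t statistics.

It does **not** emulate features of real trial data: dropout and missing
outcomes, stratification and covariates, site or therapist clustering,
drifting outcome variance, or delayed outcome ascertainment (participants
are analysable the moment they are randomized). Passing operating
characteristics therefore say what a design would do *if the analysis
model held*; for a live trial with richer structure, the same boundary
logic would be driven by the appropriate model-based Bayes factor instead,
and the design analysis should be re-run under that model.

## The directional JZS Bayes factor

Evidence is measured by the Jeffreys–Zellner–Siow two-sample Bayes factor
parameterized by the summary `(t, n1, n2)`: under the alternative the
standardized effect `delta` has a Cauchy(0, `rscale`) prior, truncated to
`delta > 0` for the directional (superiority) test; the null is the point
`delta = 0`. The marginal likelihood under the alternative integrates the
noncentral-t density (noncentrality `delta * sqrt(n_eff)`) over the prior.
The `(t, n1, n2)` parameterization means the same engine serves simulated
summaries and raw data (`two_sample_t()`, `sequential_bf()`).

Two conventions are fixed and documented rather than configurable
per-call:

* **Sign convention.** Superiority means `delta > 0` with higher outcomes
  better; a design-level `direction = "less"` flips the orientation for
  lower-is-better measures (internally, t is reflected — the two are
  mirror images).
* **Pooled, not Welch.** The carrier statistic is the equal-variance
  pooled t, matching the standardized outcome model in which a common SD
  is assumed.

### Numerical evaluation

The prior integral is computed by adaptive quadrature **on the prior's
quantile scale**: substituting `u = F(delta)` (Cauchy CDF) turns the
integral into one of the likelihood over `u` in (0, 1). This compresses
the heavy Cauchy tails into a bounded domain, so no truncation of the
integration limits is needed and the full prior tail mass is retained by
construction. The domain is split at the likelihood peak
(`delta = t / sqrt(n_eff)`, which becomes very narrow at large n) before
calling the adaptive integrator, with relative tolerance `1e-8` — orders
of magnitude finer than the ~1% accuracy that boundaries like 1/5 and 3
actually require.

Two numerical regimes deserve note:

* **Deep tails.** R evaluates the noncentral-t density through a
  difference formula whose rounding noise dominates when the density is
  many orders of magnitude below its peak (|t| of several tens). There a
  pure relative tolerance is unattainable; pieces are then accepted
  against an absolute tolerance that is negligible on the Bayes-factor
  scale (at worst ~1e-4 relative). Decisions are unaffected — these t
  values are far beyond any plausible boundary.
* **A lower asymptote.** Because both marginal likelihoods have
  polynomial (Cauchy-induced) tails, the directional BF does not tend to
  zero as t decreases: it flattens onto a positive floor (about 0.27 at
  n = 4 per arm, 0.12 at n = 10, smaller as n grows). A failure boundary
  below that floor is simply unreachable at that sample size; the
  threshold machinery detects this and maps it to an infinite t threshold
  (the boundary is never crossed), which is also how "unreachable
  boundary" stress scenarios are expressed.

An independent Monte-Carlo oracle (`oracle_bf_mc()`) estimates the same
ratio by averaging the noncentral-t density over inverse-CDF draws from
the truncated prior, with a standard error; the test suite requires
quadrature/oracle agreement across a grid of t, n and `rscale`. The
two-sided quadrature was additionally verified (to six decimals, during
development) against an independent implementation that evaluates the same
model through the marginalized g-integral form.

## From boundaries to thresholds: the simulation engine

At fixed `(n1, n2, rscale)` the directional BF is strictly increasing in
t. Each decision boundary therefore corresponds to an exact t-scale
threshold, found once per look by root-finding `log BF(t) = log b`
(warm-started along the look grid, cached across calls). Simulating a
sequential comparison then requires no quadrature at all: outcome paths
are drawn to `n_max` per arm, running pooled-t statistics are formed at
every look from cumulative sums, and the first threshold crossing is the
boundary event. This is exact — not an approximation — by monotonicity,
and it is what makes fully sequential (step = 1) operating
characteristics at 10^4–10^5 replications a matter of seconds.

`simulate_pairwise_trace()` additionally reports the BF at every look (by
quadrature) for inspection; `estimate_oc()` reports cumulative
boundary-crossing percentages by checkpoint with binomial Monte-Carlo
standard errors; `first_look_probabilities()` is the single-look fast
path. For a design with `n_min = n_max` (one look) the success
probability has a closed form — the noncentral-t tail beyond the success
threshold — which the test suite uses as an analytic oracle for the
simulator.

### Randomness and reproducibility

Every stochastic entry point takes a mandatory integer seed and restores
the caller's RNG state afterwards; the same seed reproduces a trace, an
OC table or a trial history exactly. Within one OC run, outcome paths are
drawn as a single seeded vectorized block (chunked at 5,000 replications)
rather than as one named RNG stream per replication: R's base generator
has no cheap substream API, and block drawing is precisely what makes the
fully sequential cadence affordable. Determinism under a fixed seed — the
property the reproducibility contract needs — is preserved.

## Analysis cadence

How often the BF is recomputed ("every `step` participants per arm") is a
genuine free parameter of a sequential design, and cumulative
boundary-crossing probabilities at interior checkpoints **depend on it**:
more frequent looks give more chances to cross, so crossing probabilities
increase as `step` shrinks. First-look cells do not depend on cadence,
and the terminal (by-`n_max`) success probabilities are nearly
cadence-invariant in practice. The package defaults to `step = 1` — the
finest, fully sequential reading — and exposes coarser cadences in
`trial_design()`. When comparing against published calibration tables,
bear in mind that interior failure-boundary cells can shift by a few
percentage points between step 1 and step 10; the tolerance used in this
package's own checks reflects that.

## The multi-arm engine

`run_trial()` allocates participants by permuted blocks over the
recruiting arms (block size = number of recruiting arms, blocks re-formed
whenever the active set changes), so arms recruited in the same period
accrue at the same rate. Decisions are evaluated at block boundaries —
the moment every recruiting arm has just gained one participant — which
keeps per-arm counts exactly equal within a recruitment generation,
makes per-arm totals of narrated scenarios exactly reproducible, and
reduces the two-arm trial to the pairwise simulator's look schedule (a
property the test suite checks distributionally).

Design decisions in the engine, each a point on which reasonable
implementations could differ:

* **Contemporaneity after promotion.** A challenger's comparator subset
  is every comparator-arm participant with randomization index at or
  after the challenger's entry — *including* participants the new
  comparator accrued while still a challenger. This is the reading under
  which a promoted arm's full concurrent data remain usable, and it is
  what makes the package's worked five-challenger scenario account add up
  (1,250 participants). The restrictive alternative (comparator-role
  participants only) is available via `all_phases = FALSE`.
* **The cap applies to arms under test.** `n_max` drops challengers; the
  current comparator is exempt while it holds the role (it must keep
  recruiting to serve as the concurrent control). Set
  `comparator_nmax_exempt = FALSE` to freeze its recruitment at `n_max`
  instead.
* **Simultaneous crossings.** At one block boundary challengers are
  evaluated in entry order. A promotion ends the sweep: remaining
  challengers are re-evaluated at their next look against the *new*
  comparator, not retroactively. (In scripted replays, forced
  simultaneous events stay simultaneous.)
* **Arm entry triggers.** Queued arms (`entry = "on_drop"`) enter one per
  arm-leaving event — a failure drop, a cap drop, or the retirement of a
  replaced comparator — in schedule order. Counting retirement as an
  arm-leaving event avoids deadlock when the last challenger is promoted
  while arms are still queued. If the trial would otherwise end with
  scheduled arms never released, they are released then rather than
  silently never tested.
* **Replay is deterministic.** `replay_scenario()` forces decisions from
  a script and allocates round-robin; per-arm totals are invariant to
  within-block order, so no RNG is involved in a bookkeeping audit.

## Classical benchmark

`sample_size_two_arm()` computes the smallest per-arm n whose two-sided
pooled-t power reaches the target, by direct noncentral-t iteration — the
Normal approximation is off by one in exactly the regime these designs
care about (it gives 393 rather than 394 per arm at d = 0.2, 80% power,
alpha 0.05). `cumulative_cost()` turns a sequence of fixed-N trials into
a total participant count for comparison with a leapfrog trajectory.

## Problem sizes used in the package's own checks

The bundled tests run the calibrated default design (150/450, 1/5, 3,
rscale 0.5, step 1) at 10,000 replications for first-look probabilities
and 20,000–200,000 replications for cumulative cells (the mid-trajectory
power cell sits close to its comparison band, so it is estimated with
enough replications that Monte-Carlo noise is negligible against the
band); engine-level distributional checks use scaled-down designs
(n_min 20–25, n_max 50–75) at 250–500 simulated trials. These sizes are
the package's choice of a good precision/runtime trade-off; all of them
rerun from scratch at every test invocation.

## Known limitations

* Outcomes are single, immediate and complete; no missing-data or
  longitudinal modelling (rate-of-change or intermediate-endpoint BFs are
  out of scope).
* Only the two-sample JZS t-test BF family is provided — no informed or
  shifted priors, paired designs, non-inferiority regions, or
  model-based approximate BFs.
* Effect estimates from boundary-stopped comparisons are biased (an
  inherent feature of sequential stopping); the package reports crossing
  probabilities and stopping sizes, and point estimates from stopped
  trials should be interpreted with that caution.
* Allocation ratios other than 1:1 are supported in the pairwise
  machinery but the multi-arm engine always block-randomizes equally
  across recruiting arms.
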