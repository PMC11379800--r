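# leapfrog

Design analysis and simulation for **leapfrog adaptive platform trials** —
a simplified adaptive platform design in which challenger treatment arms are
compared to a contemporaneous comparator arm by *directional sequential
Bayes factors*, get dropped when the evidence favors non-superiority, and
"leap over" the comparator to become the new benchmark when the evidence
favors superiority.

The package is aimed at trialists and methodologists planning continuous
treatment-development programmes (for example, iterating on personalized
psychological therapies inside a routine-care service) who need to:

* calibrate the analysis parameters of such a design — the per-arm sample
  sizes at which sequential looks begin (`N_min`) and end (`N_max`) and the
  Bayes-factor boundaries (`BF_fail`, `BF_success`) — to a target power and
  pairwise false-positive rate,
* simulate whole multi-arm trials, with arm dropping, promotion,
  mid-trial arm entry and full event logging, and
* compare the resulting expected sample sizes against the classical
  fixed-N route.

## The statistic at the core

For a challenger with outcomes $y_1$ and comparator outcomes $y_2$
(Normal, common SD), evidence is summarized by the pooled two-sample
$t$ statistic and converted to a directional Jeffreys–Zellner–Siow Bayes
factor. With $\delta$ the standardized mean difference, effective sample
size $n_\mathrm{eff} = n_1 n_2 / (n_1 + n_2)$ and $\nu = n_1 + n_2 - 2$
degrees of freedom,

$$
\mathrm{BF}_{+0}(t) \;=\;
\frac{\int_0^\infty f_{\nu,\;\delta\sqrt{n_\mathrm{eff}}}(t)\,
      \pi(\delta)\, d\delta}{f_{\nu,\,0}(t)},
\qquad
\pi(\delta) = \text{Cauchy}(0, r)\ \text{truncated to } \delta > 0,
$$

where $f_{\nu,\mu}$ is the noncentral-$t$ density. The trial's decision
rules are absorbing boundaries on this quantity: a challenger is dropped
when $\mathrm{BF} \le \mathrm{BF_{fail}}$, promoted to comparator when
$\mathrm{BF} \ge \mathrm{BF_{success}}$, and dropped undecided at `N_max`.
Because the directional BF is strictly increasing in $t$ at fixed sample
sizes, each boundary maps to an exact threshold on the $t$ scale — which is
what makes large Monte-Carlo operating-characteristic runs cheap.

## Worked example

The default `trial_design()` is calibrated for detecting a standardized
effect of d = 0.2 with roughly 80% pairwise power and a false-positive rate
below ~5%:

```r
library(leapfrog)

design <- trial_design()       # N_min 150, N_max 450, BF 1/5 and 3, rscale 0.5
oc <- estimate_oc(design, effect_grid = c(0, 0.2, 0.5),
                  checkpoints = c(150, 200, 450), n_reps = 2000, seed = 1)
oc
#>     d fail@150 fail@200 fail@450 success@150 success@200 success@450
#> 1 0.0     56.1     73.6     89.7         1.5         2.9         5.1
#> 2 0.2      6.4     12.1     14.3        34.2        53.3        80.4
#> 3 0.5      0.0      0.0      0.0        98.8       100.0       100.0
```

Read: if the challenger is truly no better (d = 0), over half of
comparisons already hit the failure boundary at the first look (150/arm)
and only ~5% ever falsely reach the success boundary; at the target effect
(d = 0.2) about half the comparisons succeed by 200/arm and ~80% by
450/arm; a large effect (d = 0.5) is promoted almost surely at first look.

A single sequential comparison, and a whole multi-arm trial:

```r
simulate_pairwise_trace(design, outcome_model(0.2), seed = 8)
#> Sequential pairwise trace (d = 0.2): stopped 'success' at n = 226 per arm after 77 look(s)
#>   final BF = 3.369 at n = 226

sc <- leapfrog_demo_scenario()   # five challengers tested against evolving comparators
replay_scenario(sc$script, sc$design, sc$schedule)
#> Leapfrog trial history: 1250 participants, 6 arms, final comparator 'arm4'
#>   arm_id true_effect entry_index       status   n
#> 1      C         0.0           1      retired 200
#> 2   arm1         0.0           1 dropped_fail 150
#> 3   arm2         0.0           1 dropped_fail 200
#> 4   arm3         0.2           1      retired 350
#> 5   arm4         0.4         601     promoted 200
#> 6   arm5         0.2         801 dropped_fail 150
```

Testing five challenger methods used 1,250 participants. The classical
route needs far more:

```r
sample_size_two_arm(0.2)          # 394 per arm at 80% power, alpha 0.05
cumulative_cost(2, 394)           # 788   - one two-arm fixed-N trial
cumulative_cost(c(4, 3), 394)     # 2758  - a 4-arm then a 3-arm trial
cumulative_cost(rep(2, 5), 394)   # 3940  - five successive two-arm trials
```

`run_trial()` simulates the same multi-arm machinery with random outcomes,
`search_parameters()` screens candidate designs for target operating
characteristics, and `sequential_bf()` applies a design's analysis to raw
accumulating trial data read with `read_outcomes_csv()`.

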