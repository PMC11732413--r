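# trapsocial

Quantifying animal social behaviour from simultaneous trap catches.

Studying social behaviour in the wild usually means watching, filming or
tagging animals — all hard or impossible in turbid ponds, dense vegetation,
or for species that do not habituate to observers. An alternative uses
ordinary ecological sampling gear: deploy several identical passive traps
(e.g. minnow traps for small fish) at fixed locations simultaneously, and
read social structure out of how the catch distributes across them.
`trapsocial` implements the full analysis chain for this design, with
three-spined sticklebacks in freshwater ponds as the motivating system:

* **Aggregation** — the per-session index of dispersion of trap counts,
  `D = s²/n̄`: 0 for perfectly even spread, ≈1 for random (Poisson-like)
  scatter, >1 for aggregation; with a minimum-catch inclusion rule
  (default 26 fish) and the score-vs-catch diagnostic used to choose it.
* **Body-size assortment** — per-trap coefficient of variation of body
  lengths, the session median ("siteCOV"), and a constrained-randomization
  null (10,000 redistributions preserving per-trap counts). Sessions whose
  observed siteCOV falls below the 0.025 quantile of the null are positively
  assorted (fish group with similar sizes); above 0.975, negatively.
* **Environment** — two-step (trap, then session) averaging of logger and
  spot measurements; Spearman collinearity screen; per-site Friedman test
  for trap-location preference.
* **Model comparison** — sets of single-fixed-effect negative-binomial and
  binomial GLMMs (glmmTMB backend) ranked by AICc
  (`−2ℓ + 2k + 2k(k+1)/(n−k−1)`), reporting slope, SE and incidence rate
  ratio `IRR = exp(slope)`; plus a per-week exact 2-means adult/juvenile
  length split.
* **Synthetic data** — a Dirichlet-multinomial trap-catch generator with
  known ground truth (aggregation level, size assortment, demography,
  copula-correlated environmental covariates, covariate effects on catch)
  for power analysis and end-to-end validation.

## Worked example

```r
library(trapsocial)

# a study-scale synthetic dataset: 4 ponds x 13 weeks x 5 traps
dat <- generate_dataset(paper_scale_preset(seed = 7))
sessions <- read_catch_table(dat$catches, dat$lengths)

agg <- score_sessions(sessions, min_catch = 26)
agg[1:3, ]
#> Aggregation scores for 3 sessions (min catch 26): 2 included, 1 excluded
#>   site_id week time_of_day session_total    score included threshold_used
#> 1  pond_A    1          am            97 7.489691     TRUE             26
#> 2  pond_A    2          pm            61 2.352459     TRUE             26
#> 3  pond_A    3          am             5 1.500000    FALSE             26
```

Scores well above 1 indicate aggregated catches (1 would be random scatter;
0, perfectly even); the 5-fish session is excluded by the 26-fish rule
because the score is mechanically constrained at small totals.

```r
test_assortment(sessions[[2]], n_iter = 10000, seed = 42)
#> Constrained-randomization test for body-size assortment
#>   session: site pond_A, week 2
#>   observed siteCOV = 0.2597, null median = 0.2559 (10000 iterations)
#>   quantile = 0.5841 -> no evidence of assortment
```

The observed within-trap size variation sits at the 0.58 quantile of the
null — nowhere near the 0.025 cutoff, so no size assortment in this session.

```r
env <- summarize_env(read_env_tables(dat$env_loggers, dat$env_spot))
frames <- model_frames(sessions, env, agg)
fit_model_set(frames$session, "aggregation_score")
#> AICc-ranked single-covariate model set (response: aggregation_score)
#>    fixed_effect  slope    se   irr delta_aicc df strong conv
#>   temperature_c -0.083 0.026 0.920        0.0  4      *
#>    light_lumft2 -0.001 0.000 0.999        4.2  4      *
#>            week  0.067 0.031 1.069        4.4  4      *
#>  prop_red_males -1.716 0.791 0.180        4.7  4
#>          do_mgl -0.117 0.063 0.889        5.5  4
#>            none     NA    NA    NA        6.5  3
#>     time_of_day -0.126 0.228 0.882        8.6  4
#>   turbidity_ntu  0.005 0.015 1.005        8.8  4
```

Each row is one GLMM with a single fixed effect; `delta_aicc` is the AICc
distance to the best model and `df` the number of estimated parameters. The
generator's true structure includes a negative red-male effect on aggregation,
recovered with the right sign (slope −1.72, IRR 0.18 — each unit increase in
red-male proportion multiplies the expected score by 0.18), though at this
single-seed sample size a correlated covariate happens to rank above it.

The whole chain, from a YAML/`list` config to per-stage CSVs and a run
manifest:

```r
run_pipeline(list(simulate = list(preset = "paper", seed = 7),
                  n_iter = 10000, outdir = "run1"))
```

A thin command-line wrapper with subcommands (`simulate`, `aggregate`,
`assort`, `envstats`, `modelsel`, `run`) lives in `inst/scripts/trapsocial.R`.

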