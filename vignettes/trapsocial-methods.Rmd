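---
title: "Quantifying social behaviour from simultaneous trap catches: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying social behaviour from simultaneous trap catches: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapsocial)
```

## The method

Direct observation, filming and tagging are often unworkable for social
behaviour in the field, especially in turbid or vegetated fresh water. An
alternative is to deploy several identical passive traps simultaneously at
fixed locations in a site and compare the counts of individuals caught. If
individuals move independently, counts scatter like Poisson draws; if they
move in groups (or join trapped conspecifics), counts pile up in few traps.
The distribution of one sampling session's counts therefore carries a signal
about social tendency, and phenotypes recorded from the catch (body length,
breeding colouration) let one ask whether groups are non-randomly composed.

`trapsocial` implements this analysis chain for the canonical design — `K`
funnel traps per session, one session per site per sampling week — together
with a synthetic data generator so every stage can be validated against known
ground truth.

## Aggregation: the index of dispersion

For one session with per-trap counts $n_1, \dots, n_K$, the aggregation score
is the index of dispersion

$$ D = \frac{s^2}{\bar n}, \qquad
   s^2 = \frac{1}{K-1}\sum_j (n_j - \bar n)^2 . $$

$D = 0$ when all traps hold the same number of fish (perfectly even spread,
suggesting avoidance), $D \approx 1$ under independent random (Poisson-like)
scatter, and $D > 1$ indicates aggregation. We use the sample ($K-1$)
variance, the convention in ecology and what standard software returns; the
population-variance alternative is exposed via the `denominator` argument of
`index_of_dispersion()`.

Two numerical caveats are built into the contract:

* **All-zero sessions.** $D = 0/0$ is undefined; such sessions are excluded
  with a warning rather than scored.
* **The minimum-catch rule.** With few fish the score is mechanically
  constrained (variance and mean are both limited by the total), so
  `score_sessions()` flags sessions below a catch threshold — default 26 —
  as excluded. The threshold is a visual choice, made from the
  score-versus-total-catch diagnostic (`score_vs_catch_diagnostic()`,
  `plot()` on the scores); no automatic changepoint detection is attempted.

A useful calibration fact, relevant to interpreting the score on small trap
arrays: if per-trap counts are independent negative binomial with mean $m$
and size $k$, the *pooled* variance-to-mean ratio is $1 + m/k$, but the
*mean per-session score* at finite $K$ sits below that value because
$\mathrm{E}[s^2/\bar n] \ne \mathrm{E}[s^2]/\mathrm{E}[\bar n]$. A
second-order expansion gives

$$ \mathrm{E}\!\left[\frac{s^2}{\bar n}\right] \approx
   \frac{\sigma^2}{\mu}\left(1 + \frac{\sigma^2/K}{\mu^2}
   - \frac{\mu_3/K}{\sigma^2 \mu}\right), $$

which for $K = 5$, $m = 20$, $k = 2$ evaluates to about $0.9 \times 11
\approx 9.9$ — a downward ratio bias of order $1/K$ that does not vanish
with more sessions, only with more traps per session. The test suite checks
both facts: the per-session mean score at $K = 5$ and the pooled ratio.

## Body-size assortment: siteCOV and its randomization null

Within one trap, size heterogeneity is summarized by the coefficient of
variation of body lengths, $\mathrm{COV} = \hat\sigma / \bar x$ (sample
standard deviation over mean). Traps with fewer than two measured fish carry
no information and are skipped. The session statistic — the *observed
siteCOV* — is the median of the per-trap COVs over eligible traps, with the
even-count median defined as the midpoint of the central pair.

The null hypothesis is random assortment: fish distribute across traps
without regard to size. It is simulated by a constrained randomization that
permutes the pooled measured lengths of the session uniformly at random and
re-splits them by the observed per-trap measured counts, preserving the
catch-size marginals exactly. Each iteration records its median per-trap
COV (*expected siteCOV*); 10,000 iterations form the null distribution. The
session's quantile is the proportion of expected values less than or equal
to the observed value, and in a two-tailed test quantiles below 0.025
indicate positive assortment (groups of similar sizes — less within-trap
variation than chance) and quantiles above 0.975 negative assortment.

Design choices worth stating:

* **Eligibility inside the null.** Because the randomization preserves
  per-trap measured counts, a trap's eligibility (at least two measured
  fish) is identical in every iteration and in the observed data — the two
  conceivable conventions (fix the eligible set from the data, or recompute
  it per iteration) provably coincide, so no option is exposed.
* **Suitability.** A session needs at least two eligible traps; otherwise
  the null is degenerate (all fish in one trap) or the median rests on a
  single trap, and the session is classed `unsuitable`. Suitability is
  judged from the length distribution alone, independent of the aggregation
  catch threshold; an opt-in `min_catch` argument couples them if desired.
* **Measured fish only.** Fish without length measurements (escapes) take
  no part in the statistic or the null; counts still use all fish.
* **Ties.** The null is a finite discrete distribution, so exact ties with
  the observed value are real support points that the "less than or equal"
  rule must count. `assortment_quantile()` applies a relative tolerance of
  $10^{-9}$ so that arithmetically different but mathematically equal COV
  evaluations compare as ties.
* **Seeding.** Each session draws its own RNG stream, derived from the
  master seed plus a hash of the session identity, so a single session can
  be re-analysed in isolation and reproduce the batch result exactly.

The suite validates the machinery three ways: exhaustive enumeration of all
redistributions on sessions of up to eight fish agrees with the Monte-Carlo
quantile within Monte-Carlo error; with no size structure the positive rate
at the 0.025 cutoff matches its nominal level over 500 simulated sessions;
and with between-trap spread three times the within-trap spread and ten or
more fish per trap, essentially every session is classified positive.

## Environmental summaries and screens

Loggers record temperature and light every minute over the two-hour session
at each trap; turbidity and dissolved oxygen are spot measurements at the
start and end. Summaries follow a strict two-step rule: per-trap means first
(series mean for logged variables, start/end mean for spot pairs, one phase
alone — flagged — if the other is missing), then the session mean as the
mean of the five trap means. The two-step average, not the pooled-series
mean, is what session-level models consume, so each trap contributes equally
regardless of series length.

Collinearity among candidate covariates (temperature, light, dissolved
oxygen, turbidity, week) is screened with pairwise Spearman rank
correlations, two-sided with the asymptotic-$t$ approximation. Trap-location
preference is tested per site with a Friedman test — weeks as blocks, trap
locations as treatments, mid-ranks with the standard tie correction (the
base-R implementation provides exactly this). One edge case is defined
explicitly: when every block is completely tied the tie-corrected statistic
is 0/0, which we report as statistic 0 and $p = 1$ (no rank variation, no
evidence of preference). No multiple-testing correction is applied anywhere;
interpretation is left to the user.

## Single-covariate model comparison

Three responses are modelled, each by a set of GLMMs that differ only in a
single fixed effect, plus a null model, ranked by the small-sample Akaike
criterion

$$ \mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1}. $$

| response | family / link | random structure | candidates |
|---|---|---|---|
| catch per trap | negative binomial, log | trap in site | temp, light, DO, turbidity, week, am/pm |
| proportion of adults | binomial (adults vs juveniles) | trap in site | the five above, each plus week; week alone; intercept only |
| aggregation score | negative binomial, log | site | the six above plus red-male proportion |

`k` counts every estimated parameter — fixed effects, intercept, the NB
dispersion, and each random-effect variance — so a one-covariate NB model
with a site intercept has $k = 4$ and its null $k = 3$. A model more than
two AICc units below its null is flagged as strongly supported; in the
adult-proportion set the week-only model is the reference, since week is
carried in every candidate (it defines the age classes). Slopes are reported
per raw covariate unit (optional z-standardization is off by default), with
the incidence rate ratio $\mathrm{IRR} = e^{\beta}$ and, for headline
effects, the percent-change restatement $100(1 - e^{\beta})$ for decreases.

Numerical policy for mixed fits (backed by `glmmTMB`, fitted by maximum
likelihood): a model leaves the ranking only on genuine optimizer failure.
Variance components on the zero boundary routinely produce a singular
Hessian (standard errors unavailable) or an optimizer "false convergence"
code with a near-zero gradient; both still yield a valid maximized
likelihood, which is taken from the optimizer objective, and such fits stay
ranked. Model adequacy is checked with the Pearson dispersion statistic
(sum of squared Pearson residuals over residual degrees of freedom) rather
than simulated-residual machinery.

The aggregation score is a continuous index, yet the field convention this
package follows models it with a negative binomial on the score rounded to
the nearest integer; a gamma-log alternative is exposed through `family`
for strictly positive scores, and the IRR back-transform is unaffected by
that choice since both use a log link.

The adult/juvenile split behind the proportion response is a per-week exact
1-D 2-means (exhaustive scan over sorted lengths), because juveniles recruit
and grow over the season so no single cutoff works for all weeks. Weeks with
no clear divide — the between-cluster gap not exceeding the pooled
within-cluster standard deviation — are flagged and fall back to the global
split; a fixed user cutoff is also supported.

## The synthetic generator

The generator emulates the study design at the level the statistics can see,
deliberately avoiding any movement or behaviour simulation:

* **Design**: sites × weeks × `K` traps; alternating am/pm sessions. The
  study-scale preset is 4 sites × 13 weeks × 5 traps.
* **Totals**: session totals are negative binomial; the preset uses a
  per-trap mean of 18 with size 1.2, matching per-trap means near 15–22 and
  strongly overdispersed per-site totals.
* **Aggregation**: the total is allocated to traps by a symmetric
  Dirichlet-multinomial whose concentration sets the aggregation level
  (preset 0.5, giving scores in the tens), or alternatively by independent
  NB counts per trap. The session red-male proportion — a waning logistic
  function of week — can modulate the log concentration (preset slope +3:
  more territorial breeding males, less aggregation), reproducing the sign
  structure of the field finding.
* **Demography and lengths**: each fish is juvenile with a week-increasing
  logistic probability; juvenile mean length grows linearly (12 mm plus
  1.8 mm per week) below a constant adult mode at 50 mm, giving the bimodal,
  diverging length structure a per-week split can recover. Assortment is
  induced by a per-trap shift in mean length (`between_trap_sd_mm`, preset
  0 — the field study found none); red males are drawn binomially from
  adults only.
* **Environment**: session means follow seasonal linear trends plus a
  one-factor Gaussian copula keyed to temperature, with loadings
  $2\sin(\pi\rho_s/6)$ so Spearman targets are hit on the rank scale
  (preset temperature–light 0.5); site offsets share the factor structure
  so between-site variation does not dilute the correlations. Trap-level
  values jitter around session means; one-minute logger series are AR(1)
  (autocorrelation 0.9) around trap means, and spot measurements add small
  noise. Correlation targets outside $[-1, 1]$ are rejected before any
  generation.
* **Covariate effects on catch**: optional log-scale slopes per covariate,
  applied to per-trap expected counts around the covariate's configured
  mean, recorded in the ground truth for recovery tests.

Everything is reproducible byte-for-byte from the seed, and the ground truth
(per-session concentration and red-male proportion, per-fish age class, true
trap-level covariate means, true slopes) is returned alongside the tables.

What the generator does *not* emulate — and hence what passing tests cannot
show about real data: trap-avoidance learning across weeks, phenotype-biased
capture, spatial structure among trap locations (the Friedman screen is
null under the generator by construction), diurnal environmental cycles
within a session, and any behavioural mechanism behind aggregation (attraction
to trapped conspecifics versus group entry are indistinguishable here).

### Conditions used in the validation studies

The packaged checks run at these problem sizes, chosen to estimate each
quantity with useful precision: score calibration uses $10^4$
five-trap Poisson sessions and 2000 NB sessions; the type-I study uses 500
sessions (25 sites × 20 weeks) at 2000 randomization iterations; the power
study uses ~25 sessions passing the ten-fish-per-trap condition; model
recovery uses the 260-trap-record preset with a temperature slope of 0.3 and
100 no-effect replicates. The model-calibration studies use the
`nb_per_trap` allocation: independent per-trap counts are what the NB GLMM
assumes, whereas the Dirichlet-multinomial preset couples counts within a
session — that coupling *is* the aggregation signal, and under it a
session-level covariate can absorb shared session variation, which is a
property of the design rather than of the model-selection code.

## Known limitations

* The NB-on-rounded-score model for aggregation discards sub-integer
  information; the gamma alternative requires strictly positive scores.
* With only four sites, site random-intercept variances are weakly
  identified and often estimated on the zero boundary; the ranking handles
  this, but per-model standard errors can be unavailable there.
* The assortment test conditions on measured fish; systematic measurement
  loss correlated with size would bias it in ways the generator's uniform
  thinning does not represent.
* The minimum-catch threshold is a visual convention, not an estimator.

## Reproducing a full run

```{r, eval = FALSE}
res <- run_pipeline(list(
  simulate = list(preset = "paper", seed = 7),
  n_iter = 10000, min_catch = 26, seed = 7,
  outdir = "run1"))
res$model_sets$aggregation_score
```
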