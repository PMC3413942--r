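---
title: "Models and methods behind rrdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rrdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrdesign)
```

## The estimand: individual response and its variance

A subject's individual treatment response is the causal contrast
$D = T - C$: the change in the outcome under treatment minus the change the
*same* subject would have shown under control over the same period. Its
population mean $\mu_D$ is the average treatment effect; its variance
$\sigma^2_D$ across subjects is the treatment response heterogeneity (TRH).
The two are logically independent: $\mu_D \neq 0$ with $\sigma^2_D = 0$
means everyone responds identically, while $\mu_D = 0$ with
$\sigma^2_D > 0$ means strong individual effects that cancel on average.
Neither variability among treated subjects' changes nor the ranking of
observed changes says anything about TRH by itself, which is why observed
"non-responders" in a parallel-groups trial may respond perfectly well.

## Generative model

`rrdesign` gives these estimands operational meaning through the minimal
linear mixed model in which TRH is a single identified variance component:

$$Y_{ij}(x) = \mu + \pi_j + a_i + (\tau + b_i)\,x + \gamma\,x_{i,j-1} + e_{ij},$$

with $a_i \sim N(0, \sigma^2_a)$ subject intercepts,
$b_i \sim N(0, \sigma^2_D)$ subject-treatment interactions,
$e_{ij} \sim N(0, \sigma^2_e)$ residuals, fixed period effects $\pi_j$
(first period is the reference, $\pi_1 = 0$) and first-order carryover
$\gamma$ applied when the previous period was treated. The outcome is a
per-period weight change in kg; negative values are weight lost, so
$D_i = \tau + b_i < 0$ means treatment is superior for weight loss.

Three modeling choices deserve explanation:

* **One residual per cell.** The residual $e_{ij}$ is indexed by subject
  and period only and is shared by the two counterfactuals of a cell, so
  the per-period causal difference is exactly $D_i$. The correlation
  between the two counterfactual outcomes of one cell is not estimable from
  any realized trial (only one of the two is ever seen), so we fix it at
  the simplest identified structure. Consequences: `observe()` is a pure
  selection from the counterfactual tables when $\gamma = 0$, and the
  sample variance of the true $D_i$ converges to $\sigma^2_D$ — both are
  tested properties.
* **Carryover sits outside $D_i$.** The counterfactual tables exclude the
  $\gamma$ term; `observe()` adds it from the *realized* sequence, because
  what carries over depends on what was actually experienced. This keeps
  TRH a pure subject-treatment interaction variance. $\gamma$ defaults to
  0: the design is intended for interventions with minimal carryover.
* **Independent $a_i$ and $b_i$.** An intercept-slope correlation is
  weakly identified at small $p$ and defaults to absent.

$D$ is modeled as a per-period quantity; whole-trial totals scale by $p$.

## Allocation schedules and the single-arm probability

`build_schedule()` produces parallel-groups (one baseline randomization),
two-period crossover (TC/CT), Balaam (TT/TC/CT/CC) and RRD schedules.
"Balanced" assignment for the first three fills equal sequence blocks and
assigns the remainder at random — no algorithm is canonical here, and the
choice only affects remainder subjects. The unconstrained RRD flips an
independent fair coin per cell, making the probability of an all-one-arm
sequence $(1/2)^{p-1}$ (both single-arm sequences together); Balaam is
exactly the $p = 2$ special case. The constrained scheme instead permutes a
balanced vector of $p/2$ ones per subject, guaranteeing equal allocation —
e.g. treatment in exactly 12 of 24 months — at the cost that, if blinding
fails, late assignments become predictable; the builder surfaces this as a
message (class `rrd_predictability_note`) rather than preventing it.
Periods are abstract indices; washout and period length are protocol
concerns outside the schedule.

## Estimators and the identifiability ladder

`individual_effects()` computes $\hat d_i$ as the difference of a subject's
within-condition means, optionally after subtracting per-period
cross-subject means (`period_adjust`, default on: randomization balances
$\pi_j$ only in expectation). Its standard error uses the subject's own
within-condition variances when replication exists.

`trh_moment()` corrects the between-subject variance of $\hat d_i$ for
sampling noise. Since
$\mathrm{Var}(\hat d_i \mid D_i) = \sigma^2_e (1/p_{T,i} + 1/p_{C,i})$,

$$\hat\sigma^2_D = \mathrm{Var}_i(\hat d_i) - \hat\sigma^2_e \cdot
  \mathrm{mean}_i\!\left(\tfrac{1}{p_{T,i}} + \tfrac{1}{p_{C,i}}\right),$$

truncated at zero (the raw value is kept for bias checks; truncation makes
the reported estimate valid as a variance but positively biased near zero).
$\hat\sigma^2_e$ is the within-subject, within-condition sample variance
pooled by degrees of freedom — *restricted to subjects observed under both
conditions*. The restriction is a deliberate design choice: the Balaam
design's TT/CC subjects do see one condition twice, but using their
replication to de-noise the *other* subjects' effects would lean on
cross-period homogeneity assumptions that repeated designs are meant to
avoid, and the correction exists precisely to serve the subjects
contributing $\hat d_i$. Under this contract the estimators reproduce the
identifiability ladder as hard errors:

1. parallel groups — no subject sees both arms, so `individual_effects()`
   fails (`rrd_identifiability_error`);
2. two-period crossover and Balaam — dual-condition subjects have
   $p_T = p_C = 1$, so `pooled_residual_variance()` fails and TRH cannot be
   separated from noise;
3. RRD with $p \ge 4$ — everything is estimable, and the moment estimator
   is unbiased for $\sigma^2_D$ before truncation (tested by Monte Carlo).

`trh_mixed()` fits the same model by REML with `lme4`:
`outcome ~ treated + period + (1 | subject) + (0 + treated | subject)`,
diagonal random-effect covariance. On balanced data without period effects
its fixed effect equals the grand mean of the $\hat d_i$ exactly (the
treatment contrast is orthogonal to the subject intercepts), which the
suite asserts at $10^{-6}$. Singular fits (zero variance estimates) are
legitimate answers for degenerate inputs and are not treated as failures;
genuine optimizer errors are re-thrown as `rrd_fit_error`.

`responder_proportions()` assumes $D \sim N(\hat\mu_D, \hat\sigma^2_D)$ and
reports $P(|D| \le \delta)$, $P(D < 0)$, $P(D > 0)$, with point-mass
indicators when $\hat\sigma_D = 0$. The non-response band half-width
$\delta$ (kg) has *no default*: "true non-responder" is only meaningful
relative to an explicit equivalence margin, so the analyst must supply one.
An empirical plug-in variant (`responder_proportions_empirical()`) uses the
ECDF of the $\hat d_i$ instead; it is provided for normality-skeptics but
is noise-inflated — sampling error in each $\hat d_i$ leaks band mass into
the tails. Missing outcomes are handled by complete-period analysis
throughout (dropped, with skip counts retained).

## Design efficiency

`run_efficiency()` compares designs at an **equal observation budget**
(same $N$ and $p$, hence $N \times p$ measurements) — the convention every
report states, since "relative efficiency" is otherwise underdetermined.
Common random numbers are used across designs within a replicate (one set
of potential outcomes, per-design schedules), which substantially shrinks
the Monte-Carlo error of variance ratios; ratio standard errors come from a
leave-one-replicate-out jackknife. An optional balanced binary covariate
(assigned by subject-index parity, so exactly 50/50) shifts treated
outcomes by `covariate_effect`; the interaction is then estimated per
replicate by a random-intercept mixed model
`outcome ~ treated * covariate + (1 | subject)` — the intercept-only random
structure is used because the slope variance is weakly identified at the
default $p = 4$ and the interaction coefficient is the estimand.

Closed forms used as pre-built test oracles (no carryover, no period
effects, balanced allocation):

* constrained RRD, $p_T = p_C = p/2$:
  $\hat d_i = D_i + \bar e_{i,T} - \bar e_{i,C}$, so
  $\mathrm{Var}(\hat\tau) = (\sigma^2_D + 4\sigma^2_e/p)/N$;
* parallel groups, $N/2$ per arm, per-subject means over $p$ periods have
  variance $\sigma^2_a + \sigma^2_D x + \sigma^2_e/p$, so
  $\mathrm{Var}(\hat\tau) = (4\sigma^2_a + 2\sigma^2_D + 4\sigma^2_e/p)/N$.

With $\sigma^2_a = \sigma^2_D = 0$ both reduce to $4\sigma^2_e/(Np)$ — the
designs tie. Subject intercept variance inflates only the parallel-groups
variance (within-subject contrasts eliminate $a_i$), so the RRD's relative
efficiency exceeds 1 exactly when $\sigma^2_a > 0$; at
$\sigma^2_a = 4, \sigma^2_e = 1, p = 4$ the predicted ratio is 17, which
the Monte-Carlo suite reproduces. Relative efficiency is scale-invariant,
tested by doubling every outcome through the parameterization.

## Survey analysis

The five-item preference instrument is analyzed as: per-item mean with
normal-approximation CI, median and range; the design-preference proportion
with a **plain Wald interval** in percent (chosen because it reproduces the
printed 63.6% (54.9, 72.2) from 75 of 118 exactly — verified, not assumed);
and paired Wilcoxon signed-rank tests for enrollment (items 2 vs 3) and
completion (4 vs 5) likelihood. Items 4 and 5 arrive reverse-scored
(acquiescence control) and are flipped with `reverse_score()` (an
involution, $r \mapsto 6 - r$) before any statistic.

The signed-rank statistic is the *centered* convention
$S = \sum_{d_i > 0} r_i - m(m+1)/4$: zero-mean under the null and
sign-equivariant under pair swapping, so negative values indicate the first
item tended larger. Zero differences are dropped; tied absolute differences
get mid-ranks. For $m \le 15$ nonzero pairs the p value is exact by full
enumeration of all $2^m$ sign assignments on the observed (possibly tied)
ranks — the brute-force enumeration also exists independently in the test
helpers and the two must agree on every random input. Above 15 a normal
approximation with tie-corrected variance $\sum r_i^2/4$ and no continuity
correction is used; 15 keeps the exact path under a second while covering
any plausible questionnaire comparison.

`generate_synthetic_survey()` stands in for undeposited questionnaire data:
a latent equicorrelated Gaussian copula thresholded at the normal quantiles
of each item's requested marginal. Defaults emulate the pilot cohort —
$n = 118$, B-preference 0.636, item means 3.9/4.1/3.9/4.0 with median 4 —
and latent correlation $\rho = 0.5$, a realistic within-respondent value
for same-instrument Likert items (the pilot reports no correlation, so this
is a one-time modeling choice, not a fit). What the generator does *not*
emulate: acquiescence and other response styles beyond what reverse scoring
absorbs, demographic structure, and item-specific correlation patterns —
so passing tests certify the analysis pipeline, not psychometrics.

## Numerical and reproducibility choices

Every stochastic function takes an explicit integer seed and sets the RNG
once at entry; subject loops are in fixed order, so results are
reproducible bit-for-bit. Monte-Carlo suites derive replicate seeds from
the master seed. Problem sizes in the shipped tests — 200 replicates at
$N = 200, p = 8$ for TRH recovery, 300–400 replicates at $N = 40, p = 4$
for efficiency, $10^5$ subjects for allocation frequencies — were chosen so
each targeted tolerance sits at least three Monte-Carlo standard errors
from its pass boundary.

## Limitations

Linear, time-constant treatment effects only: no dose-response, no
time-varying TRH, no dropout (retention effects of repeated randomization
are an empirical question the simulator cannot answer). Missing data are
dropped rather than imputed. Responder proportions inherit the normality of
$D$. The moment estimator's truncation biases it upward when the true TRH
is near zero; compare with `sigma2_trh_raw` when averaging across
replicates. The efficiency module reports Monte-Carlo ratios, not analytic
relative-efficiency formulas — the closed forms above cover only the
balanced, no-carryover special cases where they serve as oracles.
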