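# rrdesign

Tools for studying **treatment response heterogeneity (TRH)** with the
**repeated-randomizations design (RRD)** — a crossover-style trial in which
every subject is re-randomized to treatment or control at each of *p*
periods.

## The problem

A subject's individual treatment response is the causal difference
*D = T − C*: the change they show under treatment minus the change the
*same* subject would have shown under control over the same period. A
parallel-groups trial observes each subject under one arm only, so *D* has
no sample analogue there, and labeling an observed change a "response" is a
category error — a subject with 0 kg observed change on treatment has still
lost 0.5 kg *because of* treatment if they would have gained 0.5 kg on
control. Population summaries hide this entirely: both arms can average the
same change (zero mean effect) while individual effects vary widely.

TRH is the variance of *D* across subjects, written σ²_D, with population
mean μ_D. `rrdesign` gives these estimands operational meaning through a
potential-outcomes generative model

    Y_ij(x) = μ + π_j + a_i + (τ + b_i)·x + γ·x_{i,j−1} + e_ij

with subject intercepts a_i ~ N(0, σ²_a), subject-treatment interactions
b_i ~ N(0, σ²_D), fixed period effects π_j, first-order carryover γ and
residual noise e_ij ~ N(0, σ²_e). The individual response is D_i = τ + b_i,
so σ²_D *is* the TRH. The package simulates both counterfactual tables,
realizes trials under four allocation schemes (parallel groups, two-period
crossover, Balaam, RRD — constrained or not), and estimates:

* individual mean effects d̂_i = mean(treated outcomes) − mean(control
  outcomes), available only when a subject sees both arms;
* total TRH, by a noise-corrected method of moments
  (σ̂²_D = Var_i(d̂_i) − σ̂²_e · mean(1/p_T + 1/p_C), truncated at 0) and by a
  REML random-slope mixed model (via `lme4`);
* the population mean effect and normal-model responder proportions
  P(|D| ≤ δ), P(D < 0), P(D > 0);
* Monte-Carlo relative efficiency of designs at an equal observation budget;
* ordinal preference-survey statistics: reverse scoring, paired Wilcoxon
  signed-rank tests (exact by enumeration for ≤ 15 nonzero pairs), Wald
  proportion intervals, and a Gaussian-copula synthetic survey generator.

## Worked example

```r
library(rrdesign)

params <- trial_params(mu = -1, tau = -0.5, sigma2_subject = 1,
                       sigma2_trh = 0.6, sigma2_resid = 0.8)
po    <- simulate_potential_outcomes(params, n_subjects = 120,
                                     n_periods = 8, seed = 42)
sch   <- build_schedule("rrd", 120, 8, scheme = "constrained", seed = 43)
trial <- observe(po, sch)

(est <- trh_moment(trial))
#> <rrd_trh: moment estimator, 120 subjects>
#>   mu_D hat:         -0.6117 kg
#>   TRH (sigma2_D):    0.2787 kg^2
#>   residual var:      0.8424 kg^2

responder_proportions(est, delta = 0.25)
#> # A tibble: 1 x 6
#>   delta prop_nonresponder prop_treat_better prop_control_better mu_d_hat
#>   <dbl>             <dbl>             <dbl>               <dbl>    <dbl>
#> 1  0.25             0.195             0.877               0.123   -0.612
```

The moment estimator reads: the average causal effect of treatment is an
extra 0.61 kg lost per period, individual effects vary with estimated
variance 0.28 kg² beyond what residual noise explains, and under a normal
model for *D* about 12% of the population genuinely does better on control
even though treatment wins on average. (This seed draws a cohort whose
realized response variance is 0.48 kg², below the generative 0.6 —
single-trial TRH estimates are noisy; the recovery tests average many
replicates.) `trh_mixed(trial)` fits the equivalent mixed model and agrees
here to the second decimal; `tidy()` / `glance()` return both in broom
form, and `autoplot()` / `plot_individual_effects()` draw the standard
pictures.

A thin command-line wrapper (`inst/cli/rrd`) exposes the same pipeline as
`simulate`, `estimate`, `efficiency` and `survey` subcommands.

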