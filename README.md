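# anchorMI

Information-anchored sensitivity analysis for longitudinal randomized
trials, by controlled multiple imputation.

## The problem

When patients in a longitudinal trial deviate from protocol (withdraw,
take rescue medication, become lost to follow-up), their later outcomes
are missing and the primary analysis must assume something untestable
about them — usually that they are missing at random (MAR). Sensitivity
analyses then re-impute the missing data under alternative assumptions:
**reference-based** rules that borrow the control arm's behaviour (jump
to reference, copy increments in reference, copy reference, last mean
carried forward) or a **δ-adjustment** that shifts MAR imputations by a
fixed or elicited amount. The primary analysis model is refitted to each
of K imputed datasets and results are pooled by Rubin's rules.

A sensitivity analysis should not quietly *add* or *destroy* statistical
information relative to the primary analysis. Writing I(·) for the
inverse variance of the treatment-effect estimator, an analysis is
**information anchored** when

    I(obs, sensitivity) / I(full, sensitivity)
      = I(obs, primary) / I(full, primary),

i.e. the proportion of information lost to missing data is held constant
across the two analyses. The corresponding **anchored variance** is

    V_anchored = (V_obs,primary / V_full,primary) × V_full,sensitivity.

`anchorMI` implements the full stack: monotone-MAR multivariate-normal
fitting and exact conjugate posterior draws, all the controlled
imputation rules above, ANCOVA / difference-in-means analyses, Rubin's
rules with Barnard–Rubin degrees of freedom, the anchoring calculus
(expected full-data variances under a controlled scenario, the anchored
variance, the leading discrepancy term against Rubin's variance, the
δ-method Q term, information-loss percentages, classification as
information negative/anchored/positive, sample size and power), and a
simulation engine that demonstrates empirically that Rubin's-rules
variance is information anchored for these methods.

## Worked example

Simulate an asthma-like trial (FEV1 in litres at baseline, week 4,
week 12; n = 250 per arm; true final-visit treatment effect 0.3), impose
25% monotone dropout in the active arm, and compare the primary MAR
analysis with a jump-to-reference sensitivity analysis:

```r
library(anchorMI)
cfg <- sim_config(dropout = 0.25, K = 50, seed = 2026)
trial    <- generate_complete_trial(cfg, seed = 101)
observed <- impose_mcar_monotone_dropout(trial, 0.25, seed = 102)
summarize_patterns(observed, "active")
#> pattern_summary for arm 'active': n = 250, completers = 188
#>   first missing visit: visit2=31, visit3=31 (total deviation proportion 0.248)

mar <- pool(lapply(impute_all(observed,
         imputation_spec("MAR", "reference", K = 50), seed = 2026),
         fit_ancova))
mar
#> pooled_result (ancova, K = 50)
#>   estimate = 0.2758, se = 0.06815, df = 326.8, p = 6.49e-05
#>   W = 0.003838, B = 0.0007909, V = 0.004645, lambda = 0.174

j2r <- pool(lapply(impute_all(observed,
         imputation_spec("J2R", "reference", K = 50), seed = 2026),
         fit_ancova))
j2r
#> pooled_result (ancova, K = 50)
#>   estimate = 0.217, se = 0.06881, df = 319.1, p = 0.00177
#>   W = 0.003878, B = 0.0008394, V = 0.004734, lambda = 0.181
```

Jumping to reference pulls the estimate from 0.276 toward zero (0.217),
as it assumes deviators lose the treatment benefit. The interesting part
is the variance: computing the anchored benchmark from this replicate's
complete data and a scenario-complete dataset drawn under jump to
reference,

```r
sens_full <- generate_full_sensitivity_data(observed, cfg,
               imputation_spec("J2R", "reference"), seed = 103)
anchored_variance(mar$V, fit_ancova(trial)$variance,
                  fit_ancova(sens_full)$variance)
#> [1] 0.004733
```

Rubin's variance (0.004734) reproduces the anchored variance (0.004733)
to four digits: the sensitivity analysis loses the same share of
information as the primary analysis. By contrast, an elicited-prior
δ-analysis reporting a standard error of 0.132 would lose
`round(info_loss_percent(j2r$se, 0.132))` = 73% of that information.

`run_study()` repeats this comparison over a grid of dropout proportions
and methods; `cmd_impute()` / `cmd_analyze()` / `cmd_anchor()` (and the
dispatcher script in `inst/cli/`) run the same workflow from a
configuration file against a trial CSV with columns `id, arm, y1..yJ`.

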