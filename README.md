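# pswtrial

Propensity-score-weighted (PSW) analysis of randomized controlled trials in
depression whose treatment-effect estimates are confounded by heterogeneous
placebo response.

## The problem and the method

Depression trials enroll a mixture of patients: some respond to nothing
(D−P−), many respond to anything — the placebo-type responders (D+P+) —
and a small informative group responds to active drug only (D+P−). When the
placebo-type share is large, the arm contrast of the conventional analysis
shrinks toward zero and an active drug can fail its trial; when it is
unusually small, chance imbalance can manufacture separation.

The PSW method estimates, for every randomized subject, the probability
*p* of a placebo-type response (a ≥50% improvement in the HAMD-17 or MADRS
total score at end of study under placebo) **from pre-randomization data
only**: the per-item changes between screening and baseline. A feed-forward
neural network is trained on 75% of the placebo arm, qualified on the held
back 25% by a bootstrap ROC (the model is used only when the lower 95%
bound of the validation AUC exceeds 0.5), and applied to all arms. Each
subject then enters the longitudinal analysis with weight

```
w = 1 / max(p, p_floor)
```

in a mixed model for repeated measures (MMRM) fit by REML:

```
change_i ~ visit + baseline:visit + arm:visit,   Cov(y_i) = Sigma[V_i, V_i] / w_i
```

with unstructured `Sigma`. The package reports, per active arm, the
treatment effect TE (LS-mean difference from placebo at end of study), its
standard error, the Tukey-adjusted p-value, the pooled SD
(`sqrt(Sigma[EOS, EOS])`) and the effect size `|TE| / pooled SD`, for the
weighted analysis and the conventional unweighted (reference) analysis side
by side.

Because real item-level trial data of this kind are not public, the package
ships a synthetic-trial simulator with a known latent class mixture and a
recoverable ground truth, plus the design calculations such trials use
(exact noncentral-t sample size; truncated Hochberg multiplicity with
simulated power) and an operating-characteristics harness that measures
type-I error and power of the weighted versus reference analysis over
hundreds of simulated trials. Two methodological safeguards the harness
motivated — out-of-fold (cross-fitted) propensities for the placebo
training subjects and a cluster-robust covariance for the weighted fit —
are defaults; see the methods vignette (`vignettes/psw-methodology.Rmd`)
for the reasoning and the literal conventions they replace.

## Worked example

```r
library(pswtrial)

preset <- design_preset("madrs_3arm", n_per_arm = 100)
trial  <- generate_trial(preset$design, preset$scale, seed = 1)

cfg <- psw_config(scale_name = "MADRS", eos_week = 6, seed = 1)
res <- run_psw_analysis(trial$data, cfg)
print(res)
```

```
<psw_analysis> ok
  validation AUC 0.750 [0.510, 0.948] -> pass
  reference comparisons:
            comparison   te std_err  df p_unadjusted p_adjusted pooled_sd effect_size
1 placebo vs. dose_200 4.20    1.38 271     0.002518    0.00709      9.15       0.459
2 placebo vs. dose_400 4.78    1.38 270     0.000623    0.00180      9.15       0.522
  weighted comparisons:
            comparison   te std_err  df p_unadjusted p_adjusted pooled_sd effect_size
1 placebo vs. dose_200 5.97    2.54 284       0.0192    0.05016      9.97       0.599
2 placebo vs. dose_400 7.79    2.18 284       0.0004    0.00116      9.97       0.782
```

Both simulated active arms carry a real drug-specific effect that a 55%
placebo-type majority dilutes. The propensity model qualifies (validation
AUC 0.75, CI lower bound 0.51 > 0.5), and the weighted analysis enlarges
the treatment effects (4.20 → 5.97 and 4.78 → 7.79 points) and effect sizes
(0.46 → 0.60, 0.52 → 0.78) relative to the conventional analysis — the
signature of a true effect masked by placebo response. The weighted
standard errors are honestly *larger* (cluster-robust covariance): the gain
is in the estimand, not in an understated variance. Single trials vary —
the replicated behavior (type-I control at the null, the power and
effect-size gain under masking) is what `operating_characteristics()`
measures.
`write_psw_report(res, "out/")` writes the comparison tables, LS means,
ROC summary, propensity bin table and a JSON manifest with every frozen
choice and seed; `inst/cli/pswtrial.R` exposes `simulate`, `analyze`,
`design` and `oc` subcommands over the same functions.

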