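---
title: "Propensity-score-weighted analysis of placebo-confounded trials: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propensity-score-weighted analysis of placebo-confounded trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pswtrial)
```

## The problem

Randomized trials in major depressive disorder fail at a remarkable rate,
and a large share of those failures trace back to the placebo response: a
sizeable fraction of enrolled patients improves under any treatment, active
or inactive. If that fraction is large, the arm contrast shrinks toward
zero regardless of the drug's true activity (a false-negative risk); if it
is unusually small, chance imbalances can manufacture separation (a
false-positive risk). Conceptually the population mixes three latent
classes: patients responsive to neither drug nor placebo (D−P−, typically
30–50% of a non-resistant population), patients responsive to anything
(D+P+, often over 40%), and the small informative remainder responsive to
drug only (D+P−).

Randomization balances these classes only in expectation, and the
conventional longitudinal analysis assigns every subject equal influence.
Propensity-score weighting (PSW) instead estimates, for every randomized
subject, the probability *p* of showing a placebo-type response — from data
collected *before* randomization — and weights each subject by 1/*p* in the
longitudinal model. Subjects likely to improve no matter what are
down-weighted; the informative low-propensity subjects carry more of the
contrast.

`pswtrial` implements the full procedure — response labeling, a neural-
network propensity model with bootstrap-ROC qualification, inverse-
propensity weighting, and a REML mixed model for repeated measures (MMRM)
with unstructured covariance — together with a synthetic-trial simulator
whose ground truth makes every stage testable, and the design calculations
(exact noncentral-*t* sizing, truncated-Hochberg multiplicity) that such
trials use.

## The five-step procedure

Given a long-format table of item-level rating-scale scores (HAMD-17 or
MADRS) at screening, baseline and scheduled post-baseline visits:

1. **Label** placebo-arm subjects as responders when the end-of-study (EOS)
   total score improves by 50% or more from baseline (inclusive threshold;
   `label_placebo_responders()`). Subjects with no EOS observation are
   excluded from labeling and counted — no imputation, since an imputed
   label would leak the imputation model into the classifier target.
   The baseline anchor is the randomization visit (week 0), not screening.
2. **Develop** a feed-forward network on 75% of the labeled placebo arm
   (stratified split, `split_placebo()`), with inputs the per-item
   screening-to-baseline changes (`item_delta_matrix()`; the signed
   convention baseline − screening is a labeled constant). Architecture is
   chosen by stratified 5-fold cross-validated AUC over a grid of 1–3
   hidden layers × \{1, 3, 5, 7\} nodes (`grid_search_ann()`), ties broken
   toward smaller networks. One guard sits on top of the AUC criterion:
   narrow candidates can converge to a saturated optimum whose predictions
   are essentially one constant — the residual micro-ordering still scores
   a respectable AUC because AUC is scale-free, but constant probabilities
   make constant weights and the weighted analysis silently degenerates to
   the reference. Candidates whose out-of-fold probabilities span less than
   0.05 are therefore set aside (with a fallback to the plain AUC ranking
   so that zero-signal data still reach — and fail — the validation gate).
3. **Validate** on the held-out 25%: the AUC of the validation predictions
   with a percentile bootstrap 95% interval over stratified resamples
   (`bootstrap_roc()`; predictions are resampled, not refit — refitting is
   available via `refit_fun`). The model qualifies only when the lower
   bound exceeds 0.5 strictly (`validate_model()`); an unqualified model
   blocks the weighted analysis while the reference analysis still runs.
4. **Predict** the placebo-response propensity for every randomized subject
   in every arm and form weights `w = 1 / max(p, p_floor)`, optionally
   renormalized to mean 1 (`predict_propensity()`).
5. **Fit** the MMRM on change from baseline with `w` as a subject-level
   precision weight, alongside the identical unweighted (reference) fit
   (`fit_mmrm()`, `run_psw_analysis()`).

Propensity models are trial-specific: individual placebo propensity
reflects expectations shaped by the trial's own conduct, so a persisted
model refuses to load against a different instrument unless explicitly
overridden (`load_propensity_model()`).

## The longitudinal model

The response is the change from baseline of the total score at the
post-baseline visits. Writing $y_i$ for subject $i$'s observed vector over
the visit set $V_i$, the marginal model is

$$ y_i \sim N\!\big(X_i\beta,\; \Sigma[V_i, V_i] / w_i \big), $$

with fixed effects for visit (categorical), baseline, baseline×visit and
treatment×visit, and an unstructured $T \times T$ covariance $\Sigma$
estimated by REML. This is the standard MMRM; the weight enters as
precision on the within-subject covariance, the convention of the usual
mixed-model software `WEIGHT` statements. Missing visits contribute nothing
(direct-likelihood MAR handling). The treatment effect (TE) at EOS is the
LS-mean difference placebo − active (positive when the active arm improves
more), the pooled SD is $\sqrt{\hat\Sigma_{\text{EOS,EOS}}}$, the effect
size is $|TE|$ / pooled SD, and p-values are Tukey-adjusted over the
all-pairwise family of arm means (`treatment_effects()`, `tukey_adjust()`).

Numerical choices:

* $\Sigma$ is optimized on the log-Cholesky scale (positive-definite by
  construction) by BFGS from a pairwise-complete residual covariance start,
  followed by an analytic polish of the free variance scale — for a single
  visit this makes the fit equal weighted least squares to machine
  precision. Convergence is judged on the relative change of the REML
  criterion (`reltol = 1e-12`).
* Subjects are grouped by missingness pattern, so the criterion costs a few
  small Cholesky factorizations per evaluation regardless of sample size.
* Weights are renormalized to mean 1 *inside* the fit. Rescaling all
  weights by a constant is a pure reparameterization of $\Sigma$, so this
  makes every reported quantity — including the pooled SD and effect size —
  exactly invariant to the weights' scale.
* Degrees of freedom are Satterthwaite by default (delta-method gradient of
  the contrast variance against the REML information); `"residual"`
  degrees of freedom are available and practically indistinguishable at
  these sizes.

### Inference under estimated weights

Two properties of the weighted analysis deserve explicit care, and both are
visible in this package's own null simulations.

**Whose prediction may weight a subject?** The classifier is trained on
placebo-arm outcomes. If the final network also *predicts* its own training
subjects, a flexible net reproduces their observed labels (training AUC near
1 against held-out AUC near 0.7), so placebo-arm weights encode placebo-arm
outcomes: placebo responders are down-weighted *because they responded*,
the placebo arm's weighted mean improvement drops, and the null treatment
effect acquires a positive bias of several points. The pipeline therefore
uses out-of-fold (cross-fitted) predictions for the placebo training
subjects by default: each is predicted by a fold model that never saw it
(`crossfit_predictions()`), while validation-set and active-arm subjects —
out of sample by construction — use the final model. The literal
apply-the-final-model-to-everyone behavior is available with
`crossfit = FALSE`.

**Which covariance for the weighted estimator?** Inverse-propensity weights
are *working* precision weights: the data are not actually more precise for
low-propensity subjects. The model-based covariance
$(X'\Omega^{-1}X)^{-1}$ then understates the weighted estimator's sampling
variance by roughly $\sqrt{1 + \mathrm{Var}(w)}$ — in our null simulations
the empirical SD of the TE exceeded the model SE by a factor of 1.50 where
$\sqrt{1+\mathrm{Var}(w)} = 1.49$. The weighted analysis therefore defaults
to the cluster-robust (sandwich) covariance with the usual $m/(m-1)$
small-sample factor and between-subject degrees of freedom
(`vcov_method = "empirical"`); the model-based covariance remains the
default for the unweighted reference fit and is available for the weighted
fit with `vcov_weighted = "model"`. A tell-tale of the model-based
convention is a weighted SE *smaller* than the reference SE on the same
data — the direction a precision weight forces — where the honest sandwich
SE is larger.

## The synthetic-trial simulator

`generate_trial()` draws each subject's latent class from the design
mixture, then:

* screening items are per-item binomials matched to a typical entry
  severity (HAMD-17 total ≈ 22, MADRS ≈ 30);
* screening→baseline item changes are multivariate normal, mean-shifted by
  −`propensity_signal` per item for D+P+ subjects (placebo-type responders
  begin improving before randomization), then clamp-rounded to the
  instrument bounds — `propensity_signal = 0` makes the pre-randomization
  data independent of class;
* post-baseline latent totals follow a concave (log-like) improvement
  curve whose EOS magnitude is the class's fractional improvement (default
  0.70 for D+P+, 0.10 otherwise) plus the arm's drug-specific points for
  D+P− subjects in active arms only; noise of SD `noise_sd` (default 6
  points) splits evenly between a subject-level and a visit-level
  component; totals are spread back over items in proportion to the
  baseline item profile;
* dropout is monotone missing-at-random (an MNAR stress switch doubles the
  hazard of D−P− subjects), never touching screening or baseline.

The defaults give end-of-study placebo response rates near 45–50% under the
high-PE mixture (D−P− 0.25, D+P+ 0.55, D+P− 0.20) — high enough to mask a
real drug effect in the unweighted analysis — and validation AUCs in the
0.75–0.90 range at `propensity_signal` 0.5–0.8, bracketing what qualified
propensity models reach on real depression trials. Class prevalences are
mixture midpoints of the ranges quoted above, since only ranges are
reported for real populations. `true_propensity()` returns the generative
probability of a ≥50% EOS improvement under placebo on the latent
(pre-rounding) scale — a closed normal form that Monte-Carlo integration
over the outcome noise reproduces — and is reserved for tests; the analysis
pipeline never reads the truth table.

What the simulator does *not* emulate: site effects, dose–response within
an arm, adverse-event-driven (outcome-dependent) dropout, rater drift, and
item-level correlation structure beyond what the shared total induces.
Passing operating characteristics here demonstrate the method's behavior
under its own assumptions, not performance guarantees on any real trial.

## Design calculations

`two_sample_n()` inverts the exact noncentral-*t* power of the two-sided
two-sample test (fractional solution rounded up): detecting a 3-point
difference at SD 7.5 with 80% power and two-sided α = 0.05 takes 100
subjects per group. `truncated_hochberg()` implements the step-up procedure
with critical constants
$c_i = \left(\frac{\gamma}{m-i+1} + \frac{1-\gamma}{m}\right)\alpha$ for
the *i*-th smallest p-value — Hochberg at γ = 1, Bonferroni at γ = 0; the
constants follow the gatekeeping literature's convention since the
procedure is usually cited by name only. `hochberg_power_sim()` simulates
the three-arm shared-control design directly (which induces the correct
correlation between the two comparisons, rather than assuming it): at 93
subjects per arm and a standardized effect of 0.44 in both active arms,
γ = 0.9 at global α = 0.05 yields ≈90% power to reject at least one
comparison and ≈74–75% to reject both (200,000 replicates; Monte-Carlo SE
< 0.1 points).

## Operating characteristics

`operating_characteristics()` re-runs the *entire* pipeline — simulate,
label, split, train, validate, cross-fit, weight, fit both MMRMs — on
every replicate and tabulates rejection rates at the adjusted α and TE
estimates for the weighted and reference analyses. The shipped scenarios
(`oc_scenarios()`) are two-arm trials of 60 subjects per arm with three
post-baseline visits, crossing a null against a real drug-specific effect
(18 points, i.e. drug-only responders improve by about 0.6 of a typical
MADRS baseline — as strongly as the placebo-type responders do, which is
what membership in the drug-responsive class means; the unweighted analysis
of the masked scenario then sits near a treatment effect of 3.5 points and
effect size 0.3–0.4, the regime of a failed trial of an active drug) with a
low- versus high-PE class mixture, at `propensity_signal = 0.8` so
the per-replicate models sit in the validated-AUC regime in which the
method is actually allowed to operate (the per-replicate configuration
disables the validation gate so the weighted estimator is *measured* in
every replicate rather than conditioning on qualification, uses a fixed
single-architecture grid, 200 bootstrap resamples and residual degrees of
freedom; sizes chosen so several hundred replicates run on one core in
minutes). Under the null/high-PE scenario the weighted rejection rate stays
at the nominal level *because of* the two inference choices above; with the
masked true effect, the weighted analysis recovers power and enlarges the
effect size relative to the reference analysis in most replicates. The
package's test suite computes these rates at 500 replicates per scenario;
this vignette states no number the suite does not itself compute.

## Known limitations

* The sandwich covariance ignores the sampling variability of the weights
  themselves (the first-stage classifier); with cross-fitted weights this
  is second-order, but exact frequentist calibration under estimated
  weights is not claimed.
* The weighted estimand is a propensity-tilted contrast, not the ITT
  average treatment effect; when the drug effect is concentrated in
  low-propensity subjects the tilt is exactly the point, but the two
  estimands should not be conflated.
* `p_floor` (default 0.05) caps raw weights at 20; lowering it toward the
  raw 1/p of the original formulation destabilizes the weighted fit when
  predictions approach 0.
* The network is a plain fully-connected logistic MLP trained by BFGS with
  a small L2 penalty (`decay`, default 1e-3 on the mean cross-entropy);
  there is no early stopping, so regularization strength is the only
  complexity control besides the architecture grid.
* Labeling excludes subjects with missing EOS rather than imputing; with
  heavy, outcome-dependent dropout the labeled subsample may not represent
  the placebo arm.
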