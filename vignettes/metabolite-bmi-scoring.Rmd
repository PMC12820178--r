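---
title: "Metabolite scores for pre-pregnancy BMI: methods and design"
author: "metabmi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite scores for pre-pregnancy BMI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Maternal pre-pregnancy BMI is associated with several pregnancy
complications — gestational diabetes most prominently — and part of that
association is plausibly carried by the maternal blood metabolome.  `metabmi`
implements the full analysis chain for that question on tabular cohort data
(a samples × metabolites abundance matrix, a covariate/outcome table, and a
metabolite annotation):

1. **Preprocessing** — missingness filtering, random-forest imputation,
   log/centre/scale standardisation, iterative-PCA covariate imputation and
   twin de-duplication.
2. **Scoring** — a one-component sparse partial least squares (sPLS) model of
   standardized metabolites on BMI, tuned by repeated cross-validation, and
   projected into external cohorts over overlapping metabolite panels.
3. **Association** — multivariable logistic models of each binary
   complication on BMI, on the score, and on the BMI-adjusted score, with
   per-SD odds ratios and Wald inference.
4. **Enrichment** — hypergeometric over-representation of the selected
   metabolites among annotation sub-pathways, with FDR and Bonferroni
   control.
5. **Mediation** — quasi-Bayesian causal mediation of the BMI → outcome
   association through a composite metabolite score, wrapped in a backward
   elimination that isolates the maximally mediating metabolite subset.

Real mother–child cohorts with these measurements are access-restricted, so
the package ships a synthetic-cohort generator with planted ground truth;
every stage is validated by recovering what was planted.

## The sparse PLS score

Metabolite columns are standardized (natural log, centre, scale; the log
base only rescales weights, not inference).  For standardized response $y$
(BMI per SD) and matrix $Z$, the one-component PLS direction is proportional
to the vector of column–response correlations $c_j = \mathrm{cor}(Z_j, y)$.
Sparsity soft-thresholds this direction at a fraction $\eta$ of its largest
entry,

$$w_j = \mathrm{sign}(c_j)\,\max\!\bigl(0,\ |c_j| - \eta \max_k |c_k|\bigr),$$

after which $w$ is normalised and the score is $s = Zw$, with the sign fixed
so that $\mathrm{cor}(s, y) \ge 0$ ("higher score = higher predicted BMI").
At $\eta = 0$ this is exact one-component PLS (the tests verify agreement
with an independent NIPALS implementation to cosine $1 - 10^{-8}$); at
$\eta = 1$ every weight is thresholded away and the fit is refused.  This
soft-thresholded-direction family, with a single sparsity parameter on a
grid from 0 to 1 in steps of 0.1, is the canonical sparse-PLS variant behind
common machine-learning front-ends; only one component is used, trading a
little fit for interpretability and robustness to overfitting.

Sparsity is selected by repeated (default 10×) 5-fold cross-validated RMSE.
All standardisation — of the metabolite columns *and* of the response — is
re-learned inside each training fold, so held-out predictions carry no
leakage; the final reported model standardizes on the full training cohort.
`RMSECV` is the root mean squared held-out error pooled across folds and
repeats, in response-SD units, and `R2CV` $= 1 - \mathrm{SSE}/\mathrm{SST}$
with SST about the training-fold mean, so `R2CV` $\approx 1 -$
`RMSECV`$^2$ for a standardized response.  Ties in RMSECV go to the larger
$\eta$ (the sparser model).  Fold assignment is stratified by response
tertile to stabilise RMSECV at small $n$ (configurable off).  Grid values
that degenerate in some fold (all weights thresholded away, always the case
at $\eta = 1$) are recorded as `NA` and excluded from selection.

For transfer to an external cohort measured on a partially overlapping
panel, `transfer_fit()` restricts the training matrix to the overlap and
reruns tuning and fitting from scratch — one model per external panel —
and `predict_score()` z-scores the projected score within the external
cohort, the convention that makes per-SD odds ratios comparable across
cohorts and visits.

## Association models

Binary complications are modelled with `glm(binomial)` maximum likelihood.
Continuous exposures are z-scored so odds ratios read per SD.  Inference is
Wald: normal-tail two-sided p-values and $\exp(\hat\beta \pm 1.959964\,
\mathrm{SE})$ intervals.  The association table applies no multiplicity
adjustment (each row answers its own question); pathway enrichment, which
screens many sub-pathways, does adjust.  Rank-deficient designs and
separation (non-convergence with $|\hat\beta| > 15$) are refused with
explicit errors rather than returned as fragile estimates.  Nested models
are compared with the likelihood ratio test,
$\Lambda = 2(\ell_{\mathrm{full}} - \ell_{\mathrm{reduced}})
\sim \chi^2_{\Delta\mathrm{df}}$.

## Pathway enrichment

For a background of $N$ metabolites available to the model of which $K$ lie
in a sub-pathway, and $n$ selected metabolites of which $k$ lie in it, the
over-representation p-value is the inclusive upper hypergeometric tail
$P(X \ge k)$ and the fold enrichment is $(k/n)/(K/N)$.  The background
defaults to the metabolites available to the model (e.g. the overlap panel),
not the full annotated catalogue; the multiplicity $m$ for BH-FDR and
Bonferroni counts the sub-pathways actually tested (those with at least one
selected member), both configurable.  Unannotated metabolites fall into an
`"Unassigned"` sub-pathway so the background always partitions.

## Causal mediation and backward elimination

The mediator is a *composite* metabolite score: the sPLS weights restricted
to a subset, applied to the standardized metabolites and re-standardized.
Two models are fitted with a shared covariate structure — a linear model of
the composite on standardized BMI, and a logistic model of the outcome on
BMI plus the composite.  The average causal mediation effect (ACME) is
estimated by quasi-Bayesian simulation: coefficient vectors are drawn from
each model's asymptotic normal distribution; per draw, counterfactual
mediator values are simulated at the treated and control exposure (adding
mediator-model residual noise), pushed through the outcome model, and the
four exposure/mediator combinations averaged over samples.  ACME is the
mediator contrast averaged over the two exposure arms, ADE the exposure
contrast at fixed mediator arm, and their sum equals the total effect draw
by draw (asserted to $10^{-12}$ in the tests).  Design choices:

- **Scale.** Effects are reported on the probability (risk-difference)
  scale, the convention of the simulation-based mediation framework for
  binary outcomes.
- **Contrast.** Control = mean BMI, treat = mean + 1 SD, matching the
  pipeline's per-SD reporting; configurable.
- **Residual noise.** The same noise matrix is used for both counterfactual
  mediator arms (common random numbers), which cancels Monte-Carlo noise
  from the ACME contrast without biasing it.
- **Draws.** 10,000 parameter draws for final inference; the test suite and
  desk-scale runs use 500–2,000 with correspondingly widened tolerances.
- **Proportion mediated** is reported only when ACME and total effect share
  a sign.

Backward elimination starts from the sPLS-selected set and repeatedly drops
the metabolite whose removal most increases the ACME, provided it increases
it at all (a strict point-estimate rule; the stop criterion "no further
gain" is judged on the point estimate, not an interval), down to a floor of
two metabolites so the mediator model stays non-degenerate.  Every ACME
evaluation in one elimination run shares a single derived seed: candidates
within an iteration are compared on common random numbers, removals are
accepted against exactly reproducible baselines, and the accepted ACME
sequence is strictly increasing by construction.  The composite score is
*not* refitted per step — the original sPLS weights, restricted to the
remaining set, are reused and re-standardized, which is what a fixed
"composite metabolite score" implies; per-step refitting is deliberately
out of scope.

One property worth knowing when interpreting elimination traces: for a
z-scored composite with homogeneous weights over equally BMI-loaded
metabolites, adding or removing a *non-mediating but BMI-correlated*
metabolite leaves the population ACME unchanged — the dilution of the
outcome path exactly cancels the gain in the mediator path.  Elimination
therefore prunes metabolites that are weakly loaded or noise-like, and
retains strong mediators, but has no gradient against perfect BMI proxies.
The mediator-recovery tests plant heterogeneous loadings (strong for
mediators, weak for bystanders), the regime in which the procedure is
informative; on real data the same caveat applies to metabolites that track
BMI as tightly as the mediators do.

## The synthetic cohort generator

`generate_cohort()` draws a latent adiposity factor $A \sim N(0,1)$ per
pregnancy and builds, in order:

- **Covariates** mirroring a typical adjustment set in shape: a continuous
  social-circumstances summary, smoking (made dependent on it, so
  covariates correlate), child sex, and three continuous dietary-pattern
  components.  No claim is made about real covariate distributions; the
  set exists to exercise mixed-type handling and confounding adjustment.
- **BMI** $= \mu + \sigma\,(\sqrt{r^2} A + \text{covariate effects} +
  \varepsilon)$, with the noise scaled so the latent factor explains the
  configured `signal_r2` of BMI variance (default 0.4, matching the
  cross-validated predictability the pipeline is designed around).
- **Metabolites**: log-abundances of the `n_signal` signal metabolites load
  on $A$ with magnitudes drawn from `weight_range` (default 0.4–1.0) and
  70% positive signs, plus unit noise; all metabolites are exponentiated
  around random baselines, so abundances are log-normal and the pipeline's
  log/centre/scale is the correct inverse.  Defaults are 700 samples × 640
  metabolites with 46 signal and 16 mediator metabolites — the shape of the
  study this package is built for; the test suite scales down to ~200 × 120.
- **Outcomes** from logistic models: intercept at the configured baseline
  prevalence, a direct per-SD BMI term, per-SD terms for the mediator
  metabolites, and covariate terms.  A mediator's outcome coefficient
  carries the sign of its adiposity loading, so all mediators route BMI
  risk in a coherent direction (protective metabolites are negative on
  both paths).  Mediators load on $A$, so their outcome effects are a
  BMI-mediated path by construction.
- **Twins** (default 2% of samples) share a duplicated `family_id` and the
  maternal record, with jittered BMI — exercising the rule that keeps one
  pregnancy record per family.
- **Missingness**: MCAR at a configured cell rate, or an outcome-dependent
  variant multiplying each sample's per-cell missingness odds by
  $e^{\gamma y}$ — a stylised stand-in for non-random missingness observed
  in real cohorts (where cesarean delivery associated with *less* missing
  metabolite data), not a claim about the real mechanism.

What the generator does **not** emulate: real abundance distributions and
their heavy tails, batch and drift effects, the true covariate correlation
structure, or assay-specific missingness patterns.  Tests passing on this
generator demonstrate that the statistical machinery recovers planted
truth under its own assumptions — not that the pipeline is robust to every
artefact of real LC-MS data.

## Preprocessing choices

- **Missingness filter**: "more than a third missing" is read literally —
  strictly greater than 1/3 excludes; exactly 1/3 is retained.
- **RF imputation** is the missForest scheme (mean-initialise, sweep columns
  by decreasing missingness with ties by index, refit a forest per column,
  stop when the change in imputed values increases, returning the previous
  sweep).  It makes no missing-at-random assumption.  Imputation runs on
  the log scale, where abundances are approximately Gaussian; observed
  cells are never altered (asserted cell-wise in the tests).
- **Covariate imputation** is one-component iterative PCA with centring and
  scaling recomputed from the current completed table each iteration (an
  exactly rank-1 table is then a fixed point, which the tests verify by
  closed-form completion).  Categorical columns are one-hot expanded and
  re-collapsed to the category with the largest reconstructed indicator.
- **Missingness diagnostic**: the per-sample predictor is an any-missing
  indicator over the metabolite subset by default, with a count option; the
  original analysis's exact coding is not stated anywhere, so both are
  provided.

## Reproducibility and problem sizes

Every stochastic routine takes an explicit seed and restores the caller's
RNG state; a single pipeline seed fans out to per-stage seeds through a
fixed affine map (`derive_seed()`), so stages rerun independently yet
reproducibly, and two runs under one seed produce byte-identical artifacts
(asserted in the acceptance tests).  The packaged test suite and
`scripts/acceptance.R` run at desk scale — cohorts of 200–500 samples ×
120–140 metabolites, 3–5 CV repeats, 500–2,000 mediation draws — sizes
chosen so the whole validation executes in minutes on one core while
leaving every planted effect recoverable; defaults for real analyses remain
at the full settings (10 CV repeats, 10,000 draws).

## Known limitations

- One sPLS component only; no orthogonalised deflation, no elastic-net
  alternatives, and a single sparsity parameter.
- No exposure–mediator interaction in the mediation models, and no
  sensitivity analysis for sequential ignorability; the elimination is a
  selection heuristic on the ACME point estimate, not a joint
  multiple-mediator decomposition.
- Wald (not profile) intervals throughout; separation is refused, not
  penalised (no Firth correction).
- The enrichment background and multiplicity conventions are configurable
  because the "correct" choices are genuinely ambiguous; defaults are
  documented above.
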