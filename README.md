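# metabmi

Metabolite scores, pathway enrichment and causal mediation for maternal
pre-pregnancy BMI and pregnancy complications.

## What this package is for

Maternal pre-pregnancy BMI raises the risk of several pregnancy
complications, gestational diabetes above all, and part of that association
is plausibly carried by the maternal blood metabolome.  `metabmi` implements
the complete analysis chain for cohort metabolomics data addressing that
question, for epidemiologists and biostatisticians working with
samples × metabolites abundance tables:

- **Preprocessing**: exclusion of metabolites with more than a third
  missing values, iterative random-forest imputation (missForest scheme,
  via `ranger`), log/centre/scale standardisation, one-component
  iterative-PCA covariate imputation, twin de-duplication, and a diagnostic
  for outcome-associated (non-random) missingness.
- **BMI metabolite score**: one-component sparse partial least squares.
  With standardized metabolites `Z` and standardized BMI `y`, the direction
  is the soft-thresholded correlation vector
  `w_j = sign(c_j) max(0, |c_j| − η max|c|)`, `c_j = cor(Z_j, y)`, with the
  sparsity η tuned over the grid 0, 0.1, …, 1 by repeated (10×) 5-fold
  cross-validated RMSE (RMSECV, with R²CV alongside), standardisation
  re-learned inside every training fold.  Scores transfer to external
  cohorts by refitting on the overlapping metabolite panel and z-scoring
  the projected score within cohort.
- **Association models**: multivariable logistic regression of each binary
  complication on BMI, on the score, and on the BMI-adjusted score, with
  per-SD odds ratios, Wald 95% CIs and two-sided p-values, plus
  likelihood-ratio tests for nested models.
- **Pathway enrichment**: inclusive upper-tail hypergeometric
  over-representation of selected metabolites among annotation
  sub-pathways, with fold enrichment `(k/n)/(K/N)`, BH-FDR and Bonferroni
  control.
- **Causal mediation**: quasi-Bayesian ACME (risk-difference scale, per-SD
  exposure contrast) for a composite metabolite score mediating
  BMI → outcome, and a backward-elimination loop that repeatedly drops the
  metabolite whose removal most increases the ACME, isolating the mediating
  subset; the subset score is compared against the full score by a 1-df LRT.
- **Synthetic cohorts**: a generator with planted ground truth (latent
  adiposity factor, sparse metabolite signal, mediator subset, confounded
  covariates, configurable MCAR/outcome-dependent missingness, twin pairs)
  so every stage is validated by recovery of known truth.

The methods vignette (`vignettes/metabolite-bmi-scoring.Rmd`) documents the
models, their assumptions, all tunable parameters and the design decisions.

## Worked example

A discovery cohort with a planted sparse BMI signal (18 of 140 metabolites,
6 of them mediating gestational diabetes), preprocessing, scoring,
association, enrichment and mediation:

```r
library(metabmi)

cfg <- cohort_config(n_samples = 500, n_metabolites = 140, n_signal = 18,
                     n_mediators = 6, signal_r2 = 0.4, missing_rate = 0.05,
                     outcome_specs = list(
                       outcome_spec("gestational_diabetes", 0.15,
                                    bmi_logor = 0.2, mediator_logor = 0.3)),
                     seed = 101)
gen <- generate_cohort(cfg)
d   <- apply_missingness(gen$data, cfg)

filt <- filter_by_missingness(d$abundances)        # > 1/3 missing excluded
logm <- filt$matrix; logm[!is.na(logm)] <- log(logm[!is.na(logm)])
imp  <- rf_impute(logm, seed = 1)                  # missForest-style, on log scale
std  <- log_center_scale(imp$matrix, log = FALSE)

model <- fit_bmi_score(std$z, as.numeric(standardize_predictor(d$bmi)),
                       repeats = 5, seed = 2, standardise = FALSE)
model
#> One-component sPLS model: 62/140 metabolites selected (eta = 0.1)
#>   RMSECV = 0.835, R2CV = 0.302

score <- predict_score(model, std$z)
fit_logistic(d$outcomes$gestational_diabetes, score,
             exposure_name = "score", outcome_name = "gestational_diabetes")
#> Logistic model gestational_diabetes ~ score  (n = 500)
#>   score: OR 2.41 [1.84-3.14], p = 1.3e-10

trace <- backward_eliminate(std$z, d$bmi, d$outcomes$gestational_diabetes,
                            model = model, n_sim = 500, seed = 3)
trace
#> Backward elimination: 62 -> 61 metabolites (no_gain)
#>   initial ACME +0.0726, final ACME +0.0743 over 1 removals
trace$final
#> Causal mediation (quasi-Bayesian, 500 draws)
#>   ACME  +0.0743 [+0.0484, +0.1054]
#>   ADE   +0.0248 [-0.0228, +0.0713]
#>   Total +0.0992 [+0.0579, +0.1454]
#>   Proportion mediated 0.75
```

Reading the output: the tuned score explains ~30% of BMI variance out of
sample (R²CV; RMSECV is in BMI-SD units, so R²CV ≈ 1 − RMSECV²).  Per SD of
the score, the odds of gestational diabetes multiply by 2.41.  The mediation
decomposition attributes about three quarters of the total BMI effect on
the probability scale to the metabolite path, and the elimination keeps all
six planted mediators in the retained set.  At this cohort size the tuner
picked a dense model (η = 0.1); larger cohorts, or stronger sparsity
signals, yield selections close to the planted 18 (see the acceptance
run below, where 17/140 are selected with Jaccard 0.94 against truth).

The whole chain, including an independently generated validation cohort,
cross-cohort score transfer and TSV/JSON outputs, runs as one call:

```r
report <- run_pipeline(run_config("my_run", seed = 1))
```

or from a shell via `inst/scripts/run-pipeline.R`.

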