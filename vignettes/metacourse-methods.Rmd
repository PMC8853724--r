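---
title: "Methods and design of the metacourse pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the metacourse pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(metacourse)
```

## The analytic problem

Plasma metabolite levels in late midlife associate with concurrent and
near-future cognitive function, but a metabolite–cognition association
measured at one point in time is the net of many influences acting over
decades. Early-life cognition and socioeconomic position shape both adult
health behaviours (which move metabolite levels) and adult cognitive test
scores, so they can confound — or mediate — cross-sectional associations.
`metacourse` operationalizes a life-course analysis: every association is
estimated under a nested series of adjustment models, the change in each
coefficient is tracked and attributed, and a correlation-network layer
summarizes co-abundant metabolites into modules whose joint behaviour is
easier to interpret biologically than hundreds of single-metabolite tests.

The pipeline has six cooperating parts: a synthetic cohort generator with
planted ground truth, metabolite quality control, covariate multiple
imputation, the regression model series, the weighted signed correlation
network, and hypergeometric pathway enrichment with reporting. This
vignette records how each part works, the parameters that matter, and the
design decisions taken where more than one defensible choice existed.

## Metabolite quality control

`filter_missingness()` drops metabolites with strictly more than
`max_frac = 0.20` missing samples; a metabolite at exactly 20% is kept.
`knn_impute()` (k = 10) treats metabolite profiles, not samples, as the
objects being matched: for a metabolite with missing cells, the k nearest
metabolites by Euclidean distance — computed over mutually observed samples
and rescaled by the fraction observed, so sparse overlap does not fake
proximity — supply the imputed value as their mean in the affected sample.
Distance ties break by column order, making the imputation deterministic. A
metabolite with no overlapping observations at all falls back to its column
mean with a warning. `log10_transform()` then maps abundances to an
approximately normal scale, and `zscore()` standardizes each column with
the n − 1 denominator.

The `metab_matrix` container enforces the stage order
raw → filtered → imputed → log10 → zscored, so a matrix cannot, for
example, be z-scored before imputation. On a complete matrix the whole QC
chain reduces exactly to log10 + z-score, which the tests verify.

## Covariate multiple imputation and pooling

`mice_impute()` implements chained equations directly. Variables are
visited in fixed column order for `iters = 10` cycles (per-variable chain
means are retained for convergence monitoring); conditional models are:

* continuous — predictive mean matching with a donor pool of 5 and a
  Bayesian draw of the regression parameters (σ² from the scaled inverse
  chi-square, β from its normal posterior). PMM was preferred over a
  normal-model draw because several covariates (pack-years, BMI) are
  skewed or semi-continuous, and PMM only ever imputes observed values.
* binary — logistic regression with a parameter draw; if the fit fails to
  converge the imputation falls back to a draw from the observed margin,
  with a warning.
* categorical (ordered or nominal) — a multinomial fit
  (`nnet::multinom`) with draws from the fitted category probabilities.
  No parameter draw is added here; with the moderate missingness rates the
  package targets, the extra between-imputation variance this would
  contribute is small, and the fallback-on-failure rule is shared with the
  logistic case.

The default `m = 50` completed datasets matches standard practice for
covariate missingness of 10–30%; tests and examples use m = 3–5, which is a
speed choice only — every formula is m-agnostic.

`pool_rubin()` combines per-imputation estimates: pooled β is the mean,
within-variance W the mean squared standard error, between-variance B the
sample variance of the βs, and T = W + (1 + 1/m)·B. Degrees of freedom use
the Barnard–Rubin small-sample formula with complete-data degrees of
freedom supplied by the caller (`run_model_series` passes n − p − 1).
When B = 0 the df collapse to the complete-data df, and with `dfcom = Inf`
the interval is normal-based.

## The regression model series

`model_covariates()` fixes the four nested covariate sets (basic
blood-clinic variables; + BMI and lipid medication; + childhood cognition,
education, childhood/midlife SEP; + blood pressure, activity, alcohol,
smoking, diet). Categorical covariates are dummy-coded with the first level
as reference; APOE ε4 dose (0/1/2) is treated as continuous when the
APOE-adjusted sensitivity rerun adds it. Continuous covariates, predictors
and outcomes are standardized, so coefficients are per-SD.

`run_model_series()` fits every (predictor, outcome, model) cell on each
imputed dataset and pools. Internally it uses the Frisch–Waugh–Lovell
decomposition: the covariate design is QR-factorized once per (outcome,
model, imputation), the outcome and *all* predictor columns are residualized
against it in one matrix operation, and each predictor's coefficient and
standard error come from the resulting simple regressions with
df = n − p − 1. This is algebraically identical to the full OLS fit (the
tests check agreement with `lm` to 1e-10) and makes metabolome-wide scans
cheap. Rank-deficient designs are an error naming the collinear columns,
never a silent drop.

Significance tiers use `alpha` divided by the effective number of tests:
`effective_tests()` counts the principal components of the metabolite
correlation matrix needed to exceed (strictly) 95% cumulative variance.
PCA is on the correlation rather than covariance matrix — the metabolites
are z-scored, so the two coincide up to scaling, and the correlation form
is invariant to upstream unit choices.

Attenuation is reported as the signed percent change in coefficient
*magnitude*, 100·(|β_adj| − |β_ref|)/|β_ref|: shrinkage toward zero is
negative whatever the coefficient's sign, growth is positive. This is the
convention used in attenuation tables of the epidemiological literature;
the complementary "% attenuation" form 100·(1 − |β_adj|/|β_ref|) is also
returned. A zero reference coefficient makes the quantity undefined (NA
with a warning). `attenuation_ledger()` reruns Model 1 plus one candidate
covariate at a time and ranks covariates by the attenuation they alone
produce — on synthetic cohorts the planted confounder tops this ranking.

Pathway scores are per-sample means of the z-scored member metabolites;
pathways with fewer than 5 members are dropped and reported. Pathway
regressions adjust for the basic model only. For outcomes measured at two
waves, `residual_change_score()` regresses the later wave on the earlier
one and standardizes the residuals; samples missing either wave are
excluded and counted.

## Network construction

The network branch follows the order residualize → outlier scan → exclude →
rebuild: metabolites are first residualized on the basic covariates (the
standardized residuals are the working data), sample outliers are then
flagged by standardized connectivity Z.k in the sample–sample network with
adjacency (1 + cor)/2, samples with Z.k < −4 are dropped, and the residuals
are re-centred and re-fit on the kept samples. Z-scoring happens before
outlier exclusion only in the sense that the residuals are standardized;
the final working matrix is re-standardized after exclusion.

`bicor_matrix()` implements the biweight midcorrelation: deviations from
the column median are scaled by 9·MAD (unscaled MAD, the standard biweight
tuning), observations with |u| ≥ 1 get zero weight, and the correlation is
the weighted centred cross-product over the weighted norms. A column with
zero MAD but nonzero variance falls back to its Pearson standardization,
per-column, with a warning; constant columns are an error.

`signed_adjacency()` uses the signed convention ((1 + cor)/2)^β so that
anticorrelated metabolites receive near-zero adjacency; the unsigned
|cor|^β variant is available behind the `type` flag. The diagonal is zero
so connectivity sums exclude self-adjacency.

`pick_soft_threshold()` scans powers 1..20. The scale-free fit bins the
connectivity distribution into 10 equal-occupancy bins and regresses the
log10 bin *density* (count divided by total and bin width) on the log10
mean connectivity per bin; the fit index is R² signed by the negative
slope. Equal-occupancy bins with a density correction were chosen over
equal-width histogram bins because the latter leave most bins nearly empty
at high powers, making the index noisy; the density form estimates the same
power-law slope. The chosen power is the smallest reaching
R² ≥ 0.85 — which, because mean connectivity decreases monotonically in the
power, is also the qualifying power with maximal mean connectivity. When no
power qualifies (block-structured synthetic data with a small unassigned
fraction genuinely is not scale-free), the best-fitting power is returned
with a warning; analyses in this package's examples then fix the power
explicitly.

`tom_matrix()` computes the topological overlap
TOM_ij = (Σ_u a_iu·a_uj + a_ij)/(min(k_i, k_j) + 1 − a_ij) with unit
diagonal; 1 − TOM is the clustering dissimilarity. The vectorized form is
checked against a triple-loop oracle to 1e-12 on random graphs.

### Dynamic hybrid module detection

`cluster_modules()` re-implements the dynamic hybrid cut from its published
description at reduced complexity; bit-exact agreement with the reference
implementation is not a goal — recovery of planted module structure is the
validation surface. Three stages act on the average-linkage dendrogram:

1. **Branch identification.** The tree is first cut statically at 0.99 of
   the maximum joining height, severing the loosely joined upper ladder
   where modules, stragglers and noise attach to one another. Each
   component is then refined top-down: a node splits where the joining
   height leaves a gap of at least `gap_abs` to both sub-branches; a
   sub-minimum side chained on with a clear gap is peeled off; a terminal
   branch of at least `min_module_size = 20` members becomes a module when
   its core scatter (mean internal merge height) is below `cs_abs`. Both
   thresholds are linear in `deep_split` (0–4): higher values relax the
   scatter criterion and shrink the required gap, yielding more granular
   modules, matching the conventional meaning of the parameter. Before a
   terminal branch is labelled it is trimmed to its core — members whose
   average dissimilarity to the rest of the branch is a robust outlier
   (above median + 3·MAD) are left unassigned, since they are stragglers
   that attached just below the static cut rather than module members.
2. **Nearest-module assignment.** Each unassigned metabolite joins the
   module with the smallest average dissimilarity, provided that distance
   lies within the module's own radius (the maximum average within-module
   dissimilarity of its members); otherwise it stays grey. This bound is
   data-driven: background metabolites sit far outside every module's
   radius and remain grey, while genuine members peeled off in stage 1 fall
   inside it.
3. **Eigenvalue merging.** Module eigenvalues are computed, modules are
   clustered on 1 − cor(eigenvalues) and groups joined below
   `merge_height = 0.25` merge; the procedure repeats until stable.

Labels are colour strings in descending module size (turquoise, blue,
brown, yellow, …), with "grey" for unassigned metabolites. Grey never
enters eigenvalue, kME, enrichment or regression computations.

On the package's planted-module cohorts (four modules of 25–60 metabolites,
within-module correlation 0.6, background 0.05, n = 600) this procedure
recovers the planted assignment with adjusted Rand index 1.0 across seeds,
and leaves pure-noise matrices entirely grey.

`module_eigenvalues()` returns the first principal-component score of each
module's member submatrix, unit-variance scaled and sign-aligned to
correlate positively with the module's average profile (a single-member
module degenerates to that column standardized). `module_kme()` is the full
metabolite × module correlation table; `identify_hubs()` intersects the
strict own-module kME > 0.65 cut with the Bonferroni-significant set from
the single-metabolite analyses. Module eigenvalues feed back into
`run_model_series()` with `exclude_model1 = TRUE`, since the metabolites
were already residualized on the basic covariates.

## Enrichment and reporting

`hypergeom_ora()` tests each (module, pathway) pair with the upper-tail
hypergeometric probability P(X ≥ k), including the observed overlap — the
standard overrepresentation convention. The universe is the set of
metabolites that are both module-assigned (non-grey) and pathway-annotated;
chemically unidentified "X-" metabolites carry no pathway and are excluded.
Including grey metabolites in the universe is available behind
`include_grey` but off by default: grey is an "unassigned" verdict, not a
module, and counting its members would dilute every module's expected
overlap. Tiers use 0.05 divided by the realized module count — every
threshold in the report (effective tests, pathway count, module count) is
recomputed from the data at hand, never hard-coded.

`run_pipeline()` orchestrates all stages from a configuration list (or YAML
file), logs the seed of every random stage, and emits a JSON + CSV report
bundle. Sensitivity reruns re-invoke the model series with the APOE dose
added to every model, or on the subsample at or above a clinical
cognition-screen total (default threshold 82/100 when enabled). Rerunning
with the same configuration reproduces the report exactly.

## The synthetic cohort generator

`cohort_spec()` fixes the study conditions. Metabolite abundances are
10^(μ + z) of a latent normal z with block-constant within-module
correlation — the simplest positive semi-definite structure with one
recoverable parameter per module — plus a cohort-wide background factor
giving every metabolite pair a floor correlation. The log10 step of QC is
therefore the exact inverse of the generator, which the tests exploit.
Defaults: four modules of 60/45/35/25 metabolites plus 40 unassigned
metabolites (half of them "X-" unknowns), within-module correlation 0.6 and
background 0.05. The within-module default is a free choice (real cohort
magnitudes are not publishable); 0.6 sits in the middle of the 0.5–0.7
range typical of reported metabolomics modules and is a `cohort_spec()`
parameter.

The ground-truth "module eigen-signal" is the module's full unit-variance
common component, √b·g + √(ρ−b)·f scaled — not the bare module factor —
because that common component is precisely what a module eigenvalue
estimates; effects and confounder loadings defined against it are
recoverable without systematic attenuation (the eigengene–signal
correlation is ≈ 0.99 at the default module sizes).

Covariates are generated from latent normals: confounder-map entries load
on module eigen-signals with the stated correlation, and social
(childhood cognition, education, SEP), lifestyle (smoking, alcohol,
activity, diet) and cardiometabolic (BMI, lipid medication, blood pressure)
variables share mild common factors so the covariate table is realistically
intercorrelated. Categorical covariates threshold their latent at the
quantiles of realistic marginal frequencies, preserving the latent
correlation structure. Outcomes are Σ β·(standardized source) + N(0, σ²)
with σ² = 1 − Σβ², so stated betas are standardized effects; an auxiliary
0–100 cognition-screen total is derived for the exclusion rerun.
Missingness is MCAR: per-metabolite rates drawn uniformly from
`missing_rate_range`, and a single rate for non-basic covariates (the basic
blood-clinic set stays complete, mirroring a cohort where complete clinic
data are an inclusion criterion). One RNG stream per component
(metabolome / covariates / missingness), each derived from the master seed,
gives stage-level reproducibility.

What the generator does **not** emulate: LC–MS batch and drift artefacts,
missing-not-at-random mechanisms (real metabolomics missingness is partly
abundance-dependent), realistic pathway sizes and overlap structure,
selective attrition, or measurement error in covariates. Passing tests
therefore demonstrate that the machinery recovers what it is designed to
recover under clean MCAR, compound-symmetric conditions — not that the
pipeline is robust to those real-data pathologies.

## Numerical choices and degenerate inputs

* kNN distance ties break by metabolite column order; imputation is fully
  deterministic.
* MI parameter draws add a 1e-8 ridge before inversion and symmetrize the
  covariance before the Cholesky factor; a failed factorization falls back
  to the point estimate.
* Zero-variance metabolite columns are an error everywhere (z-scoring,
  bicor, residualization), never silently dropped — they indicate a
  degenerate synthetic configuration or an upstream bug.
* The TOM denominator is guarded against non-positivity, which cannot
  occur for a valid adjacency but catches numeric corruption.
* Bicor values are clamped to [−1, 1] and symmetrized against floating
  point drift; module eigenvalue signs are fixed by the average-profile
  rule, making dendrogram-independent quantities reproducible across BLAS
  implementations.

## Problem sizes

The test suite and acceptance script run at deliberately modest sizes:
n = 600 (205 metabolites) for module recovery, n = 2000–5000 for effect
recovery and confounding checks, 50 replicates of n = 300 × 100 metabolites
for the type-I error study, m = 3–5 imputations in pipeline runs. These are
the package's validation sizes; the code paths are identical at cohort
scale (n ≈ 2000, ~1000 metabolites), where the dominant costs — the
metabolite correlation matrix and the per-imputation QR — remain
small by modern standards.

## Known limitations

* The dynamic hybrid cut is a re-implementation at reduced complexity; on
  dendrograms with strongly nested module structure its assignments can
  differ from the reference algorithm even when both are defensible.
* Under covariate missingness, imputation error leaves a little residual
  confounding after Model-3 adjustment (attenuated, not exactly zero);
  this is a property of multiple imputation, not of the adjustment logic.
* Residualized change scores are used as specified but are a known source
  of bias when baseline measurement error is substantial.
* The scale-free fit criterion is honest about block-structured synthetic
  data: compound-symmetric modules with little background do not produce
  scale-free degree distributions, and the scan then reports its best
  power with a warning rather than manufacturing a qualifying fit.
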