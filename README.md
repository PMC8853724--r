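# metacourse

Metabolome-wide association analysis of midlife cognitive outcomes with
life-course confounder adjustment and weighted signed correlation network
analysis, for epidemiologists and systems biologists working with
LC–MS plasma metabolomics in cohort studies.

Blood metabolites measured in late midlife correlate with cognitive
function, but many of those associations are shaped by factors acting across
the whole life course — childhood cognition, education, socioeconomic
position, lifestyle. `metacourse` implements the full analytic pipeline for
untangling this: single-metabolite and pathway regressions across a nested
series of adjustment models with attenuation accounting, and a
correlation-network view that groups co-abundant metabolites into modules,
relates module summary profiles to outcomes, and flags highly connected
("hub") metabolites that are also individually associated — the most
promising marker candidates.

Because real cohort data of this kind are access-controlled, the package
ships a synthetic-cohort generator that plants known metabolite modules,
confounded covariates and outcome effects, so every stage of the pipeline is
validated against a recoverable ground truth.

## The methods

**Metabolite QC** — metabolites with more than 20% missing samples are
excluded; the rest are completed by k-nearest-neighbour imputation (k = 10,
neighbours are metabolite profiles, Euclidean distance over mutually
observed samples), log10-transformed and z-standardized.

**Covariate multiple imputation** — missing covariates are imputed by
chained equations (predictive mean matching for continuous variables,
logistic draws for binary, multinomial draws for categorical; default m = 50
completed datasets). Per-imputation regression estimates are pooled with
Rubin's rules: pooled β is the mean, total variance T = W + (1 + 1/m)·B with
W the mean squared standard error and B the between-imputation variance,
and degrees of freedom follow Barnard–Rubin.

**Nested adjustment models** — Model 1: sex, clinic, age at clinic, fasting;
Model 2 adds BMI and lipid medication; Model 3 adds childhood cognition,
education, childhood and midlife socioeconomic position; Model 4 adds blood
pressure, physical activity, alcohol, smoking and diet. Attenuation is
reported as the signed percent change in coefficient magnitude relative to
Model 1, and a single-addition ledger attributes it to individual
covariates. Significance uses an effective-number-of-tests Bonferroni
threshold: α divided by the number of principal components explaining >95%
of metabolite variance. Pathway scores are per-sample means of the z-scored
member metabolites (pathways with <5 members dropped); two-wave outcomes
also get residualized change scores.

**Network analysis** — metabolites are residualized on the Model-1
covariates; samples with standardized connectivity Z.k < −4 in the
sample–sample network are excluded; biweight midcorrelations between all
metabolite pairs are raised to a soft-thresholding power β (chosen as the
smallest power reaching a scale-free topology fit R² ≥ 0.85) in the signed
convention a<sub>ij</sub> = ((1 + cor<sub>ij</sub>)/2)<sup>β</sup>; the
adjacency is transformed into the topological overlap matrix
TOM<sub>ij</sub> = (Σ<sub>u</sub> a<sub>iu</sub>a<sub>uj</sub> + a<sub>ij</sub>) /
(min(k<sub>i</sub>, k<sub>j</sub>) + 1 − a<sub>ij</sub>), and 1 − TOM is
clustered by average linkage with a dynamic hybrid tree cut
(minModuleSize = 20, deepSplit = 4, mergeHeight = 0.25). Module eigenvalues
(first principal-component scores) act as predictors in the same model
series; kME is the metabolite–eigenvalue correlation, and hubs are
metabolites with own-module kME > 0.65 that are also significant in the
single-metabolite analyses. Pathway overrepresentation within modules uses
the upper-tail hypergeometric test at the 0.05/(number of modules)
threshold.

## Worked example

Simulate a 600-participant cohort with four planted modules (a direct
module → processing-speed effect of −0.3, and a module confounded with
childhood cognition), run QC, imputation and the network, then regress the
module eigenvalues across the model series:

```r
library(metacourse)
spec   <- cohort_spec(seed = 11)
cohort <- simulate_cohort(spec)

prep  <- run_preprocess(cohort$metabolome, max_missing = 0.20, k = 10)
stack <- mice_impute(cohort$covariates, m = 5, iters = 5, seed = 11)
eff   <- effective_tests(prep$matrix)

net <- build_network(prep$matrix, covariates = cohort$covariates, power = 9)
net
#> network_model: 205 metabolites, power 9, 4 modules (+41 grey)
#>   modules: turquoise(60) blue(45) brown(35) yellow(24)

kept <- rownames(net$metabolites$values)
mods <- run_model_series(net$eigenvalues,
                         cohort$outcomes[kept, c("PS_64", "STM_69")],
                         subset_stack(stack, kept),
                         models = 1:4, n_eff_tests = ncol(net$eigenvalues),
                         exclude_model1 = TRUE)

subset(mods, predictor == "turquoise" & outcome == "PS_64")
#>  model   beta ci_low ci_high        p       tier atten_pct
#>      1 -0.325 -0.401  -0.249 3.50e-16 bonferroni     0.000
#>      4 -0.328 -0.406  -0.249 1.35e-15 bonferroni     0.921

subset(mods, predictor == "blue" & outcome == "STM_69")
#>  model   beta  ci_low ci_high        p       tier atten_pct
#>      1 0.1880  0.1091   0.267 3.55e-06 bonferroni    0.0000
#>      3 0.0825 -0.0368   0.202 1.64e-01         ns  -56.1253
#>      4 0.0739 -0.0440   0.192 2.06e-01         ns  -60.6625
```

The turquoise module carries the planted direct effect: its coefficient
(−0.325, true value −0.3) survives full life-course adjustment essentially
unchanged. The blue module's association is purely confounded: adding
childhood cognition and social factors in Model 3 collapses it by 56%
to a non-significant 0.08. `effective_tests` reports 144 effective tests
here (threshold 3.47 × 10⁻⁴), and `run_pipeline()` strings all stages —
including enrichment, hub detection, the attenuation ledger and
sensitivity reruns — into a single reproducible report.

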