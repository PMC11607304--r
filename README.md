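# connlda

Latent disease factor modelling of functional connectomes in R.

Psychiatric diagnoses overlap: patients with different categorical
labels (autism spectrum, ADHD, OCD, subclinical anxiety) share symptoms
and share patterns of disturbed brain connectivity. Instead of assigning
each person to one class, `connlda` models every subject as a mixture of
a small number of **latent disease factors (LDFs)**. Each factor k has a
characteristic whole-brain connectivity profile Pr(FC | Factor k), and
each subject i expresses the factors with probabilities
Pr(Factor | Subject i) on the simplex. The package is aimed at
computational-psychiatry and connectomics researchers who have
ROI-level functional-connectivity data (or time series) plus item-level
clinical scores and want a tested, reproducible implementation of the
full analysis chain — including a synthetic-cohort generator so every
stage can be validated without access to restricted cohorts.

## The model

Given subjects' 128×128 (configurable) Pearson connectivity matrices,
each matrix is half-vectorized (E = R(R−1)/2 edges), w-scored against a
control reference (per-edge OLS on covariates; deviations in control-SD
units), clipped to ±3, and encoded as counts over a signed vocabulary:
edge *e* contributes `round(10·|z_e|)` tokens of `e+` (hyper-connected)
or `e−` (hypo-connected). Latent Dirichlet allocation is then fitted by
variational EM (full variational Bayes over the factor–word rows by
default):

- θ_i ~ Dirichlet(α) — subject i's factor expression,
- z ~ Mult(θ_i), w ~ Mult(β_z) — each connectivity token picks a factor
  and a signed edge word,
- β_k rows are the factor connectivity profiles; the reported signed
  profile is β_k(e+) − β_k(e−).

Downstream analyses: out-of-sample expression for unseen subjects
(variational inference with β fixed); bootstrap edge-wise profile
significance with Benjamini–Hochberg FDR; one CCA per (factor, clinical
scale) with site-aware permutation testing (for a scalar factor side the
first canonical correlation is the multiple correlation); group
comparisons (Wilcoxon rank-sum), pre/post treatment contrasts, Spearman
association of expression change with symptom remission; and the
individual-level Dice overlap 2|A∩B|/(|A|+|B|) between a subject's
top-10% strongest edges and a factor's significant profile.

## Worked example

```r
library(connlda)

# 1. plant a small world: 3 factors over a 16-region, 9-network parcellation
parc <- default_parcellation(16)
profiles <- generate_factor_profiles(K = 3, parc, seed = 11)
truth <- ground_truth(profiles, parc)
cohort <- sample_cohort(truth, n_subjects = 80, dirichlet_alpha = rep(1, 3),
                        noise_sd = 0.5, seed = 12)
controls <- sample_controls(100, parc, noise_sd = 0.5, seed = 13)

# 2. deviation-score against the control reference and count-encode
reference <- fit_reference(controls$deviations)
docs <- lapply(cohort$matrices, function(M)
  encode_counts(deviation_score(vectorize(M), NULL, reference)))
attr(docs, "vocabulary") <- edge_vocabulary(parc)

# 3. fit the factor model with bootstrap profile significance
ci <- bootstrap_profiles(docs, K = 3, B = 30, seed = 14,
                         alpha = 1, n_restarts = 4, max_iter = 200)
ci$model
#> factor_model: K = 3 factors over V = 240 signed edge words
#>   best restart 1/4, objective -505058.84 (converged)

# how well did we recover the planted profiles?
perm <- match_factors(profiles, ci$signed_profile)
round(sapply(1:3, function(k) cor(profiles[k, ], ci$signed_profile[perm[k], ])), 3)
#> [1] 0.911 0.912 0.919

# 4. factor expression vs item-level symptoms (factor 2 drives 'anxiety')
phen <- sample_phenotypes(cohort$loadings,
                          list(anxiety = list(n_items = 4, factor = 2,
                                              items = 1:2, effect = 2)),
                          noise_sd = 1, seed = 15, site = cohort$site)
res <- associate_factors(ci$expressions[, perm], phen,
                         attr(phen, "scales"), site = cohort$site,
                         n_perm = 999, seed = 16)
res$results
#>   factor   scale         r     p  n      q
#> 1      1 anxiety 0.3367776 0.057 80 0.0855
#> 2      2 anxiety 0.5272256 0.001 80 0.0030
#> 3      3 anxiety 0.3054768 0.140 80 0.1400

# 5. individual-level Dice overlap with the expressed factor profile
dev <- t(sapply(cohort$matrices, function(M)
  deviation_score(vectorize(M), NULL, reference)))
dice_tab <- dice_by_subject(dev, cohort$loadings, ci, fraction = 0.10)
head(dice_tab, 3)
#>   subject factor size_top size_profile size_intersection dice_pct
#> 1       1      1       12           30                 4 19.04762
#> 2       2      3       12           30                 3 14.28571
#> 3       3      2       12           27                 6 30.76923
```

Reading the output: the three estimated signed profiles correlate
0.91–0.92 with the planted ones after label matching; the CCA flags
exactly the planted (factor 2, anxiety) pair after FDR (r = 0.53,
permutation p = 0.001, q = 0.003) while the other pairs stay
non-significant; and each subject gets a Dice percentage quantifying how
much their strongest 10% of edge deviations overlap the significant
profile of their dominant factor.

A command-line interface wraps the same chain for on-disk cohorts
(delimited matrix files, phenotype CSV, parcellation TSV):

```sh
Rscript inst/cli/connlda.R simulate --config cfg.json --out run1
Rscript inst/cli/connlda.R fit      --config cfg.json --out run1
Rscript inst/cli/connlda.R report   --out run1
```

## Documentation

`vignettes/latent-disease-factors.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic world does and does not emulate, numerical conventions, and
the reasoning behind design decisions where the method description left
the choice open.
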