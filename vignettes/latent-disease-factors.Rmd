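---
title: "Latent disease factor modelling of functional connectomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent disease factor modelling of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`connlda` treats each subject's whole-brain functional connectome as a
*document* and decomposes a patient cohort into K latent disease factors
with latent Dirichlet allocation (LDA). Each factor k carries a
distribution over a signed edge vocabulary, Pr(FC | Factor) — its
connectivity profile — and each subject i carries a simplex vector
Pr(Factor | Subject), the factor expression. Generatively, for subject i
with expression θ_i ~ Dirichlet(α), every connectivity token chooses a
factor z ~ Multinomial(θ_i) and then a signed edge word w ~
Multinomial(β_z). A subject is thus a mixed-membership combination of
disease factors rather than a member of a single diagnostic class.

The observation fed to the model is not the raw correlation matrix. The
`connectome` module turns a subject's R×R Pearson matrix into counts in
four steps:

1. **Half-vectorization.** The strict upper triangle, row-major:
   (1,2), (1,3), …, (R−1,R); E = R(R−1)/2 edges.
2. **Reference normalization (w-scores).** Per edge, ordinary least
   squares of the edge value on control covariates (intercept-only when
   no covariates are supplied); a subject's deviation is
   (observed − predicted)/residual SD, in control-SD units.
3. **Clipping** to ±3 z (configurable) so single outlying edges cannot
   dominate a document.
4. **Sign-split count encoding.** Each edge contributes
   `round(scale·|z|)` tokens (scale = 10 by default) of the word
   `edge+` when hyper-connected and `edge-` when hypo-connected. The
   vocabulary has 2E words; at most one sign per edge is active in any
   document.

The encoding is the package's bridge between continuous connectivity
deviations and the nonnegative count likelihood LDA requires; scale and
clip are exposed in the configuration. A Fisher z-transform of the
correlations is available as a switch but off by default. The reported
signed profile of a factor is β(edge+) − β(edge−), which cancels the
symmetric "noise floor" mass that both sign words absorb.

## Inference

Fitting is by variational EM with a mean-field family per document
(Dirichlet over θ, independent responsibilities per token). Two
variants share all machinery and differ only in what documents see:

- `method = "vb"` (default): each factor-word row keeps a Dirichlet
  posterior λ_k (smoothing η) and documents see E[log β] (digamma
  weights). This is the better optimizer on hard corpora and the
  variant used throughout the pipeline; the reported β is the
  posterior mean.
- `method = "ml"`: a point β with the smoothed M-step
  β ∝ η + expected counts. Its per-document bound at the reported β
  is exactly the quantity certified against brute-force enumeration in
  the test suite.

Implementation choices that matter:

- **Initialization.** Each restart seeds every factor from three random
  documents plus jitter. Pure random initialization left restarts
  near-symmetric and produced unstable recoveries; document seeding
  anchors restarts at distinct corpus modes.
- **Partial E-steps.** After a cold-start pass, each EM iteration runs a
  single responsibilities/γ sweep per document with warm-started γ.
  Every sweep is coordinate ascent, so the recorded objective is
  monotone non-decreasing at a fraction of the cost of fully converged
  E-steps; convergence is declared on the relative change of the
  objective (tol, default 1e-5).
- **Restarts.** `n_restarts` (default 10) independent fits; the best
  final objective wins, ties to the lowest restart index.
- **Out-of-sample expression.** `infer_expression()` holds β fixed and
  starts from uniform responsibilities, so predictions for unseen
  subjects are deterministic given the model archive.
- **Expression estimate.** The normalized mean of the variational
  Dirichlet — always interior to the simplex, so near-zero loadings
  (e.g. 1e-6) are possible but exact zeros are not, matching how
  mixed-membership loadings behave in practice.

### Hyperparameters

| parameter | default | units / meaning |
|---|---|---|
| K | 4 | number of factors (pre-specified, as in the source design) |
| α | 50/K | Dirichlet prior on expressions; standard topic-model default |
| η | 0.01 | factor-word smoothing |
| scale | 10 | tokens per control-SD of deviation |
| clip | 3 | deviation cap (z units) |
| n_restarts / max_iter / tol | 10 / 500 / 1e-5 | optimization control |
| B | ≥ 20 (50 default) | bootstrap replicates for profile significance |
| n_perm | 10000 | permutations for the CCA test |
| fraction_top | 0.10 | subject-level top-edge fraction for Dice |

None of the model hyperparameters are stated in the source description;
all are exposed in the configuration and the defaults follow common
topic-modelling practice.

### The ELBO certificate and its limits

`elbo()` reports the converged per-document bound on
log p(docs | β, α) with β treated as a point. On tiny corpora the test
suite certifies it against exact log-evidence obtained by enumerating
all token-to-factor assignments (a Dirichlet-multinomial sum). The
certificate (bound ≤ exact) holds universally. The *tightness* of the
bound does not: for a maximally ambiguous document (e.g. two tokens of
different words under near-symmetric factors) the factorized family
cannot represent the correlation between tokens and the gap approaches
log K no matter how the bound is optimized — we verified this by
globally optimizing the per-document bound with hundreds of restarts.
The sub-half-nat tightness assertion in the acceptance suite therefore
lives where it is meaningful: on a well-separated, concentrated
two-topic corpus.

## Bootstrap profile significance

`bootstrap_profiles()` resamples subjects (the exchangeable unit) with
replacement, refits from scratch, and resolves label switching by
matching each replicate to the full-data fit with an exact linear
assignment over the factor-correlation matrix (Jonker–Volgenant; the
test suite checks it against brute-force enumeration over all K!
permutations). Per factor and edge, z = mean/SD of the signed profile
across replicates, two-sided normal p, Benjamini–Hochberg across all
K·E tests, mask at q < 0.05. Degenerate SD = 0 cells map to z = ±Inf
(p = 0) when the mean is nonzero and z = 0 otherwise.

## Association layer

One CCA per (factor, clinical scale) pair. Because the factor side is
one-dimensional, the first canonical pair *is* the multiple-correlation
solution: clinical weights are the regression of the loading on the
residualized items, r is the multiple correlation, and each item's
structural coefficient is its correlation with the fitted clinical
variate (oriented positively with the loading). Choices made where the
source is silent or ambiguous:

- **FDR family** = all tested (factor, scale) pairs.
- **Site handling**: sites are one-hot nuisance columns in
  residualization *and* exchangeability blocks in the permutation test
  (loadings are shuffled within site only); p = (1 + #{perm ≥ obs}) /
  (1 + n_perm). Sites with one subject stay fixed, with a warning.
- **Pre/post comparison** defaults to the two-sided Wilcoxon rank-sum
  on pre vs post — the source's literal procedure — with the
  conventional paired signed-rank available via
  `method = "signedrank"`; the wording and the convention disagree, so
  the default follows the wording and the flag documents the
  alternative rather than guessing intent.
- **MSE scale**: predicted loadings live on [0,1], clinical scores on
  arbitrary scales; `prediction_error()` min-max maps both to [0,1]
  before the MSE, making the number well-defined. This mapping is a
  package decision — the source never defines the quantity inside its
  MSE.
- **No CCA regularization**: p ≥ n errors out instead of silently
  shrinking.

## Individual-level Dice overlap

`dice()` is the cardinality form 2|A∩B|/(|A|+|B|), reported as a
percentage in output tables. Operand A is a subject's top-fraction edge
set — by default the 10% of edges with largest *absolute* deviation
(hyper and hypo both count, consistent with signed profiles; a
raw-positive mode exists). Operand B is the factor's
bootstrap-significant edge set. For treatment cohorts the altered-edge
set comes from per-edge paired t-tests with BH correction; per-patient
Dice can be computed against either the group-level altered set or
per-patient |post − pre| top-fraction sets (the source's operand is
ambiguous; both are exposed). Empty operands are an error — the
coefficient is undefined, not zero.

## The synthetic world

The generator stands in for the restricted discovery and validation
cohorts and emulates: (a) K sparse signed factor profiles organized into
within/between-network blocks over a 9-network, 128-region default
parcellation; (b) Dirichlet factor mixtures per subject; (c)
connectivity = mixture of profiles + i.i.d. Gaussian edge noise
relative to a control reference, clipped to (−0.999, 0.999); (d)
item-level symptoms linearly coupled to chosen factor loadings; (e)
site labels with optional shared per-edge offsets (default 0); (f)
pre/post treatment pairs in which one factor's expression drops by a
per-subject delta (floored at zero, row renormalized) and symptom
change tracks the *realized* decrease.

Stated-world values follow the source configuration where it gives one:
215 discovery patients, 173 controls, 128 regions, 9 networks, K = 4,
n = 27 treated patients, 10,000 permutations, top-10% Dice fraction,
FDR 0.05. Free parameters were fixed once, with reasons:

- **Profile support fraction 0.25.** Empirical factor profiles are
  broad (the source displays the top *half* of each profile's
  connections); narrow 10%-sparse profiles also leave planted cohorts
  with so little signal that factor recovery is information-limited for
  *any* implementation — we confirmed the ceiling with an independent
  reference LDA implementation on identical corpora before settling
  this value.
- **Nonzero magnitudes U(0.75, 2.25) deviation units**, i.e. roughly
  1.5–4.5 control SDs for a fully expressed factor at the default
  noise level — the regime of thresholded bootstrap-z profile maps in
  case–control connectomics.
- **Edge noise SD 0.5** (the recovery-benchmark value); note that
  after w-scoring the per-edge noise is ~N(0,1) by construction, so
  the informative quantity is the profile-to-noise ratio above.
- **Longitudinal defaults**: baseline loadings for treated cohorts use
  a moderately concentrated Dirichlet (patients co-express factors;
  surgical candidates express the treated factor substantially), mean
  delta 0.2, and symptom coupling to the realized decrease with noise
  SD 0.05.
- **A planted coupling for power tests** is sized analytically: 80%
  power of the p-predictor F-test at the BH-effective single-discovery
  level for the tested family, then converted to an item-level slope
  through the attenuation r = e·sd(loading)/sqrt(e²·var(loading)+σ²).

What a green suite establishes: the inference machinery recovers
structure it is told to plant, error rates are calibrated on worlds
that satisfy the model's assumptions, and every stage is deterministic
under a seed. What it does not establish: behaviour under real-data
violations — heteroscedastic and spatially correlated edge noise,
site-by-edge interactions, motion artifacts, non-Gaussian tails,
scanner differences — none of which the generator simulates, and no
claim about any real cohort.

## Numerical and degenerate-input conventions

- Vectorization order is fixed (row-major strict upper triangle,
  0-based internally, 1-based labeled output); round trips are exact.
- Ties in top-k selections (threshold_profile, top_fraction_edges)
  break by edge index; assignment ties in factor matching resolve to
  the lowest index.
- Zero-variance regions, empty documents, empty corpora, empty edge
  sets, constant vectors in min-max scaling, rank-deficient covariates
  and unidentifiable references are errors, not silent repairs.
- All generators and fitting paths derive per-stage seeds from one root
  seed (`derive_seed`), keeping every derived seed below 2^31.

## Known limitations

- The count encoding is a folded, clipped transform of Gaussian
  deviations; the fitted topics are consistent with the planted
  profiles only up to this nonlinearity, which is why recovery is
  asserted as correlation rather than equality.
- Variational EM finds local optima; restarts and document seeding
  mitigate but do not remove this, and the ELBO can prefer degenerate
  solutions under model mismatch.
- Bootstrap p-values assume approximate normality of the replicate
  signed-profile distribution.
- The CLI covers the simulate/fit/infer/associate/dice/report chain on
  delimited text files only; no neuroimaging formats are read.
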