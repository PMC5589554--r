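---
title: "Two-stage genetic risk score modelling with grspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage genetic risk score modelling with grspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grspipe)
```

## The problem

Common-disease susceptibility is spread over many variants of small
effect. A genetic risk score (GRS) aggregates them: for person $s$ with
risk-allele dosages $g_{si} \in \{0,1,2\}$ and per-SNP weights
$\beta_i \ge 0$,

$$\mathrm{GRS}_s = \sum_{i=1}^{k} \beta_i\, g_{si}.$$

`grspipe` implements the full two-stage workflow around this score for
case-control data: variant quality control, univariate screening,
LASSO-penalized selection of the weights in a training cohort, scoring,
quantile-based risk stratification, and discrimination/calibration
evaluation with the weights frozen in an independent validation cohort.
The packaged example panel is a 38-SNP lung-cancer score whose weights
span 0.0075–0.0535 per allele; on that scale a typical person's score
is near 1 (the analytic mean is $\sum_i 2 p_i \beta_i \approx 0.92$ at
the panel's risk-allele frequencies).

## Variant quality control

`apply_qc()` applies, in order:

1. **Imputation INFO** $\ge$ 0.8. INFO is consumed as an input column —
   the package never computes it, since imputation itself is out of
   scope.
2. **Control MAF** $\ge$ 0.05, computed as
   $\min(f, 1-f)$ with $f$ the effect-allele frequency among
   non-missing controls.
3. **Control HWE exact p** $\ge$ 0.05. The test is the exact
   conditional test: given the allele totals, the heterozygote count is
   compared against its exact conditional distribution, and the
   two-sided p-value sums the probabilities of all configurations no
   more probable than the observed one. The test choice was open; we
   use the exact test because it is the GWAS-QC standard and behaves
   correctly at low minor-allele counts, with the plain (non-mid)
   p-value as default and a chi-square variant behind the `method`
   flag. Probabilities are evaluated by the standard stable recurrence;
   the test suite checks it against brute-force enumeration for every
   genotype table up to $n = 50$.
4. **Windowed LD pruning**: variants are processed in ascending
   association p-value (ties broken by chromosome, position, rsid);
   a variant is dropped when it sits within 200 kb (same chromosome,
   both endpoints inclusive) of an already-kept variant with composite
   dosage $r^2 \ge 0.5$. This greedy order directly implements "keep
   only the most significant SNP of an LD cluster" and is
   deterministic. LD on unphased data is the squared Pearson
   correlation of dosages; monomorphic variants have undefined LD and
   never prune neighbours. Whether pruning should use in-sample or
   published p-values was open; both are supported (`assoc_p` is an
   argument) with in-sample as the pipeline default.

All thresholds live in `qc_thresholds()` and are fractions in $[0,1]$
(window in bp). The QC report records each variant's first failing rule
and per-stage survivor counts.

## Screening and LASSO selection

Step one of model building is a per-SNP additive logistic regression
(`assoc_scan()`); variants with Wald $p < 0.05$ (strict) survive
(`screen_assoc()`). The "univariate analysis" model form was open; we
use per-allele (additive) logistic regression, the convention of
standard GWAS tooling, with optional covariate adjustment. No
multiple-testing correction is applied at this stage — this mirrors
replication-based panel construction, where every candidate already has
prior evidence; it is a faithful design choice, not a general
recommendation.

Step two fits L1-penalized logistic regression over the screened SNPs
(`fit_lasso_logistic()`), minimizing

$$\frac1n \sum_i -\ell_i(\beta_0, \beta) + \lambda \lVert \beta \rVert_1$$

by proximal Newton with inner coordinate descent (compiled). The
intercept and any `penalty_mask`-exempt covariates are never shrunk.
Convergence is declared when the largest coefficient update falls below
$10^{-7}$; every fit satisfies the subgradient stationarity (KKT)
conditions — $|s_j| \le \lambda$ for zero coefficients,
$s_j = \lambda\,\mathrm{sign}(\beta_j)$ otherwise, with
$s_j = \frac1n \sum_i x_{ij}(y_i - p_i)$ — to $10^{-5}$, and the test
suite verifies this on every fit it produces, alongside equivalence
with an unpenalized IRLS fit at $\lambda = 0$ and with an accelerated
proximal-gradient oracle at fixed $\lambda$.

Predictors stay on the allele-count scale (not standardized) so that
each coefficient is a per-allele log-odds weight directly usable in the
GRS; a standardized mode is deliberately absent because back-transformed
weights are the only ones the score consumes. How $\lambda$ was chosen
in the original analysis is not stated; `select_lambda()` defaults to
10-fold stratified cross-validated deviance with the one-standard-error
rule (`cv_1se`), which favours the sparser model and is fully
reproducible given its `seed` (fold assignment is a pure function of
seed and sample order); `cv_min` and fixed-$\lambda$ modes are
available. The path is log-spaced from $\lambda_{\max}$ (the smallest
penalty that zeroes every penalized coefficient) down four decades.

## Scoring

`compute_grs()` computes the weighted sum exactly, in `weighted_sum`
mode. The published description of the score also mentions a rescaling
so that "one point corresponds to one risk allele"; taken literally
that multiplies the weighted sum by $k / \sum_i \beta_i$
(`allele_count_rescaled` mode). The two readings conflict with the
printed score distribution: score means near 1.0 with 38 SNPs are only
consistent with the raw weighted sum (whose analytic mean is
$\approx 0.92$), whereas the literal rescaling gives means near 38. We
therefore default to `weighted_sum` and provide the rescaled mode; the
two differ by a positive constant, so every rank-based quantity
(quartiles, AUC, high/low split) is identical under either.

Missing dosages are mean-imputed at $2f$ with $f$ the effect-allele
frequency (from the weight table when available, else the column mean);
a drop-sample policy exists. Weight rows absent from the genotypes are
a hard error unless explicitly allowed, in which case $k$ is
decremented with a warning.

The combined smoking + GRS score — whose construction was likewise
unstated — is the logistic linear predictor
$\hat\beta_{smoke}\,\mathrm{smoke} + \hat\beta_{GRS}\,\mathrm{GRS}$
from a `status ~ smoking + grs` fit, the minimal model-consistent
choice; the intercept is omitted as it is rank-invariant.

## Stratification

`quantile_categories()` cuts scores at type-7 (linear interpolation)
quantiles of the **controls** by default: published quartile tables
with near-equal control counts per category imply control-based cut
points, and the control distribution approximates the population under
case-control sampling of a rare disease. Intervals are
$[\text{lower}, \text{upper})$ with the top interval closed above, so a
score exactly at Q75 falls in the top category (matching "$\ge$ Q75"
labels); the same rule puts a score at the 90th-percentile cutoff into
the high-risk group. Crude per-category odds ratios are cross-product
ratios with Woolf CIs (Haldane–Anscombe 0.5 correction on zero cells,
flagged); adjusted ORs use indicator-coded logistic regression. The
trend test enters the category index 0–3 as a single linear term in
logistic regression (Wald p); a per-category median-score variant is
provided since the published choice is unstated. Published adjusted ORs
cannot be reproduced exactly because the adjustment covariate set is
unprinted; the printed counts and percentages can be, and are.

## Evaluation

The C-statistic is the Mann-Whitney concordance (ties count ½) computed
from ranks; its variance and the paired model comparison use per-sample
placement values (DeLong structural components), with normal intervals
truncated to $[0,1]$. The "nonparametric comparison" of two correlated
AUCs is implemented as this DeLong-style paired test — the standard
choice when the method reference is only cited, not described — and the
suite checks it against a 20,000-replicate paired sign-flip permutation
oracle at $n = 30$ as well as against an independent implementation.
Identical placements (e.g. a model compared with a monotone transform
of itself) give difference exactly 0 and a flagged $p = 1$.
Hosmer-Lemeshow uses 10 deciles of risk by default (group count
configurable), statistic
$\sum_g (O_g - E_g)^2 / (E_g(1 - E_g/n_g))$ on $\chi^2_{g-2}$; groups
with degenerate expected counts are merged with a warning, and with
fewer than 3 groups the p-value is defined only for a zero statistic.

`fit_risk_models()`/`evaluate_models()` assemble the three models and
report AUCs with CIs, each model's paired comparison against the
epidemiologic baseline, and calibration. The external-validation
contract is structural: `run_grs_pipeline()` fits weights on the
training cohort only and the testing stage consumes the frozen weight
table — rescoring the validation cohort with that table reproduces the
pipeline's scores bit for bit.

## The cohort simulator

`simulate_cohort()` emulates the study conditions end to end:
independent Hardy-Weinberg genotypes at specified risk-allele
frequencies (optionally grouped into LD blocks realized by a latent
haplotype pair copied with per-site mutation tuned to a target
composite $r^2$, with an explicit feasibility bound), a binary smoking
exposure, and disease from
$\mathrm{logit}\,P = \beta_0 + \sum_i \log(\mathrm{OR}_i) g_i +
\log(\mathrm{OR}_{smoke})\,\mathrm{smoke}$. The baseline $\beta_0$ is
solved numerically so the population prevalence equals the requested
value (default 1%, the rare-disease regime; the source analysis is
silent on prevalence). Case-control sampling is transparent rejection
sampling from the population model rather than an inversion of the
retrospective likelihood — slower but exactly faithful to the stated
generative model. Identical specs (including seed) give byte-identical
cohorts, and every cohort carries a truth record (spec, solved
baseline, realized frequencies, smoking rates).

Defaults are the published study conditions: 2,331/3,077 training and
1,937/1,984 testing cases/controls; control smoking prevalence 52.66%,
with the smoking OR solved from the published case rate
(76.85%) under the rare-disease approximation,
$\exp(\mathrm{logit}(0.7685) - \mathrm{logit}(0.5266)) \approx 2.98$;
per-SNP frequencies and per-allele ORs from the packaged panel. The
testing spec jitters the panel frequencies with a seeded Beta
(concentration 100) perturbation to stand in for a population of
different ancestry — it is a synthetic surrogate that enables transfer
tests, not a claim about any real cohort's frequencies.

What the simulator does **not** model: genome-wide LD structure,
population stratification, relatedness, genotyping or imputation
error, and any refinement of smoking beyond ever/never. Passing tests
on simulated cohorts therefore demonstrate correctness of the
statistical machinery under the stated generative model, not
performance on real data.

## Problem sizes and numerical choices

The test suite runs its recovery and calibration studies at the sizes
the methods are meant for while staying desk-sized: the full-pipeline
recovery study uses 20 simulated training cohorts at the published
2,331/3,077; type-I-error studies use 500–1,000 replicates at
$n = 400$–2,000; oracle equivalences run on exhaustive small spaces
(all HWE tables to $n = 50$, all-pairs AUC at $n = 500$). Convergence
tolerances: $10^{-7}$ coefficient change for the LASSO, KKT verified at
$10^{-5}$, exact-test ties compared with a $10^{-9}$ relative guard.
Seeds are explicit arguments everywhere randomness exists; derived
sub-seeds stay within 32-bit range.

At those published sizes the per-SNP screen has limited power for the
panel's weakest effects (per-allele ORs of 1.08–1.16 at intermediate
frequencies), so a typical simulated run screens in ~27–33 of the 38
panel SNPs and the cross-validated LASSO keeps nearly all survivors:
recovering the full panel would require either larger cohorts or the
original multi-study evidence base, which is exactly why the package
treats the panel weights as a shippable fixture rather than a quantity
to re-derive.

## Known limitations

- Adjusted odds ratios and trend p-values depend on an adjustment set
  that published tables often leave unprinted; only crude quantities
  are exactly reproducible from counts.
- The HWE exact test, LD pruning and scoring assume biallelic SNPs;
  multi-allelic records must be split upstream.
- Dosage-TSV input is assumed effect-allele oriented; only VCF input
  carries the allele metadata needed for automatic re-orientation.
- The DeLong comparison is asymptotic; for very small cohorts the
  permutation oracle in the test helpers is the safer reference.
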