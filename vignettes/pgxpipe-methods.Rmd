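---
title: "Methods: candidate-gene association analysis of composite fentanyl-response phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene association analysis of composite fentanyl-response phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pgxpipe implements a candidate-gene association pipeline for cancer-pain
patients treated with transdermal fentanyl, together with a synthetic
cohort generator that reproduces the statistical structure such an
analysis assumes. This vignette is the package's account of the methods:
the models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic data can and cannot show.

## Phenotypes

Four binary response phenotypes are derived from symptom instruments:

* **Pain control** — Brief Pain Inventory average pain (11-point numeric
  rating scale, 0–10) of 3 or less.
* **Cognitive dysfunction** — Mini-Mental State Examination total
  (0–30) of 23 or less, a cut-off with high specificity in cancer
  populations.
* **Sickness response** — at least two of: EORTC QLQ-C30
  nausea-and-vomiting scale ≥ 50 (0–100), tiredness item ≥ 3 (1–4),
  depression item ≥ 3 (1–4).
* **Opioid adverse-event complaint** — any of: nausea ≥ 50,
  constipation ≥ 50, tiredness ≥ 3, or MMSE ≤ 23.

Classification is strictly complete-case per outcome: a flag is missing
exactly when one of its required instrument fields is missing, even if an
observed field already satisfies an "any-of" criterion. This keeps the
analysable n per outcome explicit and reproducible. The depression item
feeds the sickness-response definition only; the adverse-event complaint
definition uses the four criteria listed above.

## Covariate transforms

Continuous clinical covariates are mapped to an approximately normal
scale before modelling through a fixed registry: age is squared (Box-Cox
$\lambda = 2$), BMI, time on opioids and serum fentanyl concentration are
log10-transformed, serum albumin uses $\lambda = 0.75$, creatinine
clearance $\lambda = 0.25$, and the Karnofsky performance score is
square-root transformed. The Box-Cox transform is
$(x^\lambda - 1)/\lambda$, with $\ln x$ at $\lambda = 0$.

`select_lambda()` maximises the profile log-likelihood of the normal
model on the transformed scale (with the Jacobian term
$(\lambda - 1)\sum \log x_i$) over a grid, by default $-3$ to $3$ in
steps of $0.01$ — fine enough to resolve registry values such as 0.75 and
0.25. Both modes are available: the fixed registry (the default in the
pipeline) and per-covariate re-estimation. Zeros in a covariate headed
for a log or Box-Cox transform are shifted up by half the smallest
positive observed value; the transform has no image at zero and the
half-minimum shift is the least informative repair.

## Genotype QC

Hardy-Weinberg equilibrium is tested per SNP by the 1-df Pearson
chi-squared test against expected proportions $(1-q)^2, 2q(1-q), q^2$ at
the estimated variant allele frequency, without continuity correction —
the standard choice for biallelic SNPs. Pairwise LD ($r^2$, $D'$) is
computed from haplotype frequencies estimated by an
expectation-maximisation algorithm over phase-ambiguous two-locus
genotypes; the same EM handles within-gene blocks of up to 8 SNPs and
returns maximum-posterior diplotypes (ties broken lexicographically).
The EM iterates until the log-likelihood changes by less than `tol`
(default 1e-8, maximum 200 iterations) and flags non-convergence rather
than failing. Genetic terms are coded per SNP as dominant (variant
carrier), recessive (homozygous variant), additive, genotypic (two
indicators, homozygous wild-type reference) or multilocus diplotype.

## Non-genetic screening (lasso)

Candidate non-genetic predictors are the clinical covariates
(registry-transformed, standardized; categorical covariates
indicator-coded) plus the product of each standardized covariate with
standardized log10 serum fentanyl concentration — first-order
concentration-response interactions only, not all pairwise interactions.
An L1-penalised regression (binomial, or gaussian for the continuous
delivery-rate mode) is fit over a regularisation path and the penalty is
chosen by 10-fold cross-validation with the one-standard-error rule,
which matches the small "major predictor" sets this screen is meant to
produce.

One design choice deserves a note. Fold assignment for the lasso CV is
*unstratified*. With outcome-stratified folds every fold carries nearly
the same event fraction, so the fold-level deviances of the null model
are almost identical, the estimated standard error of the CV curve
collapses, and the one-SE rule degenerates into the minimum rule — pure
noise designs then retain junk terms in a substantial fraction of runs.
With plain folds the screen is conservative: in our null simulations
(n = 500, 12 noise columns) it returns an empty set essentially always.
The price is power: effects of the size implied by the cognitive-
dysfunction odds ratios (about 0.3 per SD after transformation) are
individually detectable but jointly recovered only in a minority of
runs at n ≈ 470. Stratified folds remain the default everywhere else
(CVE, step-down selection), where they prevent degenerate single-class
training folds.

## Step-down genetic selection penalised by cross-validation error

With the screened non-genetic predictors fixed as the base model, all
candidate genetic codings of all SNPs enter a backward elimination:
repeatedly remove the genetic term whose removal most decreases
$\mathrm{deviance} + k \cdot \mathrm{df}$, stopping when no removal
decreases it. Degrees of freedom count *declared* coefficients, not
fitted rank: alternative codings of one SNP are exactly collinear, so a
redundant coding changes neither deviance nor rank, and only a
column-count penalty can eliminate it (this implements the rule that at
most one coding of a SNP survives).

The per-degree penalty $k$ is tuned by cross-validated prediction error
(CVE): for each $k$ in a grid (default 0 to 10 in steps of 0.1) the final
model is evaluated by repeated stratified k-fold cross-validation of the
Brier score — the mean squared difference between outcome and predicted
probability, with the model refit inside every training fold (CV mean
squared error in the gaussian mode). Defaults are 10 folds and 5
repeats; repeats push the Monte-Carlo noise of the CVE below the 0.001
resolution at which competing models differ. Folds are shared across all
evaluated models so CVE differences are paired. The model with minimal
CVE is returned, ties resolving toward larger $k$ (fewer terms), and the
base model always competes: genetic terms are only reported when their
model's CVE strictly beats the base model's. A training fold degenerate
to a single class is predicted by its shrunken prevalence
$(\sum y + 0.5)/(n + 1)$.

The Brier score was chosen as the CVE metric because the constant-
predictor closed form $p(1-p)$ reproduces the magnitudes this procedure
is expected to produce for base models at the observed prevalences
(e.g. $q = 210/430$ gives $0.2499$), while a misclassification error
could not.

**Selection bias and the permutation control.** Minimising CVE across
the stop-points of the elimination path is a multiple comparison: among
dozens of candidate models there is usually one whose spurious
within-dataset association also helps out-of-fold prediction *within the
same dataset*. Cross-validation cannot unmask an association that holds
across the whole dataset, so under a genetics-free simulation the
procedure still returns a "CVE-improving" genetic set in most runs, with
margins around 0.001–0.006. This is a property of the method, not an
implementation artefact (the margins are stable as CV repeats increase).
The permutation control below is therefore not an optional extra; it is
the stage that carries the family-wise error control, and the
chance-association rate of the raw step-down should be interpreted only
through it.

Effect estimation for the final model: adjusted odds ratios are
exponentiated coefficients with Wald 95% intervals; nested-model p-values
come from the likelihood-ratio test dropping the term; relative risks
use marginal standardisation — the ratio of mean predicted risk over all
subjects with the term set to exposed versus reference — with percentile
bootstrap intervals (default 200 resamples). Discrimination is the
rank-based (Mann-Whitney) area under the ROC curve, ties counted half.

## GMDR epistasis search

Non-genetic effects are absorbed into per-subject score residuals
$s_i = y_i - \hat p_i$ from the covariate-only logistic model (the
maximum-likelihood score identity centres them at zero). For each locus
combination and each of 10 CV splits, training subjects are pooled into
multilocus genotype cells; a cell is high-risk when its summed training
scores are positive (threshold 0, the convention for residual scores).
Weighted testing accuracy is the held-out score mass $\sum |s_i|$ in
cells whose label matches $\mathrm{sign}(s_i)$, divided by the held-out
mass in cells seen during training; empty test cells are excluded from
the denominator and counted in the report. Per order, the best
combination maximises mean testing accuracy; CV consistency counts the
splits in which it was also split-best. The default search covers orders
1–3 with 10-fold CV — the orders and fold count are conventions, as is
the accuracy weighting. A permutation null (scores shuffled against
genotype rows) calibrates the observed best accuracy with the add-one
empirical p-value $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(B + 1)$.

## Permutation control of the selection

To measure how often the full step-down procedure manufactures a model
by chance, the block of outcome *plus all non-genetic covariates* is
permuted as a unit against the genotype rows — outcome-covariate
relationships are preserved exactly, outcome-genotype links are broken —
and the entire selection (same penalty grid, fold counts and repeats;
folds re-drawn from each permutation's own seed stream to avoid
fold-leak artefacts) is rerun per permutation, recording the final-model
CVE. The observed model is judged `better_than_chance` when its CVE lies
below the 25th percentile of the null CVEs; an add-one empirical p-value
is reported alongside, since the qualitative quartile comparison has no
canonical cut-off. Default 200 permutations (50 in the test suite);
permutations are permuted per outcome with full re-selection — the
stricter of the possible readings. No family-wise correction is applied
across the four outcomes, which are reported separately.

A sobering property of this control is worth stating plainly. A single
candidate effect of the size planted in the default generator (carrier
odds ratio 0.38, nested chi-squared around 9) is comparable to the
*expected maximum* of the spurious association statistics across a
panel of a dozen or more candidate SNPs, so the observed CVE improvement
sits near the middle of the permutation-null improvement distribution:
in our simulations the verdict flags the planted effect in only a
minority of replicates. A candidate-gene finding of this magnitude that
does pass the control should therefore be read as sitting at the
boundary of what the design can distinguish from chance, and the control
should be expected to reject most single-SNP effects of this size.

## Synthetic cohort generator

The generator emulates the study conditions downstream stages assume:

* **Covariates** follow the published summary table: truncated normals
  matched to median ± SD and range for roughly symmetric covariates
  (age 64 ± 12 on 24–88; BMI 23 ± 5; albumin 33 ± 7), truncated
  log-normals for right-skewed ones (time on opioids 52 ± 272 days;
  serum fentanyl 5.6 ± 11.1 nM; creatinine clearance 84 ± 45 mL/min;
  patch delivery rate 50 ± 53 µg/h), category counts for sex, treatment
  country, C-reactive protein > 40 mg/L, breakthrough opioid use and the
  Karnofsky score (discrete 20–100 in tens). Covariates are drawn
  independently by default; an age-Karnofsky correlation can be
  configured but defaults to zero for testability.
* **Genotypes**: 31 SNPs in 19 innate-immune / opioid-signalling genes.
  Within-gene LD is generated by sampling haplotypes from block
  frequencies (per-SNP frequencies are then implied); independent SNPs
  follow Hardy-Weinberg sampling. The published per-SNP allele
  frequencies are not available in the text we work from, so the
  defaults are *plausible* values, not reproductions — with one
  calibrated exception: the MYD88 rs6853 variant frequency (0.137) is
  set so the carrier fraction is about 0.255, matching the carrier/
  non-carrier split of the cognitive-dysfunction contrast (111 of 436).
  ABCB1 enters with its three phenotype-associated tag SNPs; the
  reduction is a configurable SNP list, not hard-coded.
* **Outcomes** are binary latents from logistic models on
  registry-transformed covariates and genetic codings. Cognitive
  dysfunction uses the published adjusted odds ratios (squared age
  1.00037 per unit, square-root Karnofsky 0.63, rs6853 carrier 0.38)
  with the intercept calibrated by root-finding so the mean risk equals
  the target prevalence (81/438). Pain control (prevalence 210/430) has
  no systematic predictors. The sickness-response (148/418) and
  adverse-event (329/430) models use plausible effect sizes for their
  reported predictor sets, since no coefficients were published for
  them.
* **Instruments** are sampled conditional on the latents so the
  classifiers recover them exactly (e.g. MMSE uniform on 0–23 under the
  cognitive-dysfunction latent, 24–30 otherwise). Because a sickness
  response or cognitive dysfunction necessarily satisfies the
  adverse-event definition, the adverse-event latent is the union of its
  own model draw (calibrated on the unforced subset so the overall
  prevalence still matches) with those two. The four symptom indicators
  are drawn from their marginal rates conditioned exactly on the latent
  pattern by enumerating the 16 indicator combinations.
* **Missingness** is completely at random per field, at rates matched to
  the per-field analysable counts. Real instrument missingness
  co-occurs within questionnaires, so the joint complete-case n for
  multi-instrument outcomes (sickness response, adverse-event
  complaint) runs below the study's; per-field counts match.

What passing tests on this generator do **not** show: the generator
draws covariates independently, imposes exact HWE, makes missingness
ignorable and gives instruments no measurement error beyond the latent
model, so recovery results here bound what real data — with correlated
covariates, questionnaire-level missingness and baseline-versus-response
confounding inherent to a cross-sectional design — can be expected to
yield.

## Problem sizes used by the test suite

Simulation-based checks run at the sizes that make them informative:
distributional checks at n = 10,000; EM haplotype recovery at n = 2,000;
GMDR calibration and recovery at n = 1,000; selection power and
null-calibration suites at the study scale (n = 468, 12-SNP panel, 20–25
seeds) with 10-fold CV and 2 CV repeats; the permutation-control suite
uses 50 permutations per run, 5 CV folds and 2 repeats over 5 outer
seeds. The acceptance script reruns the pipeline end-to-end at n = 468
with the same reduced panel. Exhaustive oracle comparisons (Fisher,
HWE) cover all tables up to total 40 and 30 respectively.

## Known limitations

* The step-down stage alone over-selects by construction (see above);
  its output is only interpretable jointly with the permutation control.
* Diplotype groupings for multi-SNP genes are configuration-driven; no
  canonical grouping is shipped because none is defined in the source
  material available to us.
* The two-parameter (shifted) Box-Cox transform is out of scope; zeros
  are handled by the half-minimum shift.
* No imputation of instruments or genotypes; complete-case analysis
  throughout, per outcome.
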