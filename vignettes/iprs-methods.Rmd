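---
title: "Interaction-aware polygenic risk scores: models, simulators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-aware polygenic risk scores: models, simulators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A polygenic risk score (PRS) compresses a person's genotype at many trait-
associated variants into one number: a weighted sum of risk-allele counts,
with weights taken from per-variant association scans. When an environmental
exposure modifies genetic risk — smoking history and lung-cancer
susceptibility variants being the motivating example — the common practice is
to let the *whole score* interact with the exposure in a second-stage model.
That discards variant-level structure twice over. First, a variant whose
effect exists only in exposed individuals may never pass selection, because
its exposure-averaged (marginal) effect is diluted. Second, when some
variants interact antagonistically (interaction opposing the main effect) and
others synergistically, a single score-by-exposure product lets the two
cancel.

The interaction PRS (iPRS) implemented here keeps the variant-level
interaction structure. For individual $i$ with dosages $G_{ij}$ (counts of
the risk allele, 0/1/2) and binary exposure $E_i$:

$$\mathrm{PRS}_i = \sum_j \hat\beta^{M}_j G_{ij}, \qquad
  \mathrm{iPRS}_i = \sum_j \hat\beta^{M}_j G_{ij}
                  + \sum_j \hat\beta^{I}_j \, G_{ij} E_i .$$

For the traditional PRS, $\hat\beta^{M}_j$ is the marginal log-odds from a
per-variant logistic model without an interaction term. For the iPRS, both
weights come from the per-variant interaction model
$\operatorname{logit} P(y_i{=}1) = \alpha_j + \beta^M_j G_{ij} + \beta_E E_i
+ \beta^I_j G_{ij} E_i$: the main effect $\beta^M_j$ (the variant's effect in
unexposed individuals) and the interaction $\beta^I_j$. All variants are
flipped so that main-effect weights are non-negative ("risk allele"
orientation); the interaction weight is co-flipped. Flipping changes scores
only by a constant plus a term proportional to $E_i$, both of which the
second stage absorbs, so predictions are invariant — a property the test
suite asserts exactly.

Risk prediction uses second-stage logistic models refit on the constructed
covariates:

* PRS model: $\operatorname{logit} P(y{=}1) = b_0 + b_1\,\mathrm{PRS} +
  b_2\,\mathrm{PRS}\times E + b_3 E$
* iPRS model: $\operatorname{logit} P(y{=}1) = b_0 + b_1\,\mathrm{iPRS} +
  b_2 E$

The score definitions are written without free coefficients; we interpret
the prediction equations as logistic regressions with an intercept and
coefficients estimated on training data, which is the standard two-stage
practice and the only reading under which the models yield calibrated
probabilities. This is a deliberate design choice, recorded here rather than
asserted as the only possible reading.

## Pipeline and defaults

`iprs_fit()` runs the whole construction on one dataset: per-variant scans
(`genome_scan()`), optional selection, flipping, scoring and the second
stage. `cross_validate()` repeats it inside stratified k-fold training folds
(default $k=5$) so that test-fold samples never touch scan, selection or
weight estimation; `whole_sample_weights = TRUE` reproduces the alternative
reading in which stage-1 artifacts come from the full sample and only the
second stage is refit per fold.

Key defaults, with rationale:

* **Selection rule** (`select_variants()`): keep a variant iff
  $\min(p_{\text{main}}, p_{\text{interaction}}) < 5\times 10^{-6}$
  (`main_or_interaction`). The `main_only` rule is the traditional
  comparator; the difference between the two is precisely the class of
  variants with interactions but no main effect, and a property test checks
  that `main_or_interaction` recovers simulated interaction-only variants
  more often.
* **Wald tests** per coefficient (estimate over standard error, normal
  reference), the GWAS default; a test checks order-of-magnitude agreement
  with likelihood-ratio p-values at $n = 10{,}000$.
* **One selection shared by both models**: both scores are built on the same
  variant panel (selected from the interaction scan), with PRS weights taken
  from the marginal scan — this isolates the weighting scheme as the
  compared ingredient.
* **Missing dosages** are mean-imputed per variant at scoring and scan time;
  standard PRS practice, and it keeps every sample scoreable.
* **Non-converged fits** (separation, monomorphic dosage within an exposure
  stratum) are flagged and excluded from selection and weights, never
  imputed.
* **No multiple-testing correction** beyond the fixed threshold, and no LD
  pruning: synthetic genotypes here are independent, and "related SNP"
  removal has no well-defined rule to implement (QC covers exact duplicates
  by identifier or by chromosome/position/allele pair).

### Quality control

`qc_filter()` removes samples with genotype call rate below 95% first, then
variants with minor allele frequency below 0.01, exact Hardy-Weinberg
p-value below $10^{-6}$ (mid-p-free conditional test on the heterozygote
count, tested against a brute-force enumeration oracle to $10^{-12}$),
missingness above 5%, or duplication. HWE is tested on all retained samples
in a single pass. Each removed variant is tallied under the first rule it
fails, so rule counts sum to the total removed.

### Fast exact scans

With a binary exposure, complete integer dosages and no covariates, the
per-variant logistic likelihood depends on the data only through the
2 (exposure) x 2 (outcome) x 3 (dosage) count table. `genome_scan()` then
fits all variants simultaneously with vectorized Newton updates on these
sufficient statistics; the interaction model additionally factorizes into
two independent within-stratum fits whose estimates and Wald covariance
combine exactly. This is an exact reformulation, not an approximation — the
test suite asserts equality with `stats::glm` coefficient by coefficient —
and is what makes a 40,000-variant scan affordable on one CPU. Any
covariates, continuous exposure or missing dosages route the affected
variants through ordinary `glm`.

## Evaluation battery

`evaluate_predictions()` compares paired predictions from both models:

* **AUC** (Mann-Whitney, ties at 1/2) with **DeLong's test** for correlated
  AUCs (placement covariance; degenerate variance reported as $p = 1$ with a
  flag). Checked against a pair-enumeration oracle, `pROC::roc.test`, and a
  paired bootstrap.
* **Risk stratification** at the 5th and 95th percentiles of the predicted
  value (type-7 empirical quantiles; ties fall to the lower group), with
  group-wise prevalence and a Pearson chi-square on the 2-model x 3-group
  case counts. The chi-square treats the two models' counts as independent
  although they are computed on the same cohort; it is reported this way
  because that is how the comparison is printed in this literature, and the
  caveat travels with the output metadata.
* **Brier score** with a seeded 2,000-replicate percentile bootstrap CI;
  **calibration curves** on decile bins of the prediction (quantile bins
  rather than equal-width, so every point is supported by data);
  **Spiegelhalter's z**; **Cox recalibration slope and intercept** (logistic
  regression of the outcome on the logit of the prediction — slope 1,
  intercept 0 is perfect calibration, and refitting a model's own fitted
  values reproduces exactly that, a fixed point the tests assert).

## The simulators

The real cohort behind the motivating analysis is controlled-access, so the
package ships two generators that emulate its role; they are first-class,
tested code, and every acceptance quantity is computed from them.

**Sparse design** (`simulate_sparse()`): 10 independent SNPs with MAF drawn
once per dataset from $U(0.1, 0.5)$, dosages $\mathrm{Binomial}(2,
\mathrm{MAF})$, exposure $\mathrm{Bernoulli}(0.5)$. Six SNPs carry main
effects, four of those carry interactions (a flag allows interaction-only
SNPs instead, the supplementary variant of the design). Scenarios fix the
interaction signs: all antagonistic, all synergistic, or exactly half and
half. Outcomes follow the logistic model and individuals are drawn until
exactly 1,000 cases and 1,000 controls accumulate (quota sampling; the
sampler's composition is exact by construction and independent of the
intercept). Dosage generation reads the binomial-count law
$\mathrm{B}(2,\mathrm{MAF})$ as Binomial — a Beta draw cannot produce the
required 0/1/2 counts — and likewise $\mathrm{B}(1, 0.5)$ as Bernoulli for
the exposure.

Two quantities the design leaves open were fixed once, as follows:

* the intercept $\alpha = \operatorname{logit}(0.1)$, a 10% baseline
  prevalence typical of the motivating cohort, which keeps quota sampling
  fast;
* effect magnitudes $|\beta^M| = |\beta^I| = \beta_E = \log 1.5$, a
  moderate, realistic odds ratio for GWAS-scale effects. The exact published
  magnitudes live in supplementary material that is not bundled here, so
  reproductions using these canonical defaults are checked *qualitatively*
  (iPRS model at or above the PRS model in every scenario, largest gain
  under antagonism, synergistic > mixed > antagonistic ordering of absolute
  AUC) rather than against the printed scenario means.

**Polygenic design** (`simulate_polygenic()`): $m = 40{,}000$ synthetic
independent variants (MAF $\sim U(0.05, 0.5)$) for $n = 5{,}000$ samples —
a desk-scale stand-in for a real chromosome-wide panel — with 1% of variants
causal. Causal effects are drawn from $N(0, h^2/m_{\text{causal}})$ and
applied to standardized dosages, so the genetic linear predictor has
variance $h^2 = 0.3$ by construction (the "number of SNPs" in the variance
denominator is the causal count; with the total count the trait would be
essentially null, with genetic variance about $10^{-3}$). Of all variants,
0.1 per mille interact with the exposure (rounded to 4 here), 70%
antagonistically; interaction magnitudes are $|N(0, h^2/m_{\text{causal}})|$
with signs set by the antagonism rule, and $\beta_E = \log 1.5$. The truth
record stores everything needed to recompute each sample's outcome
probability exactly.

### Study evaluation modes, and why the polygenic default is a holdout split

`run_simulation_study()` chains generate, scan, (optionally select), flip,
score, fit and evaluate per replicate, with a per-replicate seed derived
from the master seed so any replicate reproduces in isolation and an
interrupted study can resume replicate by replicate.

The sparse design is evaluated **in-sample** by default: ten SNPs against
two thousand samples leave negligible optimism, and this matches a
single-dataset analysis. No p-value selection is applied — the ten SNPs
model a panel that GWAS has already delivered, false positives included.

The polygenic design cannot be evaluated in-sample: with per-variant weights
for 40,000 variants estimated on 5,000 outcomes, the score memorizes the
training labels (the weighted sum concentrates on the residual direction),
the second-stage logistic separates perfectly, and the fit degenerates. The
default is therefore a **discovery/target split**, the standard two-cohort
PRS design: stage-1 weights from a stratified half of each replicate, scores
for the held-out half, and the second stage fitted and all metrics computed
on that held-out half. Because the second stage (two or three coefficients)
is fitted on the evaluation half, its calibration metrics are
near-tautologically good; AUC and stratification, which drive the model
comparison, are honest out-of-sample quantities. Stratified k-fold
cross-validation is available for either design (`evaluation = "cv"`).

Under these conditions the polygenic study's out-of-sample AUCs are modest.
That is not an implementation artifact but an information-theoretic ceiling:
with the genetic linear predictor's variance fixed at $h^2 = 0.3$ on the
logit scale, even *true* weights give an AUC of about
$\Phi\!\big(\sqrt{h^2 + \beta_E^2/4}/\sqrt 2\big) \approx 0.65$, and
per-variant weights estimated from a few thousand samples recover only a
small fraction of that. Published full-scale figures far above this ceiling
can only arise when weight estimation and evaluation share samples, a regime
the package deliberately reports out-of-sample instead. The acceptance
script still reports the desk-scale means for both models, computed exactly
as described.

## Numerical choices

* Logistic fits: `stats::glm` (IRLS) or the exact count-table Newton solver
  described above (60 iterations max, step clamp at 4, parameters clamped to
  $\pm 30$, convergence at $10^{-11}$; non-convergence, separation and
  within-stratum monomorphism are flagged).
* Probabilities from `predict_risk()` are clamped to the open interval
  $(10^{-12}, 1-10^{-12})$ so downstream logits are finite.
* Quantiles: type 7 throughout (R's default), ties resolved toward the lower
  stratum deterministically.
* The DeLong variance uses sample covariances of placements with the usual
  $1/(m-1)$ normalization; a zero variance (identical prediction vectors) is
  reported as $p = 1$ with a degenerate flag instead of a division error.
* Randomness: every user-facing function takes a seed; nested draws use
  `derive_seed()` (a fixed affine map modulo $2^{31}-1$), and library code
  restores the caller's RNG state afterwards.
* Problem sizes used by the bundled checks: the statistical-property tests
  use up to 50,000 samples for single fits, 1,000 replicates for type-I
  error rates, 100 replicates per sparse scenario, and 20 polygenic
  replicates at $5{,}000 \times 40{,}000$ — sizes chosen so the full suite
  runs on a single CPU in well under half an hour.

## Known limitations

* Synthetic genotypes are LD-free and unstructured; nothing here models
  linkage, relatedness or population stratification, so passing tests say
  nothing about confounding-driven miscalibration on real cohorts.
* The generators produce binary exposures only (scoring and prediction
  accept continuous exposures).
* The prevalence chi-square ignores the pairing of the two models'
  stratifications, as discussed above.
* The "related SNP" QC notion is implemented only as exact duplication;
  LD-based pruning is out of scope.
* Genotype input is PLINK 1 binary only; no VCF, no dosage (imputed) formats.
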