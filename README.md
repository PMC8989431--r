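# iprs — interaction-aware polygenic risk scores

Polygenic risk scores (PRS) summarize a genotype into one number,
`PRS_i = Σ_j β^M_j G_ij`, where `G_ij` counts risk alleles and the weights
`β^M_j` are per-variant marginal log-odds from logistic association scans.
When an environmental exposure `E` (say, smoking history) modifies genetic
risk, common practice interacts the finished score with `E`. That loses
variant-level information: variants whose effect exists only in exposed
individuals can fail selection, and antagonistic and synergistic
interactions cancel inside a single score-by-exposure product.

This package implements the **interaction PRS (iPRS)**, which rebuilds the
score from a per-variant gene-environment (GxE) interaction scan:

```
iPRS_i = Σ_j β^M_j G_ij + Σ_j β^I_j G_ij E_i
```

with `β^M_j` the variant's main effect and `β^I_j` its interaction with the
exposure, estimated jointly per variant, all variants flipped to the
risk-allele orientation. Risk prediction then uses second-stage logistic
models, compared head to head:

* PRS model: `logit P(y=1) = b0 + b1·PRS + b2·PRS×E + b3·E`
* iPRS model: `logit P(y=1) = b0 + b1·iPRS + b2·E`

For whom: statistical geneticists and methodologists working on risk
prediction with GxE structure, who have PLINK 1 genotypes and a binary
outcome/exposure table, or who want the bundled simulators to study when
interaction-aware weighting helps.

What's inside:

* `read_plink()` / `write_plink()` — PLINK 1 bed/bim/fam IO (SNP-major).
* `qc_filter()` — call-rate, MAF, exact Hardy-Weinberg (`hwe_exact_test()`),
  missingness and duplicate filters with a tallied report.
* `genome_scan()`, `select_variants()` — per-variant marginal and
  interaction logistic scans (exact vectorized sufficient-statistic solver
  on the fast path) and fixed-threshold selection (`main_or_interaction`
  or `main_only`, default p < 5e-6).
* `compute_prs()`, `compute_iprs()`, `flip_to_risk()` — score construction.
* `iprs_fit()` — the end-to-end fitting function (scan → select → flip →
  score → second stage) returning a classed object with `predict`, `coef`,
  `summary`, `residuals` methods; `cross_validate()` — leakage-free
  stratified k-fold comparison of both models.
* `evaluate_predictions()` — AUC + DeLong test, 5/90/5 percentile risk
  stratification with a prevalence chi-square, Brier score with bootstrap
  CI, calibration curves, Spiegelhalter's z, Cox slope/intercept.
* `simulate_sparse()`, `simulate_polygenic()`, `synthesize_genotypes()`,
  `run_simulation_study()` — the two simulation designs (sparse 10-SNP
  quota-sampled case-control; polygenic 40k-variant cohort) and a seeded
  replicated study runner.
* An `iprs` command-line script (`simulate`, `fit-evaluate`, `study`) for
  shell pipelines; every run writes a manifest.

## Worked example

Simulate one sparse-design dataset (10 SNPs, 6 causal, 4 antagonistic
interactions, exactly 1,000 cases and 1,000 controls), cross-validate both
prediction models, and evaluate:

```r
library(iprs)
sim <- simulate_sparse(sparse_sim_config(scenario = "all_antagonistic", seed = 42))
cv  <- cross_validate(sim$genotypes, sim$y, sim$e, k = 5, seed = 1, select = FALSE)
summary(cv, seed = 1)
```

```
Evaluation on 2000 samples
  AUC  iPRS model: 0.6910   PRS model: 0.6786   (DeLong p = 0.02718)
  High-risk prevalence  iPRS: 84.00%   PRS: 79.00%   (chi2 p = 0.8791)
  Brier  iPRS: 0.2222 [0.2152, 0.2295]   PRS: 0.2253 [0.2184, 0.2322]
  Spiegelhalter z  iPRS: 1.508 (p=0.132)   PRS: 1.203 (p=0.229)
  Cox slope/intercept  iPRS: 0.900 / -0.00422   PRS: 0.910 / -0.00298
```

Reading the numbers: the iPRS model's out-of-fold AUC (0.691) beats the
traditional PRS model's (0.679), and DeLong's paired test puts p ≈ 0.027 on
that difference — under all-antagonistic interactions the marginal weights
of the PRS average risk over exposure strata and lose signal. The top-5%
group ranked by the iPRS model contains a higher disease prevalence (84%
vs 79%), its Brier score is lower, and both models are acceptably
calibrated (Spiegelhalter p > 0.05, Cox slope near 1, intercept near 0).

The same from the shell:

```sh
iprs simulate --out data/ --design sparse --scenario all_antagonistic --seed 42
iprs fit-evaluate --genotypes data/genotypes --pheno data/pheno.tsv \
    --out report/ --k-folds 5 --seed 1
```

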