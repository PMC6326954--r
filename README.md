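# relapseRF

Genomic prediction of relapse after allogeneic haematopoietic stem cell
transplantation (allo-HSCT), as a tested and reusable R pipeline.

## Who this is for, and what it does

Roughly 30% of allo-HSCT recipients relapse to their primary blood
malignancy. Individual germline variants rarely reach genome-wide
significance in transplant cohorts of realistic size, so this package
takes the predictive-modelling route instead: it asks whether the
recipient's SNP/INDEL genotypes, taken together, rank patients by relapse
risk better than chance, and which variants carry that signal. It is
aimed at statistical-genetics and transplant-immunology groups who want
the full analysis — QC through replication — as composable, unit-tested
functions rather than a one-off script.

The core procedure is **nested leave-one-out cross-validation**: for each
fold, a covariate-adjusted per-variant logistic association filter
(p < 0.001; likelihood-ratio test, Wald also reported) is run on the n−1
training samples *only*, a probability random forest is fitted on the
selected dosages, and the held-out sample is scored:

    logit P(relapse) = b0 + sum_j beta_j g_j + sum_c gamma_c x_c
    fold i:  filter({-i}) -> RF({-i}) -> score(i)

Out-of-fold scores are evaluated with the one-sided Mann–Whitney test
(AUC = U / (n1·n2)), percentile-bootstrap AUC confidence intervals, AUC
power at alpha = 0.01, and an odds-ratio-of-correct-prediction curve.
Variants are ranked by forest importance aggregated over folds and by an
Altmann-style label-permutation test on the full data; a fixed top-variant
list can then be evaluated on an independent replication panel (allele
matching with dosage flips, missing-genotype complete-case trade-off,
imputed-dosage SD filtering, fixed-set LOOCV).

Because the motivating study's patient genotypes are not publicly
deposited, the package ships a synthetic-cohort generator
(`simulate_cohort()`) with known causal structure — MAF spectrum, AR(1)
LD blocks, logistic genotype and covariate effects, duplicated samples
with GQ-dependent error, missingness, imputed dosages with per-call
uncertainty — so every stage is tested against ground truth.

## Worked example

```r
library(relapseRF)

cohort <- simulate_cohort(sim_config(
  n_samples = 150, n_variants = 1000, n_causal = 10, causal_beta = 1.5,
  maf_range = c(0.3, 0.3), prevalence_target = 0.31, seed = 42))

gm <- apply_quality_filter(cohort$genotypes, qc_config(gq_min = 0))
ps <- loocv_predict(gm, cohort$metadata,
                    cv_config(rf_n_trees = 300, base_seed = 7))
evaluate_predictions(ps, bootstrap_config(n_boot = 1000, seed = 7))
```

which prints

```
<eval_report> AUC 0.719 [0.629-0.807], one-sided MW p = 3.03e-06 (U = 3861.0), power(alpha=0.01) 0.992, n = 59/91
```

i.e. out-of-fold relapse scores separate relapsed from non-relapsed
samples with AUC 0.72 (bootstrap 95% CI 0.63–0.81), far beyond chance
(one-sided Mann–Whitney p = 3e-6), with 99% power to detect that AUC at
alpha 0.01 for these group sizes. The fold-aggregated importance table
shows what drove it:

```r
agg <- aggregate_loocv_importance(ps)
head(agg[order(-agg$selection_frequency), ], 5)
#   variant  loocv_importance selection_frequency
#  sv000173        0.051             1.00
#  sv000474        0.037             1.00
#  sv000615        0.070             1.00
#  sv000149        0.045             0.087
#  sv000314        0.021             0.020
```

`sv000173` and `sv000615` are planted causal variants; `sv000474` is a
linked proxy in the same LD block as a causal variant — exactly the
behaviour expected of a forest over correlated dosages. On null cohorts
(no effects) the same pipeline stays at AUC ≈ 0.5, and the shipped
negative control `loocv_predict_leaky()` (variant selection once on the
full data, the classic mistake) inflates null AUC to ≈ 0.77 — the
contrast that certifies the nesting is honest.

## Command line

```sh
./exec/relapseRF simulate --config cfg.json --out sim/ --seed 1
./exec/relapseRF qc --vcf sim/cohort.vcf --gq-min 18 --out qc
./exec/relapseRF screen --vcf sim/cohort.vcf --meta sim/metadata.tsv --out screen
./exec/relapseRF predict --vcf sim/cohort.vcf --meta sim/metadata.tsv --out pred --n-trees 1000
./exec/relapseRF evaluate --predictions pred_predictions.tsv --out eval
```

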