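# t1dnn — neural-network polygenic risk modelling and stratification for type 1 diabetes

`t1dnn` is an R package for building, evaluating and stratifying a
neural-network-driven polygenic risk classifier for type 1 diabetes (T1D)
on the compact 67-SNP GRS2 variant panel. It is aimed at statistical
geneticists and ML-for-genomics researchers who want a fully seeded,
testable implementation of the whole pipeline — from VCF to risk
categories — without access-restricted cohort data.

## What it computes

Subjects are represented by risk-allele dosages `d_sj ∈ {0,1,2}` over the
packaged panel of 67 GRCh37 variants with per-allele log-odds weights
`β_j`. The package provides:

* **Genotype ingestion** from VCF (GT or DS) or delimited dosage
  matrices, oriented to the panel risk alleles (indel `I`/`D` codes
  matched by allele length), with strict mismatch errors.
* **Hardy–Weinberg imputation** of missing genotypes from a
  prevalence-controlled reference subsample: expected dosage `2q`
  (default) or sampled from `((1−q)², 2q(1−q), q²)`; label-blind.
* **Encodings**: raw allele counts, or β-weighted counts `d_sj · β_j`.
* **Genotype entropy** `H = −Σ_i p_i log2(p_i)` (bits), where `p_i` is
  the reference frequency of the subject's genotype class at SNP *i*;
  global, per-chromosome, or combined feature configurations.
* **The classifier**: a feed-forward network 67 → 256 → 128 → 64 → 1
  (ReLU, dropout 0.40/0.30/0.20, sigmoid output, Glorot init, binary
  cross-entropy, batch 32, up to 1000 epochs with early stopping), grid
  search over {SGD, Adam} × {0.1, 0.01, 0.001} by stratified five-fold
  cross-validation, nested 1:1 ⊂ 1:2 ⊂ 1:3 control undersampling, and a
  20% held-out test set at a fixed 1:9 case:control ratio.
* **The linear benchmark**: the additive score `Σ_j β_j d_sj` with
  min-max normalisation.
* **Discrimination and stratification**: Mann–Whitney AUC with DeLong
  95% CIs; five risk categories (cuts 0.10/0.35/0.65/0.90); sensitivity,
  specificity and prevalence-adjusted predictive values via
  `PPV = se·π/(se·π+(1−sp)(1−π))`, `NPV = sp·(1−π)/(sp·(1−π)+(1−se)π)`.
* **A synthetic cohort generator**: HWE genotypes, logistic liability on
  the panel βs calibrated to a target prevalence, MCAR or whole-SNP
  missingness, and an attenuated-effect case subgroup emulating
  GADA-negative diabetes.

## Worked example

Simulate a 6,000-subject cohort at 10% prevalence with 1% missing
genotypes, train the default classifier (SGD, learning rate 0.001) on a
1:3 undersample, and stratify the held-out test set:

```r
library(t1dnn)

panel <- load_panel()
panel
#> <snp_panel> 67 variants (GRCh37), 18 chromosomes
#>   beta range: [-2.41, 2.08]

cohort <- simulate_cohort(n_subjects = 6000, panel = panel, seed = 11,
                          target_prevalence = 0.10, missing_rate = 0.01)
cohort
#> <synthetic_cohort> 6000 subjects (599 cases, 5401 controls), 67 SNPs

fit <- run_train(cohort$genotypes, cohort$subjects, ratio = "1:3",
                 encoding = "count", seed = 11)
fit$model
#> <risk_model> 67 features -> [256, 128, 64] -> 1; sgd lr=0.001; best epoch 439
fit$test_auc
#> AUC 0.9231 (95% CI 0.9018-0.9445)

rep <- run_stratify(fit$test_probabilities, fit$test$label,
                    prevalence = 0.10)
round(rep$category_distribution, 2)
#>              case control
#>   very_low   6.67   71.39
#>   low       12.50   15.74
#>   average   23.33    8.33
#>   high      51.67    4.44
#>   very_high  5.83    0.09
round(rep$metrics, 4)
#>    threshold sensitivity specificity    ppv    npv
#> t1      0.10      0.9333      0.7139 0.2660 0.9897
#> t2      0.35      0.8083      0.8713 0.4110 0.9761
#> 1       0.50      0.6917      0.9130 0.4689 0.9638
#> t3      0.65      0.5750      0.9546 0.5847 0.9529
#> t4      0.90      0.0583      0.9991 0.8750 0.9052
```

The test AUC (0.92) sits close to the AUC of the true generative linear
score on the same subjects — on additive synthetic data the linear score
is the Bayes-optimal classifier, so this gap is the package's accuracy
check. The category table reads as: 71% of controls but only 6.7% of
cases land in *very low* risk, giving the threshold-0.10 row its
sensitivity of 0.9333 = 1 − 0.0667 and NPV of 0.99 at 10% prevalence.
The linear GRS benchmark on the same test set:

```r
gm <- impute(cohort$genotypes, fit$reference)
rows <- match(fit$test$subject_id, gm$subject_ids)
gm_test <- genotype_matrix(gm$dosages[rows, ], panel,
                           subject_ids = fit$test$subject_id)
run_grs_benchmark(gm_test, fit$test$label, prevalence = 0.10)$auc
#> AUC 0.9546 (95% CI 0.9400-0.9692)
```

A command-line wrapper with `simulate` / `train` / `stratify` / `grs` /
`all` subcommands lives at `inst/cli/t1dnn-pipeline.R`.

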