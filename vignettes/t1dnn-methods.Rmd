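---
title: "Methods: neural-network polygenic risk modelling for type 1 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural-network polygenic risk modelling for type 1 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1dnn)
```

## The problem

Type 1 diabetes (T1D) has a strongly heritable, largely HLA-driven genetic
architecture that a compact panel of 67 SNPs (the GRS2 panel: rsID, risk
allele, per-allele log-odds weight β, GRCh37 coordinates) summarises well.
Classical genetic risk scores aggregate these variants linearly,
`GRS_s = Σ_j β_j d_sj`, where `d_sj ∈ {0,1,2}` counts risk alleles.
`t1dnn` implements the nonlinear alternative: a feed-forward neural
network trained on the same 67 dosages that outputs a per-subject
probability of T1D, together with everything around it — genotype
ingestion and orientation, Hardy–Weinberg (HWE) imputation,
genotype-entropy features, imbalance handling, DeLong confidence
intervals, the linear GRS benchmark, and a five-category risk
stratification framework with prevalence-adjusted predictive values.

Because the large case–control biobank cohorts this kind of model is
developed and validated on are access-restricted, the package ships a
synthetic cohort generator that reproduces the statistical structure the
analysis assumes, making every stage testable end to end.

## Genotype representation and encodings

Genotypes enter as risk-allele dosages aligned to the fixed panel order.
From VCF, orientation follows one rule: if an ALT allele equals the panel
risk allele the dosage is that ALT's count; if REF equals the risk allele
the dosage is `2 −` the non-reference count; indel codes `I`/`D` match the
longer/shorter of REF vs ALT; a biallelic record matching neither way is a
hard error naming the rsID. This convention is ours — array-to-panel
orientation is not otherwise pinned down — and it is checked by an
orientation-consistency property (flipping REF/ALT roles and
complementing dosages leaves the result unchanged).

Two encodings feed the classifier: `count` (raw 0/1/2) and
`beta_weighted` (`d × β` per column). Dosage-scale features are fed to
the network unstandardised: they are bounded (|β| ≤ 2.41, dosage ≤ 2) and
centring them buys nothing under Glorot-scaled first-layer weights.

## Missing genotypes: Hardy–Weinberg imputation

Missing entries (including whole panel SNPs absent from an external
genotyping platform) are filled from a *reference subsample* whose case
fraction is controlled at a stated prevalence (default 10%): all of the
scarcer class is kept and the other class undersampled (rounding down).
Per SNP the risk-allele frequency `q` is the mean observed dosage / 2 and
the genotype-class frequencies `(f0, f1, f2)` are empirical, floored at
`ε = 1e-6` and renormalised so the entropy logarithm below stays finite.

Two imputation modes are supported because the source methodology does
not say whether hard genotypes or expectations were filled:

* `expected` (default): the HWE expected dosage `2q`, deterministic,
  matching common GWAS practice; fractional dosages propagate into the
  encodings unchanged.
* `sampled`: a hard genotype drawn from `((1−q)², 2q(1−q), q²)` under a
  seed, for sensitivity analysis. Sampled fills are tested against HWE by
  χ² goodness of fit at 10,000 draws.

Imputation never consults labels. Inside `run_train` the reference is
built from the *training split only*, so neither imputation nor model
selection ever touches held-out genotypes; this makes the
"delete-the-test-set" invariance hold exactly rather than approximately.

## Genotype entropy

The per-subject descriptor
`H = − Σ_i p_i log2(p_i)` (bits) sums over panel SNPs the
reference-population frequency `p_i` of the genotype class the subject
carries at SNP *i* — an information measure of how unusual a genotype
profile is. Fractional (expected-imputed) dosages are mapped to the
nearest class for the lookup. Three feature configurations exist:
`global` (one column over all 67 SNPs), `per_chromosome` (one column per
panel chromosome; these sum exactly to the global value), and `combined`.
Entropy lives on a scale of tens of bits, far from the 0–2 dosage
features, so entropy columns are z-scored by default using training-set
statistics (stored and reusable on test cohorts); the source is silent on
this and the choice is purely optimizer conditioning. The module exists
to reproduce the exploratory experiments — entropy is *not* part of the
externally validated default model.

## The classifier and its training protocol

Architecture: input → 256 → 128 → 64 ReLU hidden layers with interleaved
dropout at rates 0.40 / 0.30 / 0.20 (the published schedule runs "40% to
20%"; the middle value is linear interpolation) → one sigmoid output.
Weights are Glorot-uniform initialised. Loss is binary cross-entropy
(computed in a numerically stable logit form); optimizers are SGD and
Adam with learning rates {0.1, 0.01, 0.001} on a grid searched by
stratified five-fold cross-validation scored by AUC, with a deterministic
tie-break (lower rate first, SGD before Adam). The documented default
configuration is SGD at 0.001. Batch size is fixed at 32 and the epoch
budget at 1000, with early stopping monitoring the loss on an internal
10% stratified validation split (patience 20 epochs, best weights
restored); the split size and patience are our dimensioning of an
undimensioned protocol, chosen so a full fit finishes in about a minute
at the cohort sizes below. Dropout uses inverted scaling, so prediction
is mask-free. Every stochastic step — initialisation, validation split,
shuffling, dropout, undersampling, train/test split — consumes an
explicit recorded seed, and a fitted model is bit-reproducible from the
seeds. The network is implemented directly on base-R matrix algebra
(BLAS); at 67 inputs and ≤256-unit layers a framework would add
dependencies, not speed.

Class imbalance is handled by nested control undersampling: all cases are
kept and controls are a prefix of one seeded permutation, so the 1:1
control set is contained in 1:2, which is contained in 1:3. The held-out
test set is 20% of subjects at a fixed 1:9 case:control ratio
(approximating a 10% screening prevalence) and is never used for fitting
or selection. A class-weighted loss is available but off by default (it
was evaluated and not adopted in the source methodology).

AUC is the Mann–Whitney probability that a random case outscores a random
control (mid-rank ties). The package computes it with a fast rank-based
routine for cross-validation loops; confidence intervals use DeLong's
nonparametric variance via pROC. Tests hold both against O(n²) pair
counting and a bootstrap (variance agreement within 25% at n = 200).

## Risk stratification

Probabilities map to five categories — very low, low, average, high, very
high — at cut points 0.10 / 0.35 / 0.65 / 0.90, left-closed (p equal to a
cut point falls in the higher category; a positive call at a threshold is
`p ≥ t`). This makes the category and threshold views cohere exactly:
sensitivity at 0.10 equals one minus the case fraction in very-low, and
specificity equals the control fraction there. Predictive values follow
the Bayes identities

```
PPV = se·π / (se·π + (1−sp)(1−π))
NPV = sp·(1−π) / (sp·(1−π) + (1−se)π)
```

at a *stated* prevalence π: 0.10 for screening-type evaluation, or the
observed case fraction for an enriched external cohort (e.g. 295/418 when
comparing GADA-positive cases with 123 controls) — predictive values are
prevalence-dependent and are always reported with the π used. The density
summary uses a Gaussian kernel with Scott-rule bandwidth on a 512-point
grid over [0, 1]; it is descriptive only.

The linear benchmark is the additive 67-SNP β score with min-max
normalisation over the evaluation cohort (out-of-cohort scores clipped to
[0, 1]). Normalisation is order-preserving, so benchmark AUCs are
normalisation-invariant; the HLA DR-DQ haplotype interaction terms of the
original GRS2 are deliberately out of scope — the benchmark is the
additive score on the same panel. One numerical caveat found in testing:
on coarse integer-dosage score distributions, min-max rescaling can
collapse nearly-equal raw values into exact floating-point ties, moving
AUC in the fourth decimal; comparisons should be made on one scale.

## The synthetic cohort generator

The generator emulates exactly the structure the analysis assumes:

* dosages `d_sj ~ Binomial(2, q_j)` (HWE, no LD), with `q_j` drawn once
  from Uniform(0.05, 0.95) under the seed, or supplied explicitly;
* a logistic liability `P(case) = sigmoid(α + γ_s c_s)` on the
  cohort-centred linear score `c_s = Σ_j β_j d_sj − mean_s(Σ_j β_j d_sj)`
  using the packaged panel βs, with `α` calibrated by bisection so the
  mean case probability hits the target prevalence (default 0.10) to
  1e-6. Centring matters: the uncentred panel score has a large positive
  mean, and scaling it by `γ < 1` would crush an attenuated subgroup's
  baseline risk toward zero instead of weakening its genotype–phenotype
  association. For a uniform `γ` the centring is only a
  reparametrisation of `α`;
* an attenuated subgroup: a seeded fraction of subjects (default choice
  0.2) has its genetic effect scaled by `γ` (0.3 in the acceptance
  runs), with *each effect stratum calibrated to the same target
  prevalence*. Equal stratum prevalences make attenuated cases about
  `subgroup_fraction` of all cases — the ~20% GADA-negative share of
  cases seen in the external cohort — while their weaker association
  mimics the lower discrimination of non-autoimmune diabetes. (A single
  shared intercept would instead let the high-variance full-effect
  stratum generate nearly all cases, leaving the subgroup comparison
  starved of data.);
* MCAR entry missingness at a configurable rate, or whole-SNP column
  masking (the "14 variants absent from the external platform" scenario).

What it does *not* model: linkage disequilibrium, population structure,
relatedness, HLA haplotypes or epistasis. Passing tests therefore show
that the pipeline recovers additive logistic signal faithfully and ranks
subgroups correctly — not that the network's nonlinear advantages on real
HLA architecture are reproduced. That is the right target here: on
additive ground truth the Bayes-optimal classifier is the true linear
score, so "network AUC within 0.03 of the true score's AUC" is a sharp
correctness check with a known optimum.

## Problem sizes and acceptance checks

The acceptance suite (also re-run by `scripts/acceptance.R`) uses cohorts
of n = 20,000 (≈2,000 cases) across 5 seeds for parameter recovery —
training on a 1:3 undersample (≈6,500 subjects) with the default
protocol takes roughly a minute per seed — and n = 10,000 with a 20%
attenuated subgroup for the ordering check. These sizes give stable AUC
estimates (test sets of ≈4,000 and ≈2,000 with 10% cases) while keeping
the whole suite in the minutes range on a single CPU. Closed-form checks
(Bayes predictive values from published sensitivity/specificity rows,
HWE triples, entropy sums, category/threshold coherence) run in
milliseconds and are exact to the stated precision.

## Known limitations

* HWE imputation is frequency-based; at immune loci under selection
  (HLA), HWE deviations make LD-aware imputation preferable — explicitly
  out of scope here.
* The benchmark omits GRS2's HLA interaction terms; real-data
  threshold-level GRS metrics are therefore not comparable cell-by-cell.
* No calibration analysis: probabilities are used as ranked scores and
  category assignments; formal calibration is future work.
* The generator's additive liability cannot demonstrate nonlinear gains;
  it validates machinery, not the scientific claim of epistasis capture.
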