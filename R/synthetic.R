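# Synthetic cohorts: Hardy-Weinberg genotypes at configurable allele
# frequencies, a logistic liability model on the panel beta weights with
# the intercept calibrated to a target prevalence, MCAR / whole-SNP
# missingness, and an attenuated-effect case subgroup emulating the
# weaker genetic signal of non-autoimmune (GADA-negative) diabetes.

#' Simulation configuration
#'
#' @param n_subjects cohort size.
#' @param panel a [load_panel()] panel supplying the beta weights.
#' @param allele_freqs per-SNP risk-allele frequencies; `NULL` (default)
#'   draws them once from Uniform(0.05, 0.95) under `seed`.
#' @param target_prevalence case fraction the liability intercept is
#'   calibrated to (default 0.10).
#' @param missing_rate MCAR entry-missingness rate in \[0, 1) (default 0).
#' @param subgroup_fraction fraction of subjects assigned to the
#'   attenuated-effect subgroup before labelling (default 0).
#' @param attenuation gamma in \[0, 1\] scaling the genetic effect for the
#'   attenuated subgroup (default 1 = no attenuation).
#' @param seed integer master seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_subjects, panel, allele_freqs = NULL,
                              target_prevalence = 0.10, missing_rate = 0,
                              subgroup_fraction = 0, attenuation = 1,
                              seed = 1L) {
  stopifnot(n_subjects >= 2,
            target_prevalence > 0, target_prevalence < 1,
            missing_rate >= 0, missing_rate < 1,
            subgroup_fraction >= 0, subgroup_fraction <= 1,
            attenuation >= 0, attenuation <= 1)
  if (is.null(allele_freqs)) {
    allele_freqs <- with_seed(seed, stats::runif(nrow(panel), 0.05, 0.95))
  }
  stopifnot(length(allele_freqs) == nrow(panel),
            all(allele_freqs > 0 & allele_freqs < 1))
  structure(list(n_subjects = as.integer(n_subjects), panel = panel,
                 allele_freqs = allele_freqs,
                 target_prevalence = target_prevalence,
                 missing_rate = missing_rate,
                 subgroup_fraction = subgroup_fraction,
                 attenuation = attenuation, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Sample Hardy-Weinberg genotypes
#'
#' Dosage at SNP j is Binomial(2, q_j), independent across SNPs and
#' subjects.
#'
#' @param config a [simulation_config()].
#' @return a [genotype_matrix()] with no missing entries.
#' @export
sample_genotypes <- function(config) {
  n <- config$n_subjects
  m <- nrow(config$panel)
  dos <- with_seed(config$seed, {
    matrix(stats::rbinom(n * m, 2L,
                         rep(config$allele_freqs, each = n)), n, m)
  })
  genotype_matrix(dos, config$panel,
                  subject_ids = sprintf("S%06d", seq_len(n)))
}

#' Calibrate the liability intercept to a target prevalence
#'
#' Finds `alpha` such that the mean over subjects of
#' `sigmoid(alpha + gamma_s * c_s)` equals the target prevalence, where
#' `c_s` is the cohort-centred linear score
#' `sum_j beta_j d_sj - mean_s(sum_j beta_j d_sj)`. Centring makes the
#' attenuation `gamma` shrink the genotype-phenotype *association* while
#' leaving the subgroup's baseline risk near the target, as intended for
#' emulating a weak-signal (GADA-negative-like) subgroup; for a uniform
#' `gamma` it is only a reparametrisation of `alpha`. The mean case
#' probability is strictly increasing in `alpha`, so the root is unique;
#' it is found by bisection to |prevalence error| < 1e-6.
#'
#' @param genotypes a [genotype_matrix()] (no missing entries).
#' @param panel panel supplying beta; defaults to the genotype panel.
#' @param target_prevalence target case fraction in (0, 1).
#' @param gamma per-subject effect attenuation (scalar or vector;
#'   default 1).
#' @return the intercept `alpha` (scalar).
#' @export
calibrate_intercept <- function(genotypes, panel = NULL,
                                target_prevalence = 0.10, gamma = 1) {
  panel <- panel %||% genotypes$panel
  stopifnot(target_prevalence > 0, target_prevalence < 1)
  base <- as.numeric(genotypes$dosages %*% panel$beta)
  score <- (base - mean(base)) * gamma
  calibrate_alpha(score, target_prevalence)
}

# bisection for mean(sigmoid(alpha + eff)) == target
calibrate_alpha <- function(eff, target) {
  f <- function(a) mean(sigmoid(a + eff)) - target
  lo <- -1; hi <- 1
  while (f(lo) > 0) lo <- lo * 2
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  alpha <- (lo + hi) / 2
  stopifnot(abs(f(alpha)) < 1e-6)
  alpha
}

#' Assign case/control labels under the logistic liability model
#'
#' Each subject is a case with probability
#' `sigmoid(alpha_g + gamma_s * c_s)`, where `c_s` is the cohort-centred
#' linear score (see [calibrate_intercept()]) and `alpha_g` the intercept
#' of the subject's stratum. A seeded random `subgroup_fraction` of
#' subjects carries the attenuated effect `gamma = attenuation` in its
#' generative probability; with each stratum calibrated to the same
#' target prevalence, attenuated cases make up about `subgroup_fraction`
#' of cases. Attenuated cases are tagged `attenuated` and full-effect
#' cases `full_effect` in the subgroup column (controls carry no tag).
#'
#' @param genotypes a [genotype_matrix()].
#' @param alpha calibrated intercept: a single value, or a named vector
#'   with elements `full_effect` and `attenuated` for per-stratum
#'   intercepts (see [simulate_cohort()]).
#' @param config a [simulation_config()].
#' @return list: `subjects` (a [subject_table()]), `true_score`
#'   (per-subject centred linear log-odds `gamma_s * c_s`),
#'   `case_probability`, `attenuated` (logical).
#' @export
assign_labels <- function(genotypes, alpha, config) {
  n <- nrow(genotypes$dosages)
  base_score <- as.numeric(genotypes$dosages %*% config$panel$beta)
  centred <- base_score - mean(base_score)
  with_seed(config$seed + 1L, {
    attenuated <- stats::runif(n) < config$subgroup_fraction
    gamma_s <- ifelse(attenuated, config$attenuation, 1)
    true_score <- gamma_s * centred
    alpha_s <- if (length(alpha) == 1) {
      rep(unname(alpha), n)
    } else {
      unname(alpha[ifelse(attenuated, "attenuated", "full_effect")])
    }
    p_case <- sigmoid(alpha_s + true_score)
    is_case <- stats::runif(n) < p_case
    subgroup <- rep(NA_character_, n)
    subgroup[is_case & attenuated] <- "attenuated"
    subgroup[is_case & !attenuated] <- "full_effect"
    list(subjects = subject_table(genotypes$subject_ids,
                                  ifelse(is_case, "case", "control"),
                                  subgroup = subgroup),
         true_score = true_score, case_probability = p_case,
         attenuated = attenuated)
  })
}

#' Inject missingness into a genotype matrix
#'
#' `random_entries` masks each entry independently at `missing_rate`
#' (missing completely at random); `whole_snps` masks `k_snps` entire
#' columns chosen at random, emulating panel variants absent from an
#' external genotyping platform. Labels are never consulted.
#'
#' @param genotypes a [genotype_matrix()].
#' @param missing_rate entry rate for `random_entries`.
#' @param pattern `"random_entries"` or `"whole_snps"`.
#' @param k_snps number of columns to mask under `whole_snps`.
#' @param seed integer seed.
#' @return a [genotype_matrix()] with the mask applied.
#' @export
inject_missingness <- function(genotypes, missing_rate = 0,
                               pattern = c("random_entries", "whole_snps"),
                               k_snps = NULL, seed = 1L) {
  pattern <- match.arg(pattern)
  dos <- genotypes$dosages
  if (pattern == "random_entries") {
    stopifnot(missing_rate >= 0, missing_rate < 1)
    if (missing_rate == 0) return(genotypes)
    mask <- with_seed(seed, {
      matrix(stats::runif(length(dos)) < missing_rate, nrow(dos), ncol(dos))
    })
  } else {
    stopifnot(!is.null(k_snps), k_snps >= 1, k_snps <= ncol(dos))
    cols <- with_seed(seed, sample.int(ncol(dos), k_snps))
    mask <- matrix(FALSE, nrow(dos), ncol(dos))
    mask[, cols] <- TRUE
  }
  dos[mask] <- NA_real_
  genotype_matrix(dos, genotypes$panel, subject_ids = genotypes$subject_ids)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: samples Hardy-Weinberg genotypes, calibrates the
#' liability intercept to the target prevalence (per effect stratum when
#' an attenuated subgroup is configured, so both strata carry the same
#' prevalence and attenuated cases form about `subgroup_fraction` of all
#' cases), assigns labels and subgroup tags, and optionally injects MCAR
#' missingness.
#'
#' @param n_subjects cohort size.
#' @param panel a [load_panel()] panel (default: the packaged 67-SNP
#'   panel).
#' @param seed master seed.
#' @param ... further arguments passed to [simulation_config()].
#' @return a `synthetic_cohort` list: `genotypes`, `subjects`,
#'   `true_score`, `alpha`, `config`.
#' @examples
#' cohort <- simulate_cohort(n_subjects = 200, seed = 42)
#' table(cohort$subjects$label)
#' @export
simulate_cohort <- function(n_subjects, panel = load_panel(), seed = 1L, ...) {
  config <- simulation_config(n_subjects = n_subjects, panel = panel,
                              seed = seed, ...)
  genotypes <- sample_genotypes(config)
  # same first draw as assign_labels, so strata match
  att <- with_seed(config$seed + 1L,
                   stats::runif(n_subjects) < config$subgroup_fraction)
  base <- as.numeric(genotypes$dosages %*% config$panel$beta)
  centred <- base - mean(base)
  alpha <- if (!any(att) || all(att)) {
    gamma <- if (all(att)) config$attenuation else 1
    calibrate_alpha(gamma * centred, config$target_prevalence)
  } else {
    c(full_effect = calibrate_alpha(centred[!att],
                                    config$target_prevalence),
      attenuated = calibrate_alpha(config$attenuation * centred[att],
                                   config$target_prevalence))
  }
  lab <- assign_labels(genotypes, alpha, config)
  if (config$missing_rate > 0) {
    genotypes <- inject_missingness(genotypes, config$missing_rate,
                                    "random_entries",
                                    seed = config$seed + 2L)
  }
  structure(list(genotypes = genotypes, subjects = lab$subjects,
                 true_score = lab$true_score, alpha = alpha,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$subjects$label)
  cat(sprintf(
    "<synthetic_cohort> %d subjects (%d cases, %d controls), %d SNPs\n",
    nrow(x$genotypes$dosages), tab["case"], tab["control"],
    ncol(x$genotypes$dosages)))
  invisible(x)
}
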