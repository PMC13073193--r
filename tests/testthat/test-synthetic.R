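test_that("sampled genotypes follow the configured allele frequencies", {
  panel <- tiny_panel(3)
  # frequencies must be strictly inside (0, 1)
  expect_error(simulation_config(100, panel, allele_freqs = c(0, 0.5, 0.5)))

  cfg <- simulation_config(10000, panel, allele_freqs = c(0.5, 0.1, 0.9),
                           seed = 2)
  gm <- sample_genotypes(cfg)
  expect_true(all(gm$dosages %in% 0:2))
  # binomial mean 2q with SE sqrt(2q(1-q)/n)
  expect_equal(mean(gm$dosages[, 1]), 1.0, tolerance = 0.03)
  expect_equal(mean(gm$dosages[, 2]), 0.2, tolerance = 0.03)

  counts <- tabulate(gm$dosages[, 1] + 1L, nbins = 3)
  gof <- suppressWarnings(chisq.test(counts, p = unname(hwe_genotype_probs(0.5))))
  expect_gt(gof$p.value, 0.01)
})

test_that("intercept calibration matches the closed form and a grid scan", {
  panel0 <- tiny_panel(3, betas = c(0, 0, 0))
  gm <- sample_genotypes(simulation_config(500, panel0, seed = 3))
  a <- calibrate_intercept(gm, panel0, target_prevalence = 0.10)
  expect_equal(a, log(0.10 / 0.90), tolerance = 1e-6)

  panel <- tiny_panel(3, betas = c(0.8, -0.5, 1.2))
  gm2 <- sample_genotypes(simulation_config(500, panel, seed = 4))
  a2 <- calibrate_intercept(gm2, panel, target_prevalence = 0.25)
  score <- as.numeric(gm2$dosages %*% panel$beta)
  score <- score - mean(score)  # the liability uses the centred score
  expect_equal(mean(1 / (1 + exp(-(a2 + score)))), 0.25, tolerance = 1e-6)

  # uniqueness: a dense grid scan lands on the same root
  grid <- seq(a2 - 1, a2 + 1, by = 1e-4)
  obj <- abs(vapply(grid, function(g) {
    mean(1 / (1 + exp(-(g + score)))) - 0.25
  }, numeric(1)))
  expect_lt(abs(grid[which.min(obj)] - a2), 1e-3)
})

test_that("empirical prevalence stays inside the binomial 99% interval", {
  cohort <- simulate_cohort(50000, panel = tiny_panel(5, betas = rep(0.3, 5)),
                            target_prevalence = 0.10, seed = 6)
  n_case <- sum(cohort$subjects$label == "case")
  ci <- qbinom(c(0.005, 0.995), 50000, 0.10)
  expect_gte(n_case, ci[1])
  expect_lte(n_case, ci[2])
  # the liability score is informative
  expect_gt(auc_mw(cohort$true_score, cohort$subjects$label), 0.5)
})

test_that("a fully attenuated subgroup carries no genetic signal", {
  panel <- tiny_panel(6, betas = rep(0.5, 6))
  cohort <- simulate_cohort(6000, panel = panel, target_prevalence = 0.3,
                            subgroup_fraction = 1, attenuation = 0, seed = 8)
  # gamma = 0: the generative probability ignores the genotype entirely
  base_score <- as.numeric(cohort$genotypes$dosages %*% panel$beta)
  y <- as.integer(cohort$subjects$label == "case")
  a <- auc_mw(base_score, y)
  se <- sqrt((1 / sum(y == 1) + 1 / sum(y == 0)) / 12)
  expect_lt(abs(a - 0.5), 3 * se)
  expect_true(all(cohort$subjects$subgroup[y == 1] == "attenuated"))
})

test_that("attenuated cases form about the configured share of cases", {
  cohort <- simulate_cohort(10000, panel = tiny_panel(8, betas = rep(0.4, 8)),
                            target_prevalence = 0.10,
                            subgroup_fraction = 0.2, attenuation = 0.3,
                            seed = 21)
  cases <- cohort$subjects[cohort$subjects$label == "case", ]
  share <- mean(cases$subgroup == "attenuated")
  expect_lt(abs(share - 0.2), 0.05)
  # both strata are calibrated to the same prevalence
  expect_lt(abs(sum(cohort$subjects$label == "case") / 10000 - 0.10), 0.02)
})

test_that("missingness injection hits the requested pattern", {
  panel <- tiny_panel(20)
  gm <- sample_genotypes(simulation_config(500, panel, seed = 9))

  expect_identical(inject_missingness(gm, 0, "random_entries"), gm)

  mcar <- inject_missingness(gm, 0.05, "random_entries", seed = 10)
  expect_lt(abs(mean(mcar$missing) - 0.05), 0.005)

  cols <- inject_missingness(gm, pattern = "whole_snps", k_snps = 14,
                             seed = 11)
  all_missing <- colSums(cols$missing) == nrow(cols$missing)
  expect_equal(sum(all_missing), 14L)
  expect_equal(sum(colSums(cols$missing) %in%
                     c(0L, nrow(cols$missing))), 20L)

  expect_error(inject_missingness(gm, pattern = "whole_snps", k_snps = 25))
})

test_that("simulated cohorts are reproducible under a seed", {
  c1 <- simulate_cohort(300, panel = tiny_panel(4), seed = 12)
  c2 <- simulate_cohort(300, panel = tiny_panel(4), seed = 12)
  expect_identical(c1$genotypes$dosages, c2$genotypes$dosages)
  expect_identical(c1$subjects$label, c2$subjects$label)
  expect_identical(c1$alpha, c2$alpha)
  c3 <- simulate_cohort(300, panel = tiny_panel(4), seed = 13)
  expect_false(identical(c1$genotypes$dosages, c3$genotypes$dosages))
})
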