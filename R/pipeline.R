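# Pipeline orchestration: end-to-end stages (simulate, train, stratify,
# GRS benchmark) that read/write the interchange formats and record a run
# manifest with every seed consumed. Each stage is a thin composition of
# the module functions; nothing is computed here that cannot be re-derived
# by calling them directly.

write_manifest <- function(path, stage, config, seeds, outputs) {
  manifest <- list(stage = stage, timestamp = format(Sys.time(), "%FT%T%z"),
                   config = config, seeds = seeds, outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a cohort to interchange files
#'
#' Dosage matrix as CSV (first column `subject_id`, then one column per
#' rsID with cells 0/1/2/NA) plus the subject table CSV — the formats
#' [read_genotypes()] and [read_subjects()] ingest.
#'
#' @param cohort a [simulate_cohort()] result (or a list with `genotypes`
#'   and `subjects`).
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno_path <- file.path(dir, "genotypes.csv")
  subj_path <- file.path(dir, "subjects.csv")
  dos <- cohort$genotypes$dosages
  out <- data.frame(subject_id = cohort$genotypes$subject_ids,
                    dos, check.names = FALSE)
  utils::write.csv(out, geno_path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  utils::write.csv(as.data.frame(cohort$subjects), subj_path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(c(genotypes = geno_path, subjects = subj_path))
}

#' Stage: simulate a cohort and write it to disk
#'
#' @param out_dir output directory.
#' @param n_subjects cohort size.
#' @param seed master seed.
#' @param panel panel (default: packaged 67-SNP panel).
#' @param ... further [simulation_config()] arguments.
#' @return (invisibly) a list with the cohort and the file paths.
#' @export
run_simulate <- function(out_dir, n_subjects, seed = 1L,
                         panel = load_panel(), ...) {
  cohort <- simulate_cohort(n_subjects = n_subjects, panel = panel,
                            seed = seed, ...)
  paths <- write_cohort(cohort, out_dir)
  write_manifest(file.path(out_dir, "manifest_simulate.json"), "simulate",
                 config = list(n_subjects = n_subjects,
                               target_prevalence = cohort$config$target_prevalence,
                               missing_rate = cohort$config$missing_rate,
                               subgroup_fraction = cohort$config$subgroup_fraction,
                               attenuation = cohort$config$attenuation,
                               alpha = cohort$alpha),
                 seeds = list(master = seed),
                 outputs = as.list(paths))
  invisible(list(cohort = cohort, paths = paths))
}

#' Stage: train the classifier on a cohort
#'
#' Builds the prevalence-controlled reference, imputes missing genotypes
#' under Hardy-Weinberg equilibrium, splits off a 1:9 test set (20%),
#' undersamples training controls at the requested ratio, encodes, and
#' either grid-searches (optimizer x learning rate) by stratified
#' five-fold cross-validation or fits the documented default
#' configuration (SGD, learning rate 0.001). Entropy features may be
#' appended in any of the three configurations.
#'
#' @param genotypes a [genotype_matrix()] (missing entries allowed).
#' @param subjects a [subject_table()].
#' @param ratio training case:control ratio (`"1:1"`, `"1:2"`, `"1:3"`,
#'   `"all"`).
#' @param encoding `"count"` or `"beta_weighted"`.
#' @param entropy `"none"`, `"global"`, `"per_chromosome"`, `"combined"`.
#' @param grid run the optimizer/learning-rate grid search (default
#'   `FALSE`: fit SGD lr 0.001 directly).
#' @param net,train network / training configuration.
#' @param reference_prevalence prevalence of the imputation reference
#'   subsample (default 0.10).
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir optional directory for the manifest and metric CSVs.
#' @return list: `model`, `test` (subject table), `test_probabilities`,
#'   `test_auc` (an `auc_estimate`), `cv` (a `cv_result` or `NULL`),
#'   `reference`, `encoder` (function mapping a genotype_matrix to
#'   features with training-set entropy scaling).
#' @export
run_train <- function(genotypes, subjects, ratio = "1:3",
                      encoding = "count", entropy = "none", grid = FALSE,
                      net = network_config(), train = train_config(),
                      reference_prevalence = 0.10, seed = 1L,
                      out_dir = NULL) {
  seeds <- list(reference = seed, split = seed + 1L, undersample = seed + 2L,
                folds = seed + 3L, fit = seed + 4L)
  split <- split_train_test(subjects, test_fraction = 0.20,
                            test_ratio = "1:9", seed = seeds$split)
  # reference frequencies come from the training split only, so neither
  # imputation nor model selection ever sees the held-out test genotypes
  tr_rows <- match(split$train$subject_id, genotypes$subject_ids)
  gm_train_pool <- genotype_matrix(
    genotypes$dosages[tr_rows, , drop = FALSE], genotypes$panel,
    subject_ids = split$train$subject_id)
  ref <- build_reference(gm_train_pool, split$train,
                         target_prevalence = reference_prevalence,
                         seed = seeds$reference)
  genotypes <- impute(genotypes, ref)
  train_subjects <- undersample(split$train, ratio, seed = seeds$undersample)

  encoder <- function(gm, scaling = NULL) {
    f <- encode(gm, encoding)
    if (entropy != "none") {
      f <- augment_features(f, gm, ref, configuration = entropy,
                            scaling = scaling)
    }
    f
  }
  subset_genotypes <- function(ids) {
    idx <- match(ids, genotypes$subject_ids)
    genotype_matrix(genotypes$dosages[idx, , drop = FALSE], genotypes$panel,
                    subject_ids = ids)
  }
  gm_tr <- subset_genotypes(train_subjects$subject_id)
  f_tr <- encoder(gm_tr)
  y_tr <- train_subjects$label

  net$seed <- seeds$fit
  train$seed <- seeds$fit
  cv <- NULL
  if (grid) {
    cv <- grid_search_cv(f_tr, y_tr, net = net, train = train,
                         seed = seeds$folds)
    train$optimizer <- cv$best$optimizer
    train$learning_rate <- cv$best$learning_rate
  }
  model <- fit_network(f_tr, y_tr, net = net, train = train)

  gm_te <- subset_genotypes(split$test$subject_id)
  f_te <- encoder(gm_te, scaling = attr(f_tr, "entropy_scaling"))
  p_te <- predict_proba(model, f_te)
  test_auc <- auc_with_delong_ci(p_te, split$test$label)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_manifest(file.path(out_dir, "manifest_train.json"), "train",
                   config = list(ratio = ratio, encoding = encoding,
                                 entropy = entropy, grid = grid,
                                 optimizer = train$optimizer,
                                 learning_rate = train$learning_rate,
                                 reference_prevalence = reference_prevalence),
                   seeds = seeds,
                   outputs = list())
    if (!is.null(cv)) {
      utils::write.csv(cv$table, file.path(out_dir, "cv_results.csv"),
                       row.names = FALSE)
    }
  }
  list(model = model, reference = ref, encoder = encoder,
       train_subjects = train_subjects, test = split$test,
       test_probabilities = p_te, test_auc = test_auc, cv = cv,
       entropy_scaling = attr(f_tr, "entropy_scaling"))
}

#' Stage: cross-validation summary across ratios and encodings
#'
#' Runs stratified five-fold cross-validation of the default
#' configuration for each requested (ratio, encoding) pair on the
#' training portion of a cohort, yielding the mean-AUC comparison table.
#'
#' @param genotypes,subjects cohort (missing genotypes allowed).
#' @param ratios character vector of ratios.
#' @param encodings character vector of encodings.
#' @param net,train configurations (the default protocol).
#' @param seed master seed.
#' @return data frame: ratio, encoding, per-fold AUCs, `cv_mauc`; the
#'   best row is flagged in column `best`.
#' @export
run_ratio_encoding_table <- function(genotypes, subjects,
                                     ratios = c("1:1", "1:2", "1:3", "all"),
                                     encodings = c("count", "beta_weighted"),
                                     net = network_config(),
                                     train = train_config(), seed = 1L) {
  split <- split_train_test(subjects, seed = seed + 1L)
  rows <- match(split$train$subject_id, genotypes$subject_ids)
  gm_pool <- genotype_matrix(genotypes$dosages[rows, , drop = FALSE],
                             genotypes$panel,
                             subject_ids = split$train$subject_id)
  ref <- build_reference(gm_pool, split$train, seed = seed)
  genotypes <- impute(genotypes, ref)
  rows <- list()
  for (ratio in ratios) {
    tr_sub <- undersample(split$train, ratio, seed = seed + 2L)
    idx <- match(tr_sub$subject_id, genotypes$subject_ids)
    gm <- genotype_matrix(genotypes$dosages[idx, , drop = FALSE],
                          genotypes$panel, subject_ids = tr_sub$subject_id)
    for (enc in encodings) {
      f <- encode(gm, enc)
      y <- as_binary_labels(tr_sub$label)
      fold <- stratified_folds(y, 5L, seed = seed + 3L)
      net$seed <- train$seed <- seed + 4L
      aucs <- vapply(1:5, function(k) {
        m <- fit_network(f[fold != k, , drop = FALSE], y[fold != k],
                         net = net, train = train)
        auc_mw(predict_proba(m, f[fold == k, , drop = FALSE]), y[fold == k])
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(ratio = ratio, encoding = enc,
                   t(stats::setNames(aucs, paste0("fold", 1:5))),
                   cv_mauc = mean(aucs))
    }
  }
  out <- do.call(rbind, rows)
  out$best <- out$cv_mauc == max(out$cv_mauc)
  out
}

#' Stage: risk stratification report
#'
#' Converts predicted probabilities into the five-category framework:
#' per-group category distribution, threshold metrics with
#' prevalence-adjusted predictive values, and a density summary.
#'
#' @param probabilities predicted probabilities.
#' @param labels case/control (or 0/1) labels.
#' @param groups optional grouping for the distribution table (defaults
#'   to the labels).
#' @param prevalence prevalence for PPV/NPV (default 0.10).
#' @param thresholds a [risk_thresholds()].
#' @param out_dir optional directory for CSV/JSON output.
#' @return list: `category_distribution`, `metrics`, `auc`
#'   (an `auc_estimate`), `density`.
#' @export
run_stratify <- function(probabilities, labels, groups = NULL,
                         prevalence = 0.10,
                         thresholds = risk_thresholds(), out_dir = NULL) {
  stopifnot(prevalence > 0, prevalence < 1)
  groups <- groups %||% as.character(labels)
  dist <- category_distribution(probabilities, groups, thresholds)
  mets <- metrics_table(probabilities, labels,
                        thresholds = sort(c(unclass(thresholds), 0.5)),
                        prevalence = prevalence)
  est <- auc_with_delong_ci(probabilities, labels)
  dens <- distribution_summary(probabilities, groups)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(dist),
                     file.path(out_dir, "category_distribution.csv"))
    utils::write.csv(mets, file.path(out_dir, "threshold_metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(thresholds = unclass(thresholds), prevalence = prevalence,
           auc = est$auc, ci = c(est$ci_low, est$ci_high),
           n = length(probabilities)),
      file.path(out_dir, "stratification_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(category_distribution = dist, metrics = mets, auc = est,
       density = dens)
}

#' Stage: linear GRS benchmark
#'
#' Computes the min-max-normalised beta-weighted score on a cohort and
#' evaluates it with the same threshold metrics used for the classifier.
#'
#' @param genotypes imputed [genotype_matrix()].
#' @param labels case/control labels aligned to the genotype subjects.
#' @param prevalence prevalence for PPV/NPV.
#' @param thresholds a [risk_thresholds()].
#' @param out_dir optional directory for the metrics CSV.
#' @return list: `grs` (scores), `metrics`, `auc` (an `auc_estimate`).
#' @export
run_grs_benchmark <- function(genotypes, labels, prevalence = 0.10,
                              thresholds = risk_thresholds(),
                              out_dir = NULL) {
  grs <- normalize_scores(compute_grs(genotypes))
  mets <- metrics_table(grs$normalized, labels,
                        thresholds = sort(c(unclass(thresholds), 0.5)),
                        prevalence = prevalence)
  est <- auc_with_delong_ci(grs$normalized, labels)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(mets, file.path(out_dir, "grs_metrics.csv"),
                     row.names = FALSE)
  }
  list(grs = grs, metrics = mets, auc = est)
}
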