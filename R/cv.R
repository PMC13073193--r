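# Cohort handling for imbalanced case-control learning: nested control
# undersampling, the 80/20 train/test split with a fixed 1:9 test ratio,
# stratified five-fold cross-validation, and the optimizer x learning-rate
# grid search.

#' Undersample controls to a target case:control ratio
#'
#' All cases are retained; controls are drawn without replacement from one
#' seeded permutation, taking a prefix of length `k * n_cases` for ratio
#' `1:k`. Because every ratio takes a prefix of the same permutation, the
#' control sets are nested: the 1:1 controls are contained in the 1:2 set,
#' which is contained in the 1:3 set. Auxiliary controls are excluded.
#'
#' @param subjects a [subject_table()].
#' @param ratio `"1:1"`, `"1:2"`, `"1:3"`, or `"all"` (no undersampling).
#' @param seed integer seed for the control permutation.
#' @return the undersampled `subject_table` (cases first, then controls).
#' @export
undersample <- function(subjects, ratio = c("1:1", "1:2", "1:3", "all"),
                        seed = 1L) {
  ratio <- match.arg(ratio)
  cc <- subjects[subjects$label %in% c("case", "control"), , drop = FALSE]
  cases <- cc[cc$label == "case", , drop = FALSE]
  controls <- cc[cc$label == "control", , drop = FALSE]
  if (ratio == "all") {
    out <- rbind(cases, controls)
    class(out) <- class(subjects)
    return(out)
  }
  k <- as.integer(sub("^1:", "", ratio))
  n_want <- k * nrow(cases)
  if (n_want > nrow(controls)) {
    max_k <- nrow(controls) %/% max(nrow(cases), 1L)
    stop(sprintf(
      "insufficient controls for ratio 1:%d (%d needed, %d available; maximum achievable ratio 1:%d)",
      k, n_want, nrow(controls), max_k), call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(nrow(controls)))
  out <- rbind(cases, controls[perm[seq_len(n_want)], , drop = FALSE])
  rownames(out) <- NULL
  class(out) <- class(subjects)
  out
}

#' Split a cohort into training and test sets
#'
#' Holds out `test_fraction` of the case/control subjects as a test set
#' with a fixed case:control ratio (default 1:9, matching a ~10% disease
#' prevalence); all remaining subjects form the training set. The test set
#' is never used for fitting or model selection.
#'
#' @param subjects a [subject_table()].
#' @param test_fraction fraction of subjects held out (default 0.20).
#' @param test_ratio case:control ratio of the test set as `"1:k"`
#'   (default `"1:9"`).
#' @param seed integer seed.
#' @return list with `subject_table` elements `train` and `test`.
#' @export
split_train_test <- function(subjects, test_fraction = 0.20,
                             test_ratio = "1:9", seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  k <- as.integer(sub("^1:", "", test_ratio))
  cc <- subjects[subjects$label %in% c("case", "control"), , drop = FALSE]
  n_test <- round(test_fraction * nrow(cc))
  n_test_case <- round(n_test / (k + 1))
  n_test_ctrl <- n_test - n_test_case
  cases <- which(cc$label == "case")
  controls <- which(cc$label == "control")
  if (n_test_case < 1 || n_test_ctrl < 1 ||
      n_test_case >= length(cases) || n_test_ctrl >= length(controls)) {
    stop(sprintf(
      "cannot form a %s test set of %d subjects from %d cases and %d controls",
      test_ratio, n_test, length(cases), length(controls)), call. = FALSE)
  }
  test_idx <- with_seed(seed, {
    c(sample(cases, n_test_case), sample(controls, n_test_ctrl))
  })
  test <- cc[sort(test_idx), , drop = FALSE]
  train <- cc[-sort(test_idx), , drop = FALSE]
  rownames(test) <- rownames(train) <- NULL
  class(test) <- class(train) <- class(subjects)
  list(train = train, test = test)
}

# k stratified folds; returns integer fold id per observation.
stratified_folds <- function(y, k = 5L, seed = 1L) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Grid search with stratified five-fold cross-validation
#'
#' Evaluates every optimizer x learning-rate combination by stratified
#' k-fold cross-validation on the supplied (training) data, scoring each
#' fold by AUC on its held-out part. The best configuration is the one
#' with the highest mean AUC; ties break deterministically toward the
#' lower learning rate, then SGD before Adam.
#'
#' @param features numeric matrix (subjects x features).
#' @param labels 0/1 or case/control labels.
#' @param optimizers candidate optimizers (default `c("sgd", "adam")`).
#' @param learning_rates candidate rates (default `c(0.1, 0.01, 0.001)`).
#' @param net a [network_config()].
#' @param train a [train_config()] supplying the non-grid settings.
#' @param k number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @return a `cv_result` list: `table` (one row per configuration with
#'   per-fold and mean AUC), `best` (optimizer, learning_rate, mean_auc),
#'   `fold_ids`.
#' @export
grid_search_cv <- function(features, labels,
                           optimizers = c("sgd", "adam"),
                           learning_rates = c(0.1, 0.01, 0.001),
                           net = network_config(), train = train_config(),
                           k = 5L, seed = 1L) {
  X <- as.matrix(unclass(features))
  y <- as_binary_labels(labels)
  fold <- stratified_folds(y, k = k, seed = seed)
  if (any(tapply(y, fold, function(v) length(unique(v))) < 2)) {
    stop("degenerate fold with a single class; provide more subjects",
         call. = FALSE)
  }
  grid <- expand.grid(optimizer = optimizers, learning_rate = learning_rates,
                      stringsAsFactors = FALSE)
  auc_mat <- matrix(NA_real_, nrow(grid), k)
  for (g in seq_len(nrow(grid))) {
    cfg <- train
    cfg$optimizer <- grid$optimizer[g]
    cfg$learning_rate <- grid$learning_rate[g]
    for (f in seq_len(k)) {
      tr <- fold != f
      model <- fit_network(X[tr, , drop = FALSE], y[tr], net = net,
                           train = cfg)
      p <- predict_proba(model, X[!tr, , drop = FALSE])
      auc_mat[g, f] <- auc_mw(p, y[!tr])
    }
  }
  tab <- cbind(grid, auc_mat, mean_auc = rowMeans(auc_mat))
  names(tab)[2 + seq_len(k)] <- paste0("fold", seq_len(k))
  # deterministic tie-break: higher mean AUC, then lower learning rate,
  # then sgd before adam
  ord <- order(-tab$mean_auc, tab$learning_rate,
               match(tab$optimizer, c("sgd", "adam")))
  best <- tab[ord[1], ]
  structure(list(table = tab,
                 best = list(optimizer = best$optimizer,
                             learning_rate = best$learning_rate,
                             mean_auc = best$mean_auc,
                             fold_aucs = as.numeric(best[paste0("fold",
                                                                seq_len(k))])),
                 fold_ids = fold),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d configurations; best: %s lr=%g (mean AUC %.4f)\n",
              nrow(x$table), x$best$optimizer, x$best$learning_rate,
              x$best$mean_auc))
  invisible(x)
}
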