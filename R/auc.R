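# Discrimination metrics: Mann-Whitney AUC (fast rank form, used inside
# cross-validation loops) and DeLong 95% confidence intervals via pROC.

#' Mann-Whitney AUC
#'
#' The probability that a random case outscores a random control, with
#' ties counted one half — computed from mid-ranks in O(n log n).
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels 0/1 or case/control labels.
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a DeLong 95% confidence interval
#'
#' Computes the Mann-Whitney AUC together with the nonparametric DeLong
#' variance and a normal-approximation 95% interval (clipped to
#' \[0, 1\]), delegating the interval to `pROC`.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels 0/1 or case/control labels.
#' @param conf_level confidence level (default 0.95).
#' @return an `auc_estimate` list: `auc`, `ci_low`, `ci_high`, `se`.
#' @export
auc_with_delong_ci <- function(scores, labels, conf_level = 0.95) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  roc <- pROC::roc(response = y, predictor = as.numeric(scores),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- pROC::ci.auc(roc, conf.level = conf_level, method = "delong")
  v <- pROC::var(roc, method = "delong")
  structure(list(auc = as.numeric(pROC::auc(roc)),
                 ci_low = max(0, as.numeric(ci[1])),
                 ci_high = min(1, as.numeric(ci[3])),
                 se = sqrt(as.numeric(v))),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.4f (95%% CI %.4f-%.4f)\n", x$auc, x$ci_low, x$ci_high))
  invisible(x)
}
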