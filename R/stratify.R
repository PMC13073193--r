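# Risk stratification: the five-category probability framework
# (thresholds 0.10 / 0.35 / 0.65 / 0.90), threshold sensitivity and
# specificity, prevalence-adjusted predictive values via Bayes'
# identities, and per-group category distributions.

RISK_CATEGORIES <- c("very_low", "low", "average", "high", "very_high")

#' Risk category thresholds
#'
#' @param cuts four increasing cut points in (0, 1); default
#'   `c(0.10, 0.35, 0.65, 0.90)`.
#' @return a `risk_thresholds` object (named numeric vector).
#' @export
risk_thresholds <- function(cuts = c(0.10, 0.35, 0.65, 0.90)) {
  stopifnot(length(cuts) == 4, all(diff(cuts) > 0), cuts[1] > 0, cuts[4] < 1)
  structure(cuts, names = c("t1", "t2", "t3", "t4"),
            class = "risk_thresholds")
}

#' Assign probabilities to risk categories
#'
#' `very_low` for `p < t1`, `low` for `t1 <= p < t2`, `average` for
#' `t2 <= p < t3`, `high` for `t3 <= p < t4`, `very_high` for `p >= t4`
#' (intervals are closed on the left, so a probability equal to a cut
#' point falls in the higher category).
#'
#' @param p probabilities in \[0, 1\] (vectorised).
#' @param thresholds a [risk_thresholds()].
#' @return factor with levels `very_low`, `low`, `average`, `high`,
#'   `very_high`.
#' @examples
#' categorize(c(0, 0.10, 0.5, 0.95))
#' @export
categorize <- function(p, thresholds = risk_thresholds()) {
  assert_prob(p, "p")
  cut(p, breaks = c(-Inf, unclass(thresholds), Inf), right = FALSE,
      labels = RISK_CATEGORIES)
}

#' Sensitivity and specificity at a probability threshold
#'
#' A subject is called positive iff `p >= threshold`. Sensitivity is the
#' called-positive fraction of cases; specificity the called-negative
#' fraction of controls.
#'
#' @param probabilities predicted probabilities.
#' @param labels 0/1 or case/control labels.
#' @param threshold decision threshold.
#' @return named numeric vector `(sensitivity, specificity)`.
#' @export
threshold_metrics <- function(probabilities, labels, threshold) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  pos <- probabilities >= threshold
  c(sensitivity = mean(pos[y == 1]), specificity = mean(!pos[y == 0]))
}

#' Prevalence-adjusted predictive values
#'
#' Bayes' identities:
#' `PPV = se * prev / (se * prev + (1 - sp) * (1 - prev))` and
#' `NPV = sp * (1 - prev) / (sp * (1 - prev) + (1 - se) * prev)`.
#'
#' @param sensitivity,specificity,prevalence values in \[0, 1\].
#' @return named numeric vector `(ppv, npv)`.
#' @examples
#' predictive_values(0.9450, 0.5454, 0.10)  # ppv 0.1876, npv 0.9889
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  sensitivity <- unname(sensitivity)
  specificity <- unname(specificity)
  prevalence <- unname(prevalence)
  assert_prob(sensitivity); assert_prob(specificity); assert_prob(prevalence)
  ppv_den <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  npv_den <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  if (any(ppv_den == 0)) stop("PPV undefined: zero denominator", call. = FALSE)
  if (any(npv_den == 0)) stop("NPV undefined: zero denominator", call. = FALSE)
  c(ppv = sensitivity * prevalence / ppv_den,
    npv = specificity * (1 - prevalence) / npv_den)
}

#' Metrics table across the framework thresholds
#'
#' Sensitivity, specificity, PPV and NPV at each supplied threshold
#' (default: the four category cuts plus the conventional 0.5), with
#' predictive values computed at a stated prevalence.
#'
#' @param probabilities predicted probabilities.
#' @param labels 0/1 or case/control labels.
#' @param thresholds numeric thresholds (default
#'   `c(0.10, 0.35, 0.50, 0.65, 0.90)`).
#' @param prevalence prevalence used for PPV/NPV (default 0.10).
#' @return data frame with one row per threshold.
#' @export
metrics_table <- function(probabilities, labels,
                          thresholds = c(0.10, 0.35, 0.50, 0.65, 0.90),
                          prevalence = 0.10) {
  rows <- lapply(thresholds, function(t) {
    m <- threshold_metrics(probabilities, labels, t)
    pv <- predictive_values(m["sensitivity"], m["specificity"], prevalence)
    data.frame(threshold = t, sensitivity = unname(m["sensitivity"]),
               specificity = unname(m["specificity"]),
               ppv = unname(pv["ppv"]), npv = unname(pv["npv"]))
  })
  out <- do.call(rbind, rows)
  attr(out, "prevalence") <- prevalence
  out
}

#' Category distribution by group
#'
#' Percentage of each group's subjects in each of the five risk
#' categories; every group column sums to 100.
#'
#' @param probabilities predicted probabilities.
#' @param groups character vector assigning each subject to one group.
#' @param thresholds a [risk_thresholds()].
#' @return matrix (5 categories x groups) of percentages.
#' @export
category_distribution <- function(probabilities, groups,
                                  thresholds = risk_thresholds()) {
  stopifnot(length(probabilities) == length(groups))
  cats <- categorize(probabilities, thresholds)
  keep <- !is.na(groups)
  if (!all(keep)) {
    warning("subjects with missing group omitted", call. = FALSE)
  }
  tab <- table(cats[keep], groups[keep])
  empty <- colSums(tab) == 0
  if (any(empty)) {
    warning("empty group(s) omitted: ",
            paste(colnames(tab)[empty], collapse = ", "), call. = FALSE)
    tab <- tab[, !empty, drop = FALSE]
  }
  100 * sweep(unclass(tab), 2, colSums(tab), `/`)
}

#' Numeric density summary of predicted probabilities per group
#'
#' A Gaussian kernel density estimate (Scott-rule bandwidth) on a fixed
#' 512-point grid over \[0, 1\], plus quantiles, per group — the numeric
#' counterpart of the usual probability-distribution plots. Groups with
#' fewer than two subjects get quantiles only.
#'
#' @param probabilities predicted probabilities.
#' @param groups character vector assigning each subject to one group.
#' @return named list per group with elements `x` (grid), `y` (density,
#'   `NULL` if n < 2), `quantiles`, `n`.
#' @export
distribution_summary <- function(probabilities, groups) {
  grid <- seq(0, 1, length.out = 512)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  out <- lapply(split(probabilities, groups), function(p) {
    dens <- if (length(p) >= 2) {
      d <- stats::density(p, bw = "nrd", from = 0, to = 1, n = 512)
      d$y
    } else {
      NULL
    }
    list(x = grid, y = dens, quantiles = stats::quantile(p, qs), n = length(p))
  })
  out
}
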