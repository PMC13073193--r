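# Feature encoding: risk-allele count (0/1/2) or beta-weighted count
# (0, beta, 2*beta per column). Both operate on fully imputed genotypes.

#' Encode genotypes as model features
#'
#' Two encodings are supported: `count` passes risk-allele dosages through
#' unchanged, and `beta_weighted` multiplies each column by its panel beta
#' coefficient. Genotypes must be fully imputed first (see [impute()]).
#'
#' @param genotypes a [genotype_matrix()] with no missing entries.
#' @param scheme `"count"` or `"beta_weighted"`.
#' @return a `feature_matrix`: numeric subjects x variants matrix with
#'   attributes `encoding` and `panel`.
#' @examples
#' panel <- load_panel()
#' cohort <- simulate_cohort(n_subjects = 20, panel = panel, seed = 1)
#' f <- encode(cohort$genotypes, "beta_weighted")
#' @export
encode <- function(genotypes, scheme = c("count", "beta_weighted")) {
  scheme <- match.arg(scheme)
  if (any(genotypes$missing)) {
    stop("genotypes contain missing entries; run impute() before encoding",
         call. = FALSE)
  }
  values <- genotypes$dosages
  if (scheme == "beta_weighted") {
    values <- sweep(values, 2, genotypes$panel$beta, `*`)
  }
  feature_matrix(values, encoding = scheme, panel = genotypes$panel)
}

feature_matrix <- function(values, encoding, panel = NULL) {
  values <- as.matrix(values)
  structure(values, encoding = encoding, panel = panel,
            class = c("feature_matrix", class(values)))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d features (%s encoding)\n",
              nrow(x), ncol(x), attr(x, "encoding")))
  invisible(x)
}
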