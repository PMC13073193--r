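# Linear genetic risk score: the additive beta-weighted 67-SNP score used
# as the benchmark against the neural network, with min-max normalisation
# over a stated cohort.

#' Compute the linear beta-weighted genetic risk score
#'
#' Per subject, the sum over panel SNPs of `beta_j * dosage_j` (a
#' log-odds-scale quantity). Genotypes must be fully imputed.
#'
#' @param genotypes a [genotype_matrix()] with no missing entries.
#' @param panel optional panel; defaults to the panel carried by
#'   `genotypes`.
#' @return a `grs_result` data frame with columns `subject_id` and `raw`.
#' @examples
#' panel <- load_panel()
#' cohort <- simulate_cohort(n_subjects = 50, panel = panel, seed = 7)
#' grs <- compute_grs(cohort$genotypes)
#' @export
compute_grs <- function(genotypes, panel = NULL) {
  panel <- panel %||% genotypes$panel
  if (any(genotypes$missing)) {
    stop("genotypes contain missing entries; run impute() first",
         call. = FALSE)
  }
  raw <- as.numeric(genotypes$dosages %*% panel$beta)
  out <- data.frame(subject_id = genotypes$subject_ids, raw = raw,
                    stringsAsFactors = FALSE)
  class(out) <- c("grs_result", "data.frame")
  out
}

#' Min-max normalise genetic risk scores
#'
#' Rescales raw scores to \[0, 1\] using the minimum and maximum over a
#' stated cohort; subjects outside the cohort range are clipped to
#' \[0, 1\]. Normalisation is strictly monotone, so rank order and AUC are
#' unchanged.
#'
#' @param grs a [compute_grs()] result.
#' @param cohort optional character vector of subject IDs defining the
#'   normalisation cohort; defaults to all subjects in `grs`.
#' @return the `grs_result` with a `normalized` column added.
#' @export
normalize_scores <- function(grs, cohort = NULL) {
  cohort <- cohort %||% grs$subject_id
  in_cohort <- grs$subject_id %in% cohort
  if (!any(in_cohort)) stop("normalisation cohort is empty", call. = FALSE)
  rng <- range(grs$raw[in_cohort])
  if (diff(rng) == 0) {
    stop("degenerate normalisation: cohort scores are constant",
         call. = FALSE)
  }
  grs$normalized <- pmin(pmax((grs$raw - rng[1]) / diff(rng), 0), 1)
  grs
}
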