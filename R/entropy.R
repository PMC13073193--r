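# Genotype-entropy features: per-subject Shannon information of the
# observed genotype profile relative to reference-population genotype
# frequencies, H = -sum_i p_i log2(p_i) in bits, where p_i is the
# reference frequency of the subject's genotype class at SNP i.

#' Per-subject genotype entropy
#'
#' For one subject, sums `-p_i * log2(p_i)` over panel SNPs (or a subset),
#' where `p_i` is the reference-population frequency of the genotype class
#' the subject carries at SNP i. Subjects carrying rare genotypes score
#' higher, reflecting deviation from population norms. Real-valued
#' (expected-imputed) dosages are mapped to the nearest genotype class for
#' the frequency lookup.
#'
#' @param dosages numeric vector of one subject's dosages, panel order, no
#'   missing values.
#' @param ref a [build_reference()] table (frequencies floored, so no
#'   zero-probability classes).
#' @param panel the panel the dosages are aligned to.
#' @param snp_subset optional character vector of rsIDs restricting the sum.
#' @return entropy in bits (non-negative scalar).
#' @examples
#' panel <- load_panel()
#' ref <- data.frame(rsid = panel$rsid, q = 0.5, f0 = 0.25, f1 = 0.5, f2 = 0.25)
#' subject_entropy(rep(1, 67), ref, panel)  # 67 * (-0.5 * log2(0.5)) = 33.5
#' @export
subject_entropy <- function(dosages, ref, panel, snp_subset = NULL) {
  if (anyNA(dosages)) {
    stop("dosages contain missing values; impute first", call. = FALSE)
  }
  rsids <- panel$rsid
  if (!is.null(snp_subset)) {
    keep <- rsids %in% snp_subset
    if (!any(keep)) return(0)
    dosages <- dosages[keep]
    rsids <- rsids[keep]
  }
  ridx <- match(rsids, ref$rsid)
  if (anyNA(ridx)) {
    stop("reference frequencies missing for: ",
         paste(rsids[is.na(ridx)], collapse = ", "), call. = FALSE)
  }
  cls <- pmin(pmax(round(dosages), 0), 2)
  fmat <- as.matrix(ref[ridx, c("f0", "f1", "f2")])
  p <- fmat[cbind(seq_along(cls), cls + 1L)]
  if (any(p <= 0)) {
    stop("zero genotype-class frequency in reference; rebuild with a floor",
         call. = FALSE)
  }
  sum(-p * log2(p))
}

#' Append entropy features to a feature matrix
#'
#' Three configurations mirror the exploratory feature set: `global` adds
#' one column (entropy over the whole panel), `per_chromosome` adds one
#' column per distinct panel chromosome (entropy over that chromosome's
#' SNPs), and `combined` concatenates both. Per-chromosome entropies sum
#' exactly to the global entropy.
#'
#' Entropy columns live on a scale of tens of bits, far from the 0-2
#' dosage features, so by default they are z-scored; the scaling constants
#' are stored in attribute `entropy_scaling` and can be passed back via
#' `scaling` to transform a test cohort with training-set statistics.
#'
#' @param features a [encode()] feature matrix.
#' @param genotypes the matching [genotype_matrix()] (same subjects, same
#'   order), fully imputed.
#' @param ref a [build_reference()] table.
#' @param configuration `"global"`, `"per_chromosome"`, or `"combined"`.
#' @param standardize z-score the entropy columns (default `TRUE`).
#' @param scaling optional scaling constants (a previous result's
#'   `entropy_scaling` attribute) to apply instead of recomputing.
#' @return a `feature_matrix` with the original columns unchanged and the
#'   entropy columns appended.
#' @export
augment_features <- function(features, genotypes, ref,
                             configuration = c("global", "per_chromosome",
                                               "combined"),
                             standardize = TRUE, scaling = NULL) {
  configuration <- match.arg(configuration)
  if (nrow(features) != nrow(genotypes$dosages)) {
    stop("features and genotypes must cover the same subjects", call. = FALSE)
  }
  panel <- genotypes$panel
  dos <- genotypes$dosages
  chroms <- unique(panel$chromosome)

  global_col <- function() {
    matrix(apply(dos, 1, subject_entropy, ref = ref, panel = panel),
           ncol = 1, dimnames = list(NULL, "entropy_global"))
  }
  per_chrom_cols <- function() {
    out <- vapply(chroms, function(ch) {
      sub <- panel$rsid[panel$chromosome == ch]
      apply(dos, 1, subject_entropy, ref = ref, panel = panel,
            snp_subset = sub)
    }, numeric(nrow(dos)))
    out <- matrix(out, nrow = nrow(dos))
    colnames(out) <- paste0("entropy_chr", chroms)
    out
  }
  extra <- switch(configuration,
                  global = global_col(),
                  per_chromosome = per_chrom_cols(),
                  combined = cbind(global_col(), per_chrom_cols()))

  if (standardize) {
    if (is.null(scaling)) {
      mu <- colMeans(extra)
      sdv <- apply(extra, 2, stats::sd)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      scaling <- list(mean = mu, sd = sdv)
    }
    extra <- sweep(sweep(extra, 2, scaling$mean, `-`), 2, scaling$sd, `/`)
  }
  vals <- cbind(unclass(features), extra)
  out <- feature_matrix(vals, encoding = attr(features, "encoding"),
                        panel = panel)
  attr(out, "entropy_scaling") <- scaling
  attr(out, "entropy_configuration") <- configuration
  out
}
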