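# Hardy-Weinberg imputation: empirical allele/genotype frequencies from a
# prevalence-controlled reference subsample, and label-blind filling of
# missing dosages under HWE.

#' Build reference allele and genotype frequencies
#'
#' Draws a reference subsample whose case fraction equals
#' `target_prevalence` (all of the scarcer class is kept; the other class
#' is undersampled, rounding down), then computes, per panel SNP over
#' non-missing entries: the risk-allele frequency `q` (mean dosage / 2)
#' and the empirical genotype-class frequencies `f0`, `f1`, `f2`.
#' Unobserved genotype classes are floored at `eps` and the triple is
#' renormalised, so downstream entropy logs stay finite.
#'
#' Only `case` and `control` subjects enter the reference; auxiliary
#' controls are excluded.
#'
#' @param genotypes a [genotype_matrix()] (missing entries allowed).
#' @param subjects a [subject_table()] covering the genotype subjects.
#' @param target_prevalence case fraction of the reference subsample
#'   (default 0.10).
#' @param seed integer seed for the undersampling draw.
#' @param eps floor applied to unobserved genotype-class frequencies.
#' @return a `reference_frequencies` data frame (rsid, q, f0, f1, f2) with
#'   attributes `n_reference` and `target_prevalence`.
#' @export
build_reference <- function(genotypes, subjects, target_prevalence = 0.10,
                            seed = 1L, eps = 1e-6) {
  stopifnot(target_prevalence > 0, target_prevalence < 1)
  idx <- match(genotypes$subject_ids, subjects$subject_id)
  if (anyNA(idx)) {
    stop("subject table does not cover all genotyped subjects", call. = FALSE)
  }
  lab <- subjects$label[idx]
  cases <- which(lab == "case")
  controls <- which(lab == "control")
  if (length(cases) == 0 || length(controls) == 0) {
    stop(sprintf(
      "need both cases and controls to target prevalence %.3f (achievable range requires >0 of each)",
      target_prevalence), call. = FALSE)
  }
  current <- length(cases) / (length(cases) + length(controls))
  if (current <= target_prevalence) {
    # keep all cases, undersample controls
    n_ctrl <- floor(length(cases) * (1 - target_prevalence) / target_prevalence)
    keep <- c(cases, with_seed(seed, sample(controls, n_ctrl)))
  } else {
    n_case <- floor(length(controls) * target_prevalence / (1 - target_prevalence))
    keep <- c(with_seed(seed, sample(cases, n_case)), controls)
  }
  dos <- genotypes$dosages[keep, , drop = FALSE]
  miss <- genotypes$missing[keep, , drop = FALSE]
  dos[miss] <- NA_real_

  q <- colMeans(dos, na.rm = TRUE) / 2
  cls <- round(dos)
  freq <- t(vapply(seq_len(ncol(dos)), function(j) {
    x <- cls[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      # fall back to HWE at q = 0.5 when a SNP is entirely unobserved
      return(c(0.25, 0.5, 0.25))
    }
    f <- tabulate(x + 1L, nbins = 3L) / length(x)
    f <- pmax(f, eps)
    f / sum(f)
  }, numeric(3)))
  q[is.nan(q)] <- 0.5
  ref <- data.frame(rsid = genotypes$panel$rsid, q = unname(q),
                    f0 = freq[, 1], f1 = freq[, 2], f2 = freq[, 3],
                    stringsAsFactors = FALSE)
  attr(ref, "n_reference") <- length(keep)
  attr(ref, "target_prevalence") <- target_prevalence
  class(ref) <- c("reference_frequencies", "data.frame")
  ref
}

#' Hardy-Weinberg genotype probabilities
#'
#' For risk-allele frequency `q`, the dosage-class probabilities under
#' random mating: `((1-q)^2, 2q(1-q), q^2)`.
#'
#' @param q allele frequency (vectorised), each in \[0, 1\].
#' @return for scalar `q` a named numeric triple `(P0, P1, P2)`; for
#'   vector `q` a matrix with one row per frequency.
#' @examples
#' hwe_genotype_probs(0.5)  # 0.25 0.50 0.25
#' @export
hwe_genotype_probs <- function(q) {
  if (any(!is.finite(q)) || any(q < 0 | q > 1)) {
    stop("allele frequency q must lie in [0, 1]", call. = FALSE)
  }
  out <- cbind(P0 = (1 - q)^2, P1 = 2 * q * (1 - q), P2 = q^2)
  if (length(q) == 1) out[1, ] else out
}

#' Impute missing dosages under Hardy-Weinberg equilibrium
#'
#' Fills every missing entry from reference frequencies, independently of
#' case/control labels (which are never consulted). `expected` mode fills
#' the HWE expected dosage `2q` (real-valued); `sampled` mode draws a hard
#' genotype from `((1-q)^2, 2q(1-q), q^2)` under the given seed. Observed
#' entries are untouched; a fully observed matrix is returned unchanged.
#'
#' @param genotypes a [genotype_matrix()].
#' @param ref a [build_reference()] table covering every panel SNP.
#' @param mode `"expected"` (default) or `"sampled"`.
#' @param seed integer seed (used by `sampled` mode).
#' @return a [genotype_matrix()] with no missing entries.
#' @export
impute <- function(genotypes, ref, mode = c("expected", "sampled"), seed = 1L) {
  mode <- match.arg(mode)
  ridx <- match(genotypes$panel$rsid, ref$rsid)
  if (anyNA(ridx)) {
    stop("reference frequencies missing for: ",
         paste(genotypes$panel$rsid[is.na(ridx)], collapse = ", "),
         call. = FALSE)
  }
  if (!any(genotypes$missing)) return(genotypes)
  q <- ref$q[ridx]
  dos <- genotypes$dosages
  miss_idx <- which(genotypes$missing, arr.ind = TRUE)
  qm <- q[miss_idx[, 2]]
  if (mode == "expected") {
    dos[miss_idx] <- 2 * qm
  } else {
    dos[miss_idx] <- with_seed(seed, stats::rbinom(length(qm), 2L, qm))
  }
  genotype_matrix(dos, genotypes$panel, subject_ids = genotypes$subject_ids,
                  missing = matrix(FALSE, nrow(dos), ncol(dos)))
}

#' Write / read reference frequencies as TSV
#'
#' Serialises the (rsid, q, f0, f1, f2) table for reuse across cohorts.
#'
#' @param ref a `reference_frequencies` object.
#' @param path output TSV path.
#' @return `write_reference` returns `path` invisibly; `read_reference`
#'   returns a `reference_frequencies` object.
#' @export
write_reference <- function(ref, path) {
  utils::write.table(as.data.frame(ref), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("rsid", "q", "f0", "f1", "f2") %in% names(tab)))
  class(tab) <- c("reference_frequencies", "data.frame")
  tab
}
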