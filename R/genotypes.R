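# Genotype ingestion: subjects x panel risk-allele dosage matrices with a
# missingness mask, read from VCF (GT or DS) or a delimited dosage matrix
# and oriented so that every column counts copies of the panel risk allele.

#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds subjects x panel risk-allele dosages together
#' with a missingness mask and the panel its columns are aligned to.
#' Observed entries must lie in \[0, 2\]; hard genotype calls are 0/1/2 and
#' expected dosages (after imputation) may be fractional.
#'
#' @param dosages numeric matrix, subjects in rows, panel variants in
#'   columns (panel order). `NA` entries are treated as missing.
#' @param panel a [load_panel()] panel whose order matches the columns.
#' @param subject_ids character vector of unique subject identifiers;
#'   defaults to `rownames(dosages)`.
#' @param missing optional logical matrix marking missing entries; defaults
#'   to `is.na(dosages)`.
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, panel, subject_ids = rownames(dosages),
                            missing = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (ncol(dosages) != nrow(panel)) {
    stop(sprintf("dosage matrix has %d columns but panel has %d variants",
                 ncol(dosages), nrow(panel)), call. = FALSE)
  }
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("S%04d", seq_len(nrow(dosages)))
  }
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) {
    stop("subject identifiers must be unique", call. = FALSE)
  }
  if (is.null(missing)) missing <- is.na(dosages)
  missing <- missing | is.na(dosages)
  obs <- dosages[!missing]
  if (length(obs) > 0 && (any(!is.finite(obs)) || any(obs < 0 | obs > 2))) {
    stop("observed dosages must be finite and lie in [0, 2]", call. = FALSE)
  }
  dosages[missing] <- NA_real_
  dimnames(dosages) <- list(subject_ids, panel$rsid)
  dimnames(missing) <- dimnames(dosages)
  structure(list(subject_ids = subject_ids, dosages = dosages,
                 missing = missing, panel = panel),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d subjects x %d variants, %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages), 100 * mean(x$missing)))
  invisible(x)
}

#' Number of subjects / variants
#' @param x a `genotype_matrix`.
#' @return integer count.
#' @export
n_subjects <- function(x) length(x$subject_ids)

#' Read subject genotypes and orient them to panel risk alleles
#'
#' Supports two sources. A VCF (v4.x, possibly gzipped) is matched to the
#' panel by rsID, falling back to (chromosome, position) for records
#' without IDs; dosages come from the `GT` field, or `DS` (rounded to
#' 0/1/2) when `GT` is absent. A delimited dosage matrix has a header row
#' of rsIDs, a first column of subject identifiers, and cells in
#' \{0, 1, 2, NA\} already counting risk alleles.
#'
#' VCF orientation rule: if an ALT allele equals the panel risk allele the
#' dosage is the count of that ALT; if REF equals the risk allele the
#' dosage is `2 -` the non-reference count. Indel codes `I`/`D` match the
#' longer/shorter of REF vs ALT. A biallelic record whose REF and ALT both
#' differ from the risk allele raises an error naming the rsID; malformed
#' genotype entries are set missing with a warning. Panel variants absent
#' from the source are marked missing for all subjects (their count is in
#' attribute `n_absent_snps`).
#'
#' @param source path to a `.vcf`/`.vcf.gz` file or a delimited matrix.
#' @param panel a [load_panel()] panel.
#' @param format `"auto"` (default, by file extension), `"vcf"`, or
#'   `"matrix"`.
#' @return a [genotype_matrix()] aligned to `panel` order, with attribute
#'   `n_absent_snps` counting panel variants not found in the source.
#' @export
read_genotypes <- function(source, panel, format = c("auto", "vcf", "matrix")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", source, ignore.case = TRUE)) {
      "vcf"
    } else {
      "matrix"
    }
  }
  if (format == "vcf") read_genotypes_vcf(source, panel)
  else read_genotypes_matrix(source, panel)
}

read_genotypes_matrix <- function(source, panel) {
  first <- readLines(source, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(source, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  subject_ids <- as.character(tab[[1]])
  tab <- tab[, -1, drop = FALSE]
  dos <- matrix(NA_real_, nrow = length(subject_ids), ncol = nrow(panel))
  hit <- match(panel$rsid, names(tab))
  for (j in seq_along(hit)) {
    if (is.na(hit[j])) next
    v <- suppressWarnings(as.numeric(tab[[hit[j]]]))
    bad <- !is.na(v) & !(v %in% c(0, 1, 2))
    if (any(bad)) {
      stop(sprintf("dosage values outside {0,1,2,NA} for %s", panel$rsid[j]),
           call. = FALSE)
    }
    dos[, j] <- v
  }
  gm <- genotype_matrix(dos, panel, subject_ids = subject_ids)
  attr(gm, "n_absent_snps") <- sum(is.na(hit))
  gm
}

read_genotypes_vcf <- function(source, panel) {
  vcf <- vcfR::read.vcfR(source, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  subject_ids <- colnames(gt)[-1]
  n <- length(subject_ids)
  dos <- matrix(NA_real_, nrow = n, ncol = nrow(panel))

  ids <- fix[, "ID"]
  key <- paste(sub("^chr", "", fix[, "CHROM"]), fix[, "POS"])
  panel_key <- paste(sub("^chr", "", panel$chromosome), panel$position)

  for (j in seq_len(nrow(panel))) {
    row <- which(!is.na(ids) & ids == panel$rsid[j])
    if (length(row) == 0) row <- which(key == panel_key[j])
    if (length(row) == 0) next
    if (length(row) > 1) {
      stop(sprintf("multiple VCF records match %s", panel$rsid[j]),
           call. = FALSE)
    }
    ref <- toupper(fix[row, "REF"])
    alts <- toupper(strsplit(fix[row, "ALT"], ",", fixed = TRUE)[[1]])
    ori <- orient_alleles(panel$risk_allele[j], ref, alts, panel$rsid[j])
    fmt <- strsplit(gt[row, 1], ":", fixed = TRUE)[[1]]
    fields <- strsplit(gt[row, -1], ":", fixed = TRUE)
    gt_idx <- match("GT", fmt)
    ds_idx <- match("DS", fmt)
    if (!is.na(gt_idx)) {
      gts <- vapply(fields, function(f) {
        if (length(f) >= gt_idx) f[gt_idx] else NA_character_
      }, character(1))
      alt_counts <- vapply(gts, parse_gt, numeric(1),
                           alt_index = ori$alt_index, USE.NAMES = FALSE)
      n_malformed <- sum(is.na(alt_counts) &
                           !(is.na(gts) | grepl("^[./|]+$", gts)))
      if (n_malformed > 0) {
        warning(sprintf("%d malformed genotype(s) at %s set missing",
                        n_malformed, panel$rsid[j]), call. = FALSE)
      }
    } else if (!is.na(ds_idx)) {
      if (length(alts) > 1) {
        stop(sprintf("DS dosage is ambiguous for multi-allelic record %s",
                     panel$rsid[j]), call. = FALSE)
      }
      alt_counts <- vapply(fields, function(f) {
        v <- suppressWarnings(as.numeric(if (length(f) >= ds_idx) f[ds_idx] else NA))
        if (is.na(v) || v < -0.5 || v > 2.5) NA_real_ else round(v)
      }, numeric(1))
    } else {
      stop(sprintf("VCF record %s has neither GT nor DS", panel$rsid[j]),
           call. = FALSE)
    }
    dos[, j] <- if (ori$risk_is_ref) 2 - alt_counts else alt_counts
  }
  found <- colSums(!is.na(dos)) > 0 |
    panel$rsid %in% ids | panel_key %in% key
  gm <- genotype_matrix(dos, panel, subject_ids = subject_ids)
  attr(gm, "n_absent_snps") <- sum(!found)
  gm
}

# Decide whether the risk allele is REF or one of the ALTs; returns the
# 1-based ALT index counted (unused when the risk allele is REF).
orient_alleles <- function(risk, ref, alts, rsid) {
  if (risk %in% c("I", "D")) {
    lens <- nchar(alts)
    if (risk == "I") {
      if (nchar(ref) > max(lens)) return(list(risk_is_ref = TRUE, alt_index = 1L))
      cand <- which(lens > nchar(ref))
    } else {
      if (nchar(ref) < min(lens)) return(list(risk_is_ref = TRUE, alt_index = 1L))
      cand <- which(lens < nchar(ref))
    }
    if (length(cand) != 1) {
      stop(sprintf("cannot resolve indel risk allele %s for %s", risk, rsid),
           call. = FALSE)
    }
    return(list(risk_is_ref = FALSE, alt_index = cand))
  }
  if (ref == risk) return(list(risk_is_ref = TRUE, alt_index = 1L))
  hit <- which(alts == risk)
  if (length(hit) == 1) return(list(risk_is_ref = FALSE, alt_index = hit))
  stop(sprintf(
    "allele mismatch for %s: risk allele %s matches neither REF (%s) nor ALT (%s)",
    rsid, risk, ref, paste(alts, collapse = ",")), call. = FALSE)
}

# Count copies of ALT allele `alt_index` in one GT string; NA when the
# call is missing or malformed.
parse_gt <- function(gt, alt_index) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) != 2 || any(alleles == ".")) return(NA_real_)
  idx <- suppressWarnings(as.integer(alleles))
  if (anyNA(idx)) return(NA_real_)
  sum(idx == alt_index)
}

#' Read a subject table
#'
#' CSV with columns `subject_id`, `label` (one of `case`, `control`,
#' `aux_control`) and optional `subgroup` (e.g. GADA status).
#'
#' @param path CSV file path.
#' @return a `subject_table` data frame.
#' @export
read_subjects <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  subject_table(tab$subject_id, tab$label,
                subgroup = if ("subgroup" %in% names(tab)) tab$subgroup else NULL)
}

#' Construct a subject table
#'
#' @param subject_id character vector of unique identifiers.
#' @param label per-subject label: `case`, `control`, or `aux_control`.
#' @param subgroup optional per-subject tag (e.g. `GADA_pos` / `GADA_neg`).
#' @return a `subject_table` data frame.
#' @export
subject_table <- function(subject_id, label, subgroup = NULL) {
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) {
    stop("subject identifiers must be unique", call. = FALSE)
  }
  label <- as.character(label)
  bad <- !(label %in% c("case", "control", "aux_control"))
  if (any(bad)) {
    stop("labels must be one of case/control/aux_control; offending: ",
         paste(unique(label[bad]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(subject_id = subject_id, label = label,
                    subgroup = if (is.null(subgroup)) NA_character_
                               else as.character(subgroup),
                    stringsAsFactors = FALSE)
  class(out) <- c("subject_table", "data.frame")
  out
}
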