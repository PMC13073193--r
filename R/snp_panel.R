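# SNP panel: the ordered variant table (rsID, risk allele, beta weight,
# GRCh37 coordinate) that defines the feature space of every downstream
# stage. The packaged default is the 67-variant type 1 diabetes GRS2 panel.

VALID_ALLELES <- c("A", "C", "G", "T", "I", "D")

#' Load a SNP panel
#'
#' Reads a tab-separated panel table with columns `rsid`, `risk_allele`,
#' `beta`, `chromosome`, `position` (and optionally `genes`) and validates
#' it. With no argument, loads the packaged 67-SNP type 1 diabetes panel
#' (GRCh37), whose row order defines the feature order used by every
#' downstream operation.
#'
#' Risk alleles are single bases or the indel codes `I` (insertion, the
#' longer allele) and `D` (deletion, the shorter allele). Beta values are
#' per-allele log-odds weights.
#'
#' @param path path to a panel TSV; `NULL` (default) loads the packaged
#'   67-SNP panel.
#' @param build genome build tag recorded on the panel (default "GRCh37").
#' @return a `snp_panel`: a data frame with one row per variant, in panel
#'   order, with attribute `build`.
#' @examples
#' panel <- load_panel()
#' nrow(panel)          # 67
#' panel[panel$rsid == "rs2476601", c("risk_allele", "beta")]
#' @export
load_panel <- function(path = NULL, build = "GRCh37") {
  if (is.null(path)) {
    path <- system.file("extdata", "grs2_panel_grch37.tsv", package = "t1dnn",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, fill = TRUE,
                           colClasses = "character")
  required <- c("rsid", "risk_allele", "beta", "chromosome", "position")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("panel file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  panel <- data.frame(
    rsid = trimws(tab$rsid),
    risk_allele = toupper(trimws(tab$risk_allele)),
    beta = as.numeric(tab$beta),
    chromosome = trimws(tab$chromosome),
    position = as.integer(tab$position),
    genes = if ("genes" %in% names(tab)) trimws(tab$genes) else NA_character_,
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  attr(panel, "build") <- build
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

validate_panel <- function(panel) {
  if (any(!nzchar(panel$rsid)) || anyNA(panel$rsid)) {
    stop("panel contains empty rsid entries", call. = FALSE)
  }
  dup <- panel$rsid[duplicated(panel$rsid)]
  if (length(dup) > 0) {
    stop("duplicate rsid in panel: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(panel$beta))) {
    stop("non-finite beta value(s) in panel for: ",
         paste(panel$rsid[!is.finite(panel$beta)], collapse = ", "),
         call. = FALSE)
  }
  bad_allele <- !(panel$risk_allele %in% VALID_ALLELES)
  if (any(bad_allele)) {
    stop("invalid risk allele(s) (expected A/C/G/T/I/D) for: ",
         paste(panel$rsid[bad_allele], collapse = ", "), call. = FALSE)
  }
  if (anyNA(panel$position) || any(panel$position <= 0)) {
    stop("positions must be positive 1-based coordinates", call. = FALSE)
  }
  invisible(panel)
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("<snp_panel> %d variants (%s), %d chromosomes\n",
              nrow(x), attr(x, "build") %||% "unknown build",
              length(unique(x$chromosome))))
  cat(sprintf("  beta range: [%.2f, %.2f]\n", min(x$beta), max(x$beta)))
  invisible(x)
}
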