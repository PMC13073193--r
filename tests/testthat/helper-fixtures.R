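# Shared fixtures: tiny panels, in-memory genotype matrices, and
# synthetic VCF writers. Everything is built in code at test time.

tiny_panel <- function(n = 3, betas = NULL, chroms = NULL,
                       alleles = NULL) {
  df <- data.frame(
    rsid = sprintf("rs%d", seq_len(n)),
    risk_allele = if (is.null(alleles)) rep_len(c("A", "G", "T", "C"), n) else alleles,
    beta = if (is.null(betas)) seq(0.1, by = 0.1, length.out = n) else betas,
    chromosome = if (is.null(chroms)) rep_len(c("1", "2"), n) else chroms,
    position = 1000L * seq_len(n),
    genes = NA_character_,
    stringsAsFactors = FALSE
  )
  attr(df, "build") <- "GRCh37"
  class(df) <- c("snp_panel", "data.frame")
  df
}

tiny_genotypes <- function(dosages, panel = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(panel)) panel <- tiny_panel(ncol(dosages))
  genotype_matrix(dosages, panel,
                  subject_ids = sprintf("P%03d", seq_len(nrow(dosages))))
}

# uniform reference: every genotype class at the given frequency triple
flat_reference <- function(panel, f = c(0.25, 0.5, 0.25), q = 0.5) {
  data.frame(rsid = panel$rsid, q = q, f0 = f[1], f1 = f[2], f2 = f[3],
             stringsAsFactors = FALSE)
}

# Write a minimal VCF v4.2. `records` is a data.frame with columns
# chrom, pos, id, ref, alt; `gt` a records x samples character matrix.
write_test_vcf <- function(path, records, gt, format = "GT") {
  samples <- colnames(gt)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(gt)))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(samples, collapse = "\t"))
  )
  body <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(records$chrom[i], records$pos[i], records$id[i], records$ref[i],
            records$alt[i], ".", ".", ".", format, gt[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# small fast network for tests that only exercise mechanics
tiny_net <- function(seed = 1L) {
  network_config(hidden_sizes = c(16L, 8L), dropout_rates = c(0.1, 0.1),
                 seed = seed)
}

fast_train <- function(...) {
  train_config(optimizer = "adam", learning_rate = 0.01, max_epochs = 30L,
               patience = 10L, ...)
}
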