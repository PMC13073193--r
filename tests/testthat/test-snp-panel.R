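test_that("packaged panel loads with the published content", {
  panel <- load_panel()
  expect_s3_class(panel, "snp_panel")
  expect_equal(nrow(panel), 67L)
  expect_false(anyDuplicated(panel$rsid) > 0)

  row <- panel[panel$rsid == "rs2476601", ]
  expect_equal(row$risk_allele, "A")
  expect_equal(row$beta, 0.64)
  expect_equal(row$chromosome, "1")
  expect_equal(row$position, 114377568L)

  # indel-coded risk alleles are present
  expect_setdiff <- setdiff(unique(panel$risk_allele), c("A", "C", "G", "T", "I", "D"))
  expect_length(expect_setdiff, 0)
})

test_that("panel validation rejects duplicates and bad values", {
  panel <- tiny_panel(3)
  tmp <- tempfile(fileext = ".tsv")

  dup <- rbind(panel, panel[1, ])
  write.table(dup, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_panel(tmp), "duplicate rsid")

  bad <- panel
  bad$beta[2] <- Inf
  write.table(bad, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_panel(tmp), "non-finite beta")

  neg <- panel
  neg$position[1] <- 0L
  write.table(neg, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_panel(tmp), "positive")
})

test_that("VCF dosages are oriented to the risk allele over all genotypes", {
  panel <- tiny_panel(2, alleles = c("A", "A"))
  gts <- c("0/0", "0/1", "1/0", "1/1", "0|0", "0|1", "1|0", "1|1", "./.")
  # rs1: ALT is the risk allele; rs2: REF is the risk allele
  records <- data.frame(chrom = c("1", "2"), pos = c(1000, 2000),
                        id = c("rs1", "rs2"), ref = c("G", "A"),
                        alt = c("A", "G"))
  gt <- rbind(gts, gts)
  colnames(gt) <- sprintf("S%02d", seq_along(gts))
  path <- write_test_vcf(tempfile(fileext = ".vcf"), records, gt)

  gm <- read_genotypes(path, panel)
  alt_count <- c(0, 1, 1, 2, 0, 1, 1, 2, NA)
  expect_equal(unname(gm$dosages[, "rs1"]), alt_count)
  # REF = risk allele: dosage complements the ALT count
  expect_equal(unname(gm$dosages[, "rs2"]), 2 - alt_count)
  # orientation consistency: the two encodings describe the same subjects
  expect_equal(gm$dosages[, "rs1"], 2 - gm$dosages[, "rs2"],
               ignore_attr = TRUE)
})

test_that("malformed genotype strings are set missing with a warning", {
  panel <- tiny_panel(1, alleles = "A")
  records <- data.frame(chrom = "1", pos = 1000, id = "rs1",
                        ref = "G", alt = "A")
  gt <- matrix(c("0/x", "1/1", "./."), nrow = 1,
               dimnames = list(NULL, c("S01", "S02", "S03")))
  path <- write_test_vcf(tempfile(fileext = ".vcf"), records, gt)
  expect_warning(gm <- read_genotypes(path, panel), "1 malformed")
  expect_equal(unname(gm$dosages[, 1]), c(NA, 2, NA))
})

test_that("panel variants absent from the source are whole-column missing", {
  panel <- tiny_panel(3, alleles = c("A", "A", "C"))
  records <- data.frame(chrom = "1", pos = 1000, id = "rs1",
                        ref = "G", alt = "A")
  gt <- matrix(c("0/1", "1/1"), nrow = 1)
  colnames(gt) <- c("S01", "S02")
  path <- write_test_vcf(tempfile(fileext = ".vcf"), records, gt)

  gm <- read_genotypes(path, panel)
  expect_equal(attr(gm, "n_absent_snps"), 2L)
  expect_true(all(gm$missing[, c("rs2", "rs3")]))
  expect_equal(unname(gm$dosages[, "rs1"]), c(1, 2))
})

test_that("allele mismatch errors name the variant; indels match by length", {
  panel <- tiny_panel(2, alleles = c("T", "I"))
  records <- data.frame(chrom = c("1", "2"), pos = c(1000, 2000),
                        id = c("rs1", "rs2"), ref = c("G", "A"),
                        alt = c("A", "ATT"))
  gt <- matrix(c("0/1", "1/1"), ncol = 1, dimnames = list(NULL, "S01"))
  path <- write_test_vcf(tempfile(fileext = ".vcf"), records, gt)
  expect_error(read_genotypes(path, panel), "rs1")

  # insertion risk allele = the longer allele (here ALT)
  panel_ok <- tiny_panel(2, alleles = c("A", "I"))
  gm <- read_genotypes(write_test_vcf(tempfile(fileext = ".vcf"),
                                      records, gt), panel_ok)
  expect_equal(unname(gm$dosages[1, ]), c(1, 2))

  # deletion risk allele = the shorter allele (here REF of an insertion row)
  panel_del <- tiny_panel(2, alleles = c("A", "D"))
  gm2 <- read_genotypes(write_test_vcf(tempfile(fileext = ".vcf"),
                                       records, gt), panel_del)
  expect_equal(unname(gm2$dosages[1, "rs2"]), 0)  # 2 - ALT count
})

test_that("feature columns follow panel order regardless of source order", {
  panel <- tiny_panel(3, alleles = c("A", "A", "A"))
  records <- data.frame(chrom = c("2", "1", "1"), pos = c(2000, 3000, 1000),
                        id = c("rs2", "rs3", "rs1"), ref = "G", alt = "A")
  gt <- matrix(c("1/1", "0/1", "0/0"), ncol = 1,
               dimnames = list(NULL, "S01"))
  gm <- read_genotypes(write_test_vcf(tempfile(fileext = ".vcf"),
                                      records, gt), panel)
  expect_equal(colnames(gm$dosages), panel$rsid)
  expect_equal(unname(gm$dosages[1, ]), c(0, 2, 1))
})

test_that("delimited dosage matrices round-trip and validate cells", {
  panel <- tiny_panel(3)
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,rs3,rs1",
               "P1,2,0",
               "P2,NA,1"), tmp)
  gm <- read_genotypes(tmp, panel)
  expect_equal(unname(gm$dosages[, "rs1"]), c(0, 1))
  expect_equal(unname(gm$dosages[, "rs3"]), c(2, NA))
  expect_true(all(gm$missing[, "rs2"]))
  expect_equal(attr(gm, "n_absent_snps"), 1L)

  writeLines(c("subject_id,rs1", "P1,3"), tmp)
  expect_error(read_genotypes(tmp, panel), "outside")
})

test_that("encoding is identity on counts and columnwise beta scaling", {
  panel <- tiny_panel(3, betas = c(0.5, -1.0, 2.0))
  dos <- rbind(c(0, 1, 2), c(2, 0, 1))
  gm <- tiny_genotypes(dos, panel)

  fc <- encode(gm, "count")
  expect_equal(unclass(fc), gm$dosages, ignore_attr = TRUE)

  fb <- encode(gm, "beta_weighted")
  expect_equal(unclass(fb),
               sweep(gm$dosages, 2, panel$beta, `*`), ignore_attr = TRUE)
  # zero dosage annihilates under either scheme
  expect_equal(fb[1, 1], 0)
  expect_equal(fc[1, 1], 0)

  gm_na <- tiny_genotypes(rbind(c(0, NA, 2)), panel)
  expect_error(encode(gm_na, "count"), "imput")
})

test_that("beta-weighted dosage of two risk alleles doubles the weight", {
  panel <- load_panel()
  j <- which(panel$rsid == "rs2476601")
  dos <- matrix(0, nrow = 1, ncol = nrow(panel))
  dos[1, j] <- 2
  f <- encode(genotype_matrix(dos, panel, subject_ids = "X"),
              "beta_weighted")
  expect_equal(unname(f[1, j]), 1.28)
})
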