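make_variants <- function(rsids, chrom = "1") {
  variant_info(rsids, chrom = rep(chrom, length.out = length(rsids)),
               pos = seq_along(rsids) * 100L, gene = "G1",
               minor_allele = "A", major_allele = "G")
}

test_that("genotype TSV parsing maps dosages and rejects malformed values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trs1", "s1\t0", "s2\t2"), path)
  gm <- read_genotypes(path, dialect = "tsv", variants = make_variants("rs1"))
  expect_equal(unname(gm$dosage[, "rs1"]), c(0L, 2L))
  expect_identical(gm$samples, c("s1", "s2"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trs1", "s1\t3"), bad)
  expect_error(read_genotypes(bad, "tsv", make_variants("rs1")),
               "malformed dosage.*rs1")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trs1\trs1", "s1\t0\t1"), dup)
  expect_error(read_genotypes(dup, "tsv"), "duplicated rsID")
})

test_that("genotype TSV round-trips exactly, including missing calls", {
  set.seed(7)
  dos <- matrix(sample(c(0:2, NA), 60, replace = TRUE), nrow = 10,
                dimnames = list(sprintf("s%02d", 1:10), NULL))
  gm <- genotype_matrix(dos, make_variants(sprintf("rs%d", 1:6)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, path)
  back <- read_genotypes(path, "tsv", gm$variants)
  expect_identical(back$dosage, gm$dosage)
  expect_identical(back$samples, gm$samples)
})

test_that("VCF import counts ALT alleles per genotype", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("1", "100", "rs1", "G", "A", ".", "PASS", "GENE=TYR", "GT",
            "0/1", "1/1", "0/0"), collapse = "\t"),
    paste(c("11", "200", "rs2", "C", "T", ".", "PASS", "GENE=TYR", "GT",
            "1|0", "./.", "0/0"), collapse = "\t")
  ), path)
  gm <- read_genotypes(path, dialect = "vcf")
  expect_equal(unname(gm$dosage[, "rs1"]), c(1L, 2L, 0L))
  expect_equal(unname(gm$dosage[, "rs2"]), c(1L, NA, 0L))
  expect_equal(gm$variants$minor_allele, c("A", "T"))
  expect_equal(gm$variants$major_allele, c("G", "C"))
  expect_equal(gm$variants$gene, c("TYR", "TYR"))

  # equals direct dosage construction from the same ALT counts
  direct <- genotype_matrix(
    matrix(c(1L, 2L, 0L, 1L, NA, 0L), nrow = 3,
           dimnames = list(c("s1", "s2", "s3"), NULL)),
    gm$variants
  )
  expect_identical(gm$dosage, direct$dosage)
})

test_that("phenotype reading applies the fixed risk coding and rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tsex\tstatus\teye\thair\tskin\tnaevi\tlentigines\tsunburn",
    "s1\tF\tcase\tblue\tred\tfair\t>=50\tyes\tno",
    "s2\tM\tcontrol\tbrown\tblack\tdark\t<50\tno\tNA",
    "s3\tF\tcontrol\tNA\t1\t0\tNA\tyes\tyes"
  ), path)
  ph <- read_phenotypes(path)
  expect_equal(ph$eye, c(1L, 0L, NA))
  expect_equal(ph$hair, c(1L, 0L, 1L))      # blond/red is the risk phenotype
  expect_equal(ph$skin, c(1L, 0L, 0L))
  expect_equal(ph$naevi, c(1L, 0L, NA))
  expect_equal(ph$sunburn, c(0L, NA, 1L))

  nosex <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tsex\tstatus\teye\thair\tskin\tnaevi\tlentigines\tsunburn",
    "s9\tNA\tcase\tblue\tred\tfair\t<50\tno\tno"
  ), nosex)
  expect_error(read_phenotypes(nosex), "s9")

  badcat <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tsex\tstatus\teye\thair\tskin\tnaevi\tlentigines\tsunburn",
    "s1\tF\tcase\tpurple\tred\tfair\t<50\tno\tno"
  ), badcat)
  expect_error(read_phenotypes(badcat), "unknown eye category 'purple'")
})

test_that("write_results is deterministic with a header and handles empty input", {
  res <- tibble::tibble(rsid = c("rs1", "rs2", "rs3"),
                        p = c(0.123456789, 1e-7, NA))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_results(res, p1); write_results(res, p2)
  expect_length(readLines(p1), 4L)
  expect_identical(readLines(p1), readLines(p2))
  expect_match(readLines(p1)[2], "0.12345679")   # >= 6 significant digits

  empty <- withr::local_tempfile()
  write_results(res[0, ], empty)
  expect_identical(readLines(empty), "rsid\tp")
})

test_that("domain type constructors enforce their invariants", {
  expect_error(variant_info(c("rs1", "rs1"), c("1", "2"), c(1, 2), "G",
                            "A", "G"), "duplicated rsID")
  expect_error(variant_info("rs1", "1", 1, "G", "A", "A"), "identical")
  expect_error(variant_info("rs1", "Y", 1, "G", "A", "G"), "chromosome")
  expect_error(genotype_matrix(matrix(3L, 1, 1, dimnames = list("s1", NULL)),
                               make_variants("rs1")), "dosage values")
  expect_error(sample_records("s1", "F", "unknown"), "status")
  expect_error(sample_records("s1", NA, "case"), "sex")
})
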