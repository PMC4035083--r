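test_that("genotype strings parse into unordered allele pairs", {
  snps <- snp_defs(snp_def("rs1", "A", "G"))
  d <- tibble::tibble(sample_id = "S1", cohort = "polish", sex = "male",
                      status = "sprint_power", level = "elite", rs1 = "AA")
  co <- genotype_cohort(d, snps)
  expect_identical(co$rs1, "AA")

  d2 <- tibble::tibble(sample_id = c("S1", "S2"), cohort = "polish",
                       sex = "male", status = "control", level = "none",
                       rs1 = c("GA", "AG"))
  co2 <- genotype_cohort(d2, snps)
  expect_identical(co2$rs1[1], co2$rs1[2])
})

test_that("missing tokens map to NA and junk genotypes warn", {
  snps <- snp_defs(snp_def("rs1", "A", "G"))
  d <- tibble::tibble(sample_id = paste0("S", 1:4), cohort = "x", sex = "male",
                      status = "control", level = "none",
                      rs1 = c("NA", "--", "", "A?"))
  expect_warning(co <- genotype_cohort(d, snps), "unparseable")
  expect_true(all(is.na(co$rs1)))
})

test_that("undeclared alleles and duplicate ids are hard errors", {
  snps <- snp_defs(snp_def("rs1", "A", "G"))
  d <- tibble::tibble(sample_id = c("S1", "S2"), cohort = "x", sex = "male",
                      status = "control", level = "none", rs1 = c("AA", "CT"))
  expect_error(genotype_cohort(d, snps), "unknown allele.*rs1")
  d2 <- tibble::tibble(sample_id = c("S1", "S1"), cohort = "x", sex = "male",
                       status = "control", level = "none", rs1 = "AA")
  expect_error(genotype_cohort(d2, snps), "duplicated sample id")
})

test_that("genotype table round-trips through TSV with identical counts", {
  co <- toy_cohort()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(co, path)
  back <- read_genotype_table(path, cohort_snps(co))
  for (snp in cohort_snps(co)$id) {
    expect_identical(count_genotypes(back, snp), count_genotypes(co, snp))
  }
})

test_that("pooling is additive, order-invariant, and checks allele defs", {
  co <- toy_cohort()
  doubled <- pool_cohorts(co, co)
  c1 <- count_genotypes(co, "rs1")
  c2 <- count_genotypes(doubled, "rs1")
  expect_equal(c2$n, 2 * c1$n)

  a <- co[co$cohort == "polish", ]
  b <- co[co$cohort == "russian", ]
  ab <- count_genotypes(pool_cohorts(a, b), "rs2", by = c("cohort", "status"))
  ba <- count_genotypes(pool_cohorts(b, a), "rs2", by = c("cohort", "status"))
  expect_identical(dplyr::arrange(ab, cohort, status, genotype),
                   dplyr::arrange(ba, cohort, status, genotype))

  other <- genotype_cohort(
    tibble::as_tibble(co),
    snp_defs(snp_def("rs1", "A", "G"), snp_def("rs2", "T", "A")),
    normalize = FALSE)
  expect_error(pool_cohorts(co, other), "allele definitions differ")
})

test_that("pooled athlete fixtures reproduce the published cohort sizes", {
  co <- athlete_cohort_fixture("both", "rs1867785")
  expect_equal(sum(co$status == "sprint_power"), 338)
  expect_equal(sum(co$status == "endurance"), 254)
  expect_equal(sum(co$status == "control"), 603)
  # pooled sprint/power marginals: 34 AA vs 304 carriers in athletes,
  # 105 vs 498 in controls
  cnt <- count_genotypes(co, "rs1867785")
  expect_equal(cnt$n[cnt$status == "control" & cnt$genotype == "AA"], 105)
  expect_equal(cnt$n[cnt$status == "sprint_power" & cnt$genotype == "AA"], 34)
  expect_equal(cnt$n[cnt$status == "control" & cnt$genotype == "AG"], 498)
  expect_equal(cnt$n[cnt$status == "sprint_power" & cnt$genotype == "AG"], 304)
})

test_that("VCF subset ingest translates GT fields and flags multi-allelics", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1\tP2\tP3",
    "2\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1\t./.",
    "2\t200\trsB\tT\tC\t.\tPASS\t.\tGT\t0/0\t0|1\t1/1",
    "2\t300\trsM\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0")
  vpath <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, vpath)
  sheet <- tibble::tibble(sample_id = c("P1", "P2", "P3"), cohort = "polish",
                          sex = "male", status = c("control", "sprint_power",
                                                   "control"),
                          level = c("none", "elite", "none"))
  spath <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(sheet, spath)

  co <- read_vcf_subset(vpath, c("rsA", "rsB"), spath)
  expect_identical(co$rsA, c("AG", "GG", NA))
  expect_identical(co$rsB, c("TT", "CT", "CC"))
  expect_error(read_vcf_subset(vpath, c("rsA", "rsM"), spath), "multi-allelic")
})

test_that("QC flags missingness above the ceiling without failing parse", {
  snps <- snp_defs(snp_def("rs1", "A", "G"))
  d <- tibble::tibble(sample_id = paste0("S", 1:10), cohort = "x",
                      sex = "male", status = "control", level = "none",
                      rs1 = c(rep("AA", 8), NA, NA))
  co <- genotype_cohort(d, snps)
  expect_equal(missingness(co)$rate, 0.2)
  expect_error(check_cohort_qc(co, max_missing = 0.05), "QC failure")
  expect_silent(check_cohort_qc(co, max_missing = 0.25))
})
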