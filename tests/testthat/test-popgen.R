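test_that("HWE chi-squared matches hand computation", {
  # exact Hardy-Weinberg proportions
  r <- hwe_test(c(25, 50, 25))
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)

  # p-hat = 0.5, expected (7.5, 15, 7.5) -> chi2 = 10/3
  r2 <- hwe_test(c(10, 10, 10))
  expect_equal(r2$chi2, 10 / 3, tolerance = 1e-12)
  expect_equal(r2$p_value, pchisq(10 / 3, 1, lower.tail = FALSE))

  # monomorphic input is flagged, not an error
  r3 <- hwe_test(c(0, 0, 40))
  expect_true(r3$monomorphic)
  expect_equal(r3$chi2, 0)
})

test_that("HWE is invariant to allele relabeling", {
  for (counts in list(c(12, 40, 48), c(5, 20, 75), c(30, 30, 40))) {
    expect_equal(hwe_test(counts)$chi2, hwe_test(rev(counts))$chi2,
                 tolerance = 1e-12)
  }
})

test_that("r2 is 1 for a SNP against itself and matches phased truth", {
  snps <- two_snp_defs()
  co <- toy_cohort()
  self <- ld_r2(co$rs1, co$rs1, snps[1, ], snps[1, ])
  expect_equal(self$r2, 1, tolerance = 1e-9)

  # phase-known cohort built from haplotype counts AB=40 Ab=10 aB=10 ab=40:
  # D = 0.4 - 0.25 = 0.15, r2 = 0.15^2 / 0.25^2 = 0.36
  co2 <- cohort_from_haplotypes(c(`11` = 40, `10` = 10, `01` = 10, `00` = 40))
  r <- ld_r2(co2$rs1, co2$rs2, snps[1, ], snps[2, ])
  expect_equal(r$r2, 0.36, tolerance = 1e-6)
  expect_true(r$converged)
  # haplotype frequencies sum to one
  expect_equal(sum(r$haplotype_freqs[[1]]), 1, tolerance = 1e-9)
})

test_that("EM equals closed-form haplotype frequencies without ambiguity", {
  # no double heterozygotes: 11+00 and 10+01 pairings only
  co <- cohort_from_haplotypes(c(`11` = 30, `00` = 50, `10` = 12, `01` = 8))
  snps <- two_snp_defs()
  r <- ld_r2(co$rs1, co$rs2, snps[1, ], snps[2, ])
  n_hap <- 100
  expect_equal(sort(unname(r$haplotype_freqs[[1]])),
               sort(c(30, 50, 12, 8) / n_hap), tolerance = 1e-8)
})

test_that("r2 is symmetric and invariant to allele relabeling", {
  set.seed(404)
  sim <- simulate_cohort(simulation_config(
    n_cases = 50, n_controls = 150, seed = 404))
  co <- sim$cohort
  snps <- cohort_snps(co)
  a <- snps[snps$id == "rs1867785", ]; b <- snps[snps$id == "rs11689011", ]
  r_ab <- ld_r2(co$rs1867785, co$rs11689011, a, b)
  r_ba <- ld_r2(co$rs11689011, co$rs1867785, b, a)
  expect_equal(r_ab$r2, r_ba$r2, tolerance = 1e-12)

  a_swap <- snp_def("rs1867785", "G", "A") # relabel major/minor
  r_sw <- ld_r2(co$rs1867785, co$rs11689011, a_swap, b)
  expect_equal(r_sw$r2, r_ab$r2, tolerance = 1e-9)
})

test_that("monomorphic SNPs make r2 undefined", {
  snps <- two_snp_defs()
  g1 <- rep("AA", 10)
  g2 <- c(rep("TT", 5), rep("CT", 5))
  expect_error(ld_r2(g1, g2, snps[1, ], snps[2, ]), "undefined")
})

test_that("strong_ld_pairs finds exactly the simulated proxy pair", {
  sim <- simulate_cohort(simulation_config(n_cases = 300, n_controls = 500,
                                           seed = 99))
  pairs <- strong_ld_pairs(sim$cohort, threshold = 0.8)
  expect_equal(nrow(pairs), 1)
  expect_setequal(c(pairs$snp_a, pairs$snp_b), c("rs1867785", "rs11689011"))
  expect_gt(pairs$r2, 0.9)

  # strict threshold with no perfect proxies
  expect_equal(nrow(strong_ld_pairs(sim$cohort, threshold = 1.0)), 0)
})

test_that("a duplicated SNP column is reported with r2 = 1", {
  co <- toy_cohort()
  data <- tibble::as_tibble(co)
  data$rs1copy <- chartr("AG", "TC", data$rs1)
  snps <- snp_defs(snp_def("rs1", "A", "G"), snp_def("rs2", "T", "C"),
                   snp_def("rs1copy", "T", "C"))
  co2 <- genotype_cohort(data[, c(names(co)[1:5], snps$id)], snps,
                         normalize = FALSE)
  pairs <- strong_ld_pairs(co2, threshold = 0.8)
  expect_true(any(pairs$r2 > 1 - 1e-9))
})

test_that("simulated LD hits its target within sampling error", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_cohort(simulation_config(
      n_cases = 300, n_controls = 500, seed = 1000 + s))
    abs(sim$attained_ld$attained_r2 - 0.96) <= 0.03
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
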