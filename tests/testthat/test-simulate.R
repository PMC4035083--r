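test_that("haplotype pool inverts the target D at equal frequencies", {
  pool <- simulate_haplotype_pool(
    c(a = 0.5, b = 0.5),
    tibble::tibble(snp_a = "a", snp_b = "b", r2 = 0.36))
  # D = sqrt(0.36 * 0.5^4) = 0.15 -> frequencies (0.4, 0.1, 0.1, 0.4)
  probs <- pool$prob[order(pool$a, pool$b)]
  expect_equal(probs, c(0.4, 0.1, 0.1, 0.4), tolerance = 1e-12)
})

test_that("r2 = 0 gives product frequencies; r2 = 1 a two-haplotype pool", {
  p0 <- simulate_haplotype_pool(
    c(a = 0.3, b = 0.6),
    tibble::tibble(snp_a = "a", snp_b = "b", r2 = 0))
  expect_equal(p0$prob, (ifelse(p0$a == 1, 0.3, 0.7) *
                           ifelse(p0$b == 1, 0.6, 0.4)), tolerance = 1e-12)

  p1 <- simulate_haplotype_pool(
    c(a = 0.4, b = 0.4),
    tibble::tibble(snp_a = "a", snp_b = "b", r2 = 1))
  expect_equal(sum(p1$prob > 1e-12), 2)
})

test_that("infeasible targets and cyclic dependencies are rejected", {
  expect_error(simulate_haplotype_pool(
    c(a = 0.1, b = 0.9),
    tibble::tibble(snp_a = "a", snp_b = "b", r2 = 0.9)), "attainable bound")
  expect_error(simulate_haplotype_pool(
    c(a = 0.5, b = 0.5, c = 0.5),
    tibble::tibble(snp_a = c("a", "b", "c"), snp_b = c("b", "c", "a"),
                   r2 = 0.5)), "cyclic")
})

test_that("untargeted pairs of a chained pool stay near equilibrium", {
  pool <- simulate_haplotype_pool(
    c(a = 0.5, b = 0.5, c = 0.3),
    tibble::tibble(snp_a = c("a", "b"), snp_b = c("b", "c"), r2 = c(0.5, 0.4)))
  expect_equal(sum(pool$prob), 1, tolerance = 1e-12)
  # marginals preserved
  expect_equal(sum(pool$prob[pool$c == 1]), 0.3, tolerance = 1e-12)
})

test_that("simulated cohorts are byte-identical under a fixed seed", {
  cfg <- simulation_config(n_cases = 60, n_controls = 90, seed = 1234)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(tibble::as_tibble(s1$cohort), tibble::as_tibble(s2$cohort))
})

test_that("null effects leave case and control allele frequencies close", {
  cfg0 <- function(seed) simulation_config(
    n_cases = 1000, n_controls = 1000,
    effects = tibble::tibble(snp_a = character(), model_a = character(),
                             snp_b = character(), model_b = character(),
                             beta = numeric()),
    seed = seed)
  ok <- vapply(1:10, function(s) {
    co <- simulate_cohort(cfg0(2000 + s))$cohort
    snp <- cohort_snps(co)[cohort_snps(co)$id == "rs895436", ]
    cnt <- marsbif:::minor_allele_count(co$rs895436, snp)
    f_case <- mean(cnt[co$status != "control"]) / 2
    f_ctrl <- mean(cnt[co$status == "control"]) / 2
    abs(f_case - f_ctrl) < 0.03
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("a planted recessive effect is recovered by the OR pipeline", {
  cfg <- function(seed) simulation_config(
    n_cases = 1000, n_controls = 1000,
    minor_freqs = c(rs1867785 = 0.4, rs11689011 = 0.4, rs895436 = 0.35,
                    rs4035887 = 0.54, rs1867782 = 0.30),
    effects = tibble::tibble(snp_a = "rs1867785", model_a = "recessive",
                             snp_b = NA_character_, model_b = NA_character_,
                             beta = log(0.5)),
    seed = seed)
  hits <- vapply(1:10, function(s) {
    co <- simulate_cohort(cfg(3000 + s))$cohort
    r <- odds_ratio_for_rule(co, list(rs1867785 = "GG"), "sprint_power")
    abs(r$or - 0.5) <= 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("simulated controls satisfy HWE at the nominal rejection rate", {
  rejections <- vapply(1:150, function(s) {
    co <- simulate_cohort(simulation_config(
      n_cases = 30, n_controls = 300, seed = 5000 + s))$cohort
    h <- hwe_cohort(co, controls_only = TRUE, by_cohort = FALSE)
    h$p_value[h$snp_id == "rs895436"] <= 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.09)
})

test_that("count-table expansion is exact and the empty table works", {
  counts <- tibble::tibble(
    cohort = "polish", status = c("control", "endurance"),
    level = c("none", "elite"), snp = "rs1",
    genotype = c("AA", "AG"), n = c(5, 3))
  co <- fixture_from_counts(counts, snp_defs(snp_def("rs1", "A", "G")))
  expect_equal(nrow(co), 8)
  expect_equal(sum(co$rs1 == "AA", na.rm = TRUE), 5)

  empty <- fixture_from_counts(counts[0, ], snp_defs(snp_def("rs1", "A", "G")))
  expect_equal(nrow(empty), 0)
})
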