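test_that("exposure indicators honour conjunction, tautology, contradiction", {
  co <- toy_cohort()
  # tautological rule: every declared genotype class
  taut <- build_exposure_indicator(co, list(rs1 = c("AA", "AG", "GG")))
  expect_true(all(taut == 1))
  # conjunction of a rule and its complement is identically zero
  zero <- build_exposure_indicator(
    co, list(rs1 = "AA")) *
    build_exposure_indicator(co, list(rs1 = c("AG", "GG")))
  expect_true(all(zero == 0))
  # genotype spelling is order-insensitive
  expect_identical(build_exposure_indicator(co, list(rs1 = "GA")),
                   build_exposure_indicator(co, list(rs1 = "AG")))
  # impossible genotype errors
  expect_error(build_exposure_indicator(co, list(rs1 = "CC")), "impossible")
  expect_error(build_exposure_indicator(co, list(rs9 = "AA")), "unknown SNP")
})

test_that("odds ratio and Woolf CI match hand computation", {
  r <- odds_ratio(contingency_2x2(20, 80, 10, 90))
  expect_equal(r$or, 2.25, tolerance = 1e-12)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  expect_equal(r$ci_low, exp(log(2.25) - 1.959964 * se), tolerance = 1e-12)
  expect_equal(r$ci_high, exp(log(2.25) + 1.959964 * se), tolerance = 1e-12)

  expect_equal(odds_ratio(contingency_2x2(10, 10, 10, 10))$or, 1)
})

test_that("zero cells trigger Haldane correction; two zeros are an error", {
  r <- odds_ratio(contingency_2x2(0, 30, 10, 50))
  expect_identical(r$method, "haldane")
  expect_equal(r$or, (0.5 * 50.5) / (30.5 * 10.5), tolerance = 1e-12)
  expect_error(odds_ratio(contingency_2x2(0, 30, 0, 50)), "undefined")
})

test_that("swapping exposure and reference inverts the OR and its CI", {
  r <- odds_ratio(contingency_2x2(34, 304, 105, 498))
  r_swap <- odds_ratio(contingency_2x2(304, 34, 498, 105))
  expect_equal(r_swap$or, 1 / r$or, tolerance = 1e-12)
  expect_equal(r_swap$ci_low, 1 / r$ci_high, tolerance = 1e-12)
  expect_equal(r_swap$ci_high, 1 / r$ci_low, tolerance = 1e-12)
})

test_that("OR equals the exponentiated logistic slope on the same table", {
  tab <- contingency_2x2(34, 304, 105, 498)
  r <- odds_ratio(tab)
  x <- rep(c(1, 0, 1, 0), c(34, 304, 105, 498))
  y <- rep(c(1, 1, 0, 0), c(34, 304, 105, 498))
  fit <- fit_logistic(cbind(intercept = 1, exposure = x), y)
  expect_equal(r$or, exp(fit$coefficients$estimate[2]), tolerance = 1e-9)
})

test_that("published contrasts are reproduced from the count fixtures", {
  # pooled sprint/power, AA at rs1867785
  pooled <- athlete_cohort_fixture("both", "rs1867785")
  r <- odds_ratio_for_rule(pooled, list(rs1867785 = "AA"), "sprint_power")
  expect_equal(round(r$or, 2), 0.53)
  expect_equal(round(r$ci_low, 2), 0.35)
  expect_equal(round(r$ci_high, 2), 0.80)
  expect_equal(r$exposed_cases, 34)
  expect_equal(r$exposed_controls, 105)

  # Polish endurance, TT at rs11689011
  pol <- athlete_cohort_fixture("polish", "rs11689011")
  r2 <- odds_ratio_for_rule(pol, list(rs11689011 = "TT"), "endurance")
  expect_equal(round(r2$or, 2), 0.49)
})

test_that("subgroup ORs restrict cases but never controls", {
  pooled <- athlete_cohort_fixture("both", "rs1867785")
  sub <- subgroup_odds_ratios(pooled, list(rs1867785 = "AA"), "sprint_power")
  expect_setequal(sub$level, c("elite", "sub_elite"))
  elite <- sub[sub$level == "elite", ]
  expect_equal(round(elite$or, 2), 0.41)
  expect_equal(elite$exposed_controls, 105) # controls unchanged
  expect_equal(elite$exposed_cases + elite$unexposed_cases, 164)

  # a stratum equal to all cases reproduces the unstratified OR
  co <- toy_cohort()
  data <- tibble::as_tibble(co)
  data$level[data$status != "control"] <- "elite"
  co2 <- genotype_cohort(data, cohort_snps(co), normalize = FALSE)
  full <- odds_ratio_for_rule(co2, list(rs1 = "AA"), "sprint_power")
  strat <- subgroup_odds_ratios(co2, list(rs1 = "AA"), "sprint_power",
                                strata = "elite")
  expect_equal(strat$or, full$or)
})

test_that("or_table composes rules and validates inputs", {
  pooled <- athlete_cohort_fixture("both", "rs1867785")
  tab <- or_table(pooled, list(aa = list(rs1867785 = "AA")), "sprint_power",
                  by_level = TRUE)
  expect_equal(nrow(tab), 3) # all + elite + sub-elite
  expect_equal(round(tab$or[tab$level == "all"], 2), 0.53)
  expect_equal(nrow(or_table(pooled, list(), "sprint_power")), 0)
  expect_error(or_table(pooled, list(x = list(rs999 = "AA")), "sprint_power"),
               "unknown SNP")
})
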