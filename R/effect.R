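z_95 <- 1.959964 # two-sided 95% normal quantile used for Woolf intervals

# Normalise and validate a genotype rule: a named list mapping SNP ids to
# allowed genotype classes, optionally with a `sex` entry ("female"/"male").
normalize_rule <- function(rule, snps) {
  stopifnot(is.list(rule), length(rule) > 0, !is.null(names(rule)))
  out <- list()
  for (nm in names(rule)) {
    if (nm == "sex") {
      stopifnot(all(rule[[nm]] %in% c("female", "male")))
      out$sex <- rule[[nm]]
      next
    }
    if (!nm %in% snps$id) stop("rule references unknown SNP: ", nm, call. = FALSE)
    snp <- snps[snps$id == nm, ]
    g <- toupper(rule[[nm]])
    if (!all(grepl("^[ACGT]{2}$", g))) {
      stop("malformed genotype class in rule for ", nm, call. = FALSE)
    }
    sorted <- vapply(strsplit(g, ""), function(ch) paste(sort(ch), collapse = ""),
                     character(1))
    declared <- c(snp$major_allele, snp$minor_allele)
    chars <- unique(unlist(strsplit(sorted, "")))
    if (!all(chars %in% declared)) {
      stop("rule names impossible genotype for ", nm, ": alleles are ",
           declared[1], "/", declared[2], call. = FALSE)
    }
    out[[nm]] <- unique(sorted)
  }
  out
}

rule_label <- function(rule) {
  parts <- vapply(names(rule), function(nm) {
    if (nm == "sex") paste("sex =", paste(rule[[nm]], collapse = " or "))
    else paste(paste(rule[[nm]], collapse = " or "), "at", nm)
  }, character(1))
  paste(parts, collapse = " and ")
}

#' Per-individual exposure indicator from a genotype rule
#'
#' A rule is a named list mapping SNP ids to the genotype classes that
#' count as exposed (order-insensitive strings, e.g.
#' `list(rs1867785 = "AA")` or
#' `list(rs4035887 = "AA", rs1867785 = c("GA", "GG"))`); an optional `sex`
#' entry restricts exposure by sex. The indicator is 1 iff every clause
#' holds; individuals missing any referenced genotype are `NA` and drop
#' out of the 2x2 table.
#'
#' @param cohort A `genotype_cohort`.
#' @param rule Named list of clauses (see above).
#' @return Integer vector (1 = exposed, 0 = not, `NA` = missing).
#' @export
build_exposure_indicator <- function(cohort, rule) {
  rule <- normalize_rule(rule, cohort_snps(cohort))
  ind <- rep(1L, nrow(cohort))
  for (nm in names(rule)) {
    if (nm == "sex") {
      ind <- ind * as.integer(cohort$sex %in% rule$sex)
    } else {
      g <- cohort[[nm]]
      ind <- ind * ifelse(is.na(g), NA_integer_, as.integer(g %in% rule[[nm]]))
    }
  }
  ind
}

#' Construct a 2x2 exposure-by-status contingency table
#'
#' @param exposed_cases,unexposed_cases,exposed_controls,unexposed_controls
#'   Non-negative counts.
#' @param exposure_label,reference_label Human-readable genotype rules.
#' @return A `contingency_2x2` object (named list).
#' @export
contingency_2x2 <- function(exposed_cases, unexposed_cases,
                            exposed_controls, unexposed_controls,
                            exposure_label = "exposed",
                            reference_label = "all other combinations") {
  counts <- c(exposed_cases, unexposed_cases, exposed_controls, unexposed_controls)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(list(exposed_cases = exposed_cases,
                 unexposed_cases = unexposed_cases,
                 exposed_controls = exposed_controls,
                 unexposed_controls = unexposed_controls,
                 exposure_label = exposure_label,
                 reference_label = reference_label),
            class = "contingency_2x2")
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' Point estimate \eqn{(a d)/(b c)} (the unconditional maximum-likelihood
#' estimate for a 2x2 table) with the asymptotic log-OR interval
#' \eqn{\exp(\ln OR \pm 1.959964 \sqrt{1/a + 1/b + 1/c + 1/d})}. A single
#' zero cell triggers the Haldane-Anscombe correction (0.5 added to every
#' cell, `method = "haldane"`); two or more zero cells are an error.
#'
#' @param table A `contingency_2x2`.
#' @return A one-row tibble: the four counts, `or`, `ci_low`, `ci_high`,
#'   `method`, `exposure_label`, `reference_label`.
#' @export
#' @examples
#' odds_ratio(contingency_2x2(34, 304, 105, 498))$or # 0.53 after rounding
odds_ratio <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  cells <- c(table$exposed_cases, table$unexposed_cases,
             table$exposed_controls, table$unexposed_controls)
  if (sum(cells == 0) >= 2) stop("OR undefined: two or more zero cells", call. = FALSE)
  method <- "woolf"
  if (any(cells == 0)) {
    cells <- cells + 0.5
    method <- "haldane"
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble::tibble(exposed_cases = table$exposed_cases,
                 unexposed_cases = table$unexposed_cases,
                 exposed_controls = table$exposed_controls,
                 unexposed_controls = table$unexposed_controls,
                 or = or,
                 ci_low = exp(log(or) - z_95 * se),
                 ci_high = exp(log(or) + z_95 * se),
                 method = method,
                 exposure_label = table$exposure_label,
                 reference_label = table$reference_label)
}

# 2x2 table for a rule in a cohort; cases optionally restricted to a level.
table_for_rule <- function(cohort, rule, case_group, level = NULL) {
  ind <- build_exposure_indicator(cohort, rule)
  is_case <- cohort$status == case_group
  if (!is.null(level)) is_case <- is_case & cohort$level == level
  is_control <- cohort$status == "control"
  keep <- !is.na(ind) & (is_case | is_control)
  contingency_2x2(
    exposed_cases = sum(ind == 1 & is_case & keep),
    unexposed_cases = sum(ind == 0 & is_case & keep),
    exposed_controls = sum(ind == 1 & is_control & keep),
    unexposed_controls = sum(ind == 0 & is_control & keep),
    exposure_label = rule_label(normalize_rule(rule, cohort_snps(cohort))))
}

#' Odds ratio of case status for a genotype rule
#'
#' @param cohort A `genotype_cohort`.
#' @param rule Named genotype rule (see [build_exposure_indicator()]).
#' @param case_group `"sprint_power"` or `"endurance"`.
#' @param level Optional competition level restricting the cases
#'   (`"elite"` or `"sub_elite"`); controls are never restricted.
#' @return A one-row tibble as from [odds_ratio()].
#' @export
odds_ratio_for_rule <- function(cohort, rule,
                                case_group = c("sprint_power", "endurance"),
                                level = NULL) {
  case_group <- match.arg(case_group)
  odds_ratio(table_for_rule(cohort, rule, case_group, level))
}

#' Competition-level subgroup odds ratios
#'
#' Recomputes the odds ratio with the cases restricted to each competition
#' level in turn (controls unchanged); empty strata are skipped with a
#' warning.
#'
#' @inheritParams odds_ratio_for_rule
#' @param strata Levels to analyse (default elite and sub-elite).
#' @return A tibble with one row per non-empty stratum, first column `level`.
#' @export
subgroup_odds_ratios <- function(cohort, rule,
                                 case_group = c("sprint_power", "endurance"),
                                 strata = c("elite", "sub_elite")) {
  case_group <- match.arg(case_group)
  purrr::map_dfr(strata, function(lv) {
    n_cases <- sum(cohort$status == case_group & cohort$level == lv)
    if (n_cases == 0) {
      warning("empty stratum '", lv, "' skipped", call. = FALSE)
      return(NULL)
    }
    dplyr::mutate(odds_ratio(table_for_rule(cohort, rule, case_group, lv)),
                  level = lv, .before = 1)
  })
}

#' Odds-ratio table for a list of genotype rules
#'
#' Thin composition of [odds_ratio_for_rule()] (and, when `by_level`,
#' [subgroup_odds_ratios()]) over a named list of rules.
#'
#' @param cohort A `genotype_cohort`.
#' @param rules Named list of genotype rules.
#' @param case_group `"sprint_power"` or `"endurance"`.
#' @param by_level Also compute elite/sub-elite subgroup rows.
#' @return A tibble with columns `covariate`, `level` (`"all"` for the
#'   unstratified row) and the [odds_ratio()] columns.
#' @export
or_table <- function(cohort, rules, case_group = c("sprint_power", "endurance"),
                     by_level = FALSE) {
  case_group <- match.arg(case_group)
  if (length(rules) == 0) {
    return(tibble::tibble(covariate = character(), level = character(),
                          or = numeric()))
  }
  stopifnot(!is.null(names(rules)))
  purrr::imap_dfr(rules, function(rule, nm) {
    main <- dplyr::mutate(odds_ratio_for_rule(cohort, rule, case_group),
                          covariate = nm, level = "all", .before = 1)
    if (!by_level) return(main)
    sub <- subgroup_odds_ratios(cohort, rule, case_group)
    if (nrow(sub) > 0) sub <- dplyr::mutate(sub, covariate = nm, .before = 1)
    dplyr::bind_rows(main, sub)
  })
}
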