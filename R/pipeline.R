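#' Pipeline configuration
#'
#' Defaults are the reference settings of the five-step procedure:
#' significance level 0.05, BIF retention threshold 50%, 10000 bootstrap
#' replicates, at most 100 MARS basis functions with interaction degree 2,
#' and an LD split threshold of r-squared 0.8.
#'
#' @param case_groups Athlete groups to compare against controls; each is
#'   an independent analysis sharing the control set.
#' @param alpha Wald significance level for the covariate filter.
#' @param bif_threshold BIF retention threshold in percent.
#' @param B Bootstrap replicates.
#' @param max_basis,max_degree,penalty MARS settings (see [mars_fit()]).
#' @param ld_threshold r-squared above which a SNP pair is split across
#'   MARS runs.
#' @param fdr_family `"separate"` (BH within each analysis, default) or
#'   `"pooled"` (one BH family across all case groups).
#' @param bif_count Replicate-level inclusion rule
#'   (see [bootstrap_inclusion_fraction()]).
#' @param stratified_bootstrap Preserve case/control counts in resamples.
#' @param force_sex Always carry a sex main-effect term into the logistic
#'   filter in addition to MARS proposals.
#' @param max_missing Per-SNP missingness QC ceiling.
#' @param seed RNG seed for the bootstrap stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(case_groups = c("sprint_power", "endurance"),
                            alpha = 0.05, bif_threshold = 50, B = 10000,
                            max_basis = 100, max_degree = 2, penalty = 3,
                            ld_threshold = 0.8,
                            fdr_family = c("separate", "pooled"),
                            bif_count = c("appearance",
                                          "appearance_and_significant"),
                            stratified_bootstrap = FALSE,
                            force_sex = FALSE,
                            max_missing = 0.05, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, bif_threshold >= 0, bif_threshold <= 100,
            B >= 1, max_basis >= 1, max_degree >= 1,
            ld_threshold > 0, ld_threshold <= 1,
            max_missing >= 0, max_missing <= 1)
  structure(list(case_groups = match.arg(case_groups, several.ok = TRUE),
                 alpha = alpha, bif_threshold = bif_threshold, B = B,
                 max_basis = max_basis, max_degree = max_degree,
                 penalty = penalty, ld_threshold = ld_threshold,
                 fdr_family = match.arg(fdr_family),
                 bif_count = match.arg(bif_count),
                 stratified_bootstrap = stratified_bootstrap,
                 force_sex = force_sex,
                 max_missing = max_missing, seed = as.integer(seed)),
            class = "pipeline_config")
}

# MARS splits implied by the strong-LD pairs: one run per pair member,
# excluding its partner(s); a single run over all SNPs when no pair exists.
ld_splits <- function(snp_ids, ld_pairs) {
  if (nrow(ld_pairs) == 0) {
    return(list(all = snp_ids))
  }
  members <- unique(c(ld_pairs$snp_a, ld_pairs$snp_b))
  splits <- lapply(members, function(m) {
    partners <- unique(c(ld_pairs$snp_b[ld_pairs$snp_a == m],
                         ld_pairs$snp_a[ld_pairs$snp_b == m]))
    setdiff(snp_ids, partners)
  })
  names(splits) <- paste0("excl_", vapply(members, function(m) {
    paste(setdiff(members, m), collapse = "_")
  }, character(1)))
  splits
}

# Genotype rule ("exposed" classes) for a canonical identity under the
# chosen inheritance models. The additive model has no natural 2x2 and is
# collapsed to the carrier indicator.
rule_for_identity <- function(identity, model_choices, snps) {
  vars <- strsplit(identity, ":", fixed = TRUE)[[1]]
  rule <- list()
  for (v in vars) {
    if (v == "sex") {
      rule$sex <- "female"
      next
    }
    snp <- snps[snps$id == v, ]
    model <- model_choices$model[model_choices$snp_id == v]
    het <- paste(sort(c(snp$major_allele, snp$minor_allele)), collapse = "")
    hom_minor <- paste(rep(snp$minor_allele, 2), collapse = "")
    rule[[v]] <- switch(model,
                        dominant = c(het, hom_minor),
                        recessive = hom_minor,
                        additive = c(het, hom_minor))
  }
  rule
}

#' Run the five-step association pipeline
#'
#' For each configured case group versus the shared controls: (0)
#' Hardy-Weinberg QC on controls per cohort (a failure warns, it does not
#' abort); (1) inheritance-model selection per SNP with BH adjustment;
#' (2) LD screen at the configured r-squared threshold, one MARS run per
#' strong-LD pair member (excluding its partner), each with sex as a
#' candidate predictor; (3) logistic significance filter of the proposed
#' covariates at `alpha`; (4) bootstrap inclusion fractions at `B`
#' replicates with retention above `bif_threshold`; (5) odds ratios with
#' Woolf 95% CIs for every retained covariate, plus elite/sub-elite
#' subgroup contrasts.
#'
#' @param cohort A `genotype_cohort` with at least one case group.
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list of tibbles: `hwe`, `model_choices`,
#'   `ld_pairs`, `covariates` (per split: p, BIF, retention flags),
#'   `or_table`, `subgroup_or`, and the `config` with package version.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "genotype_cohort"),
            inherits(config, "pipeline_config"))
  check_cohort_qc(cohort, config$max_missing)
  present <- intersect(config$case_groups, unique(cohort$status))
  if (length(present) == 0) stop("no case group present in cohort", call. = FALSE)
  set.seed(config$seed)
  snps <- cohort_snps(cohort)

  hwe <- hwe_cohort(cohort, controls_only = TRUE, by_cohort = TRUE)
  bad_hwe <- !hwe$monomorphic & hwe$p_value <= 0.05
  if (any(bad_hwe)) {
    warning("HWE failure in controls: ",
            paste(unique(hwe$snp_id[bad_hwe]), collapse = ", "), call. = FALSE)
  }

  choices_all <- list(); cov_all <- list(); or_all <- list(); sub_all <- list()
  ld_all <- list()
  for (grp in present) {
    sub <- cohort[cohort$status %in% c(grp, "control"), ]
    outcome <- as.numeric(sub$status == grp)
    choices <- dplyr::mutate(select_models(sub, grp), case_group = grp,
                             .before = 1)
    choices_all[[grp]] <- choices
    ld_pairs <- strong_ld_pairs(sub, config$ld_threshold)
    ld_all[[grp]] <- dplyr::mutate(ld_pairs, case_group = grp, .before = 1)
    splits <- ld_splits(snps$id, ld_pairs)
    for (sp in names(splits)) {
      design <- encoded_design(sub, choices, snp_ids = splits[[sp]],
                               include_sex = TRUE)
      cc <- stats::complete.cases(design)
      model <- mars_fit(design[cc, , drop = FALSE], outcome[cc],
                        max_basis = config$max_basis,
                        max_degree = config$max_degree,
                        penalty = config$penalty)
      proposed <- propose_covariates(model)$identity
      if (config$force_sex) proposed <- union(proposed, "sex")
      decisions <- filter_covariates(design[cc, , drop = FALSE], outcome[cc],
                                     proposed, alpha = config$alpha)
      retained3 <- decisions$identity[decisions$retained_step3]
      if (length(retained3) > 0) {
        bif <- bootstrap_inclusion_fraction(
          design[cc, , drop = FALSE], outcome[cc], retained3,
          B = config$B, threshold = config$bif_threshold,
          stratified = config$stratified_bootstrap, count = config$bif_count,
          alpha = config$alpha, max_basis = config$max_basis,
          max_degree = config$max_degree, penalty = config$penalty)
        decisions <- dplyr::left_join(decisions, bif, by = "identity")
      } else {
        decisions$appearances <- NA_integer_
        decisions$b_effective <- NA_integer_
        decisions$bif <- NA_real_
        decisions$retained_step4 <- FALSE
      }
      decisions$retained_step4[is.na(decisions$retained_step4)] <- FALSE
      cov_all[[paste(grp, sp)]] <- dplyr::mutate(decisions, case_group = grp,
                                                 split = sp, .before = 1)
      final <- decisions$identity[decisions$retained_step3 &
                                    decisions$retained_step4]
      for (id in final) {
        rule <- rule_for_identity(id, choices, snps)
        or_all[[paste(grp, sp, id)]] <- dplyr::mutate(
          odds_ratio_for_rule(sub, rule, grp),
          case_group = grp, split = sp, covariate = id, .before = 1)
        sub_or <- subgroup_odds_ratios(sub, rule, grp)
        if (nrow(sub_or) > 0) {
          sub_all[[paste(grp, sp, id)]] <- dplyr::mutate(
            sub_or, case_group = grp, split = sp, covariate = id, .before = 1)
        }
      }
    }
  }
  model_choices <- dplyr::bind_rows(choices_all)
  if (config$fdr_family == "pooled" && length(present) > 1) {
    model_choices$adjusted_p <- bh_adjust(model_choices$wald_p)$adjusted_p
  }
  or_tab <- dplyr::bind_rows(or_all)
  if (nrow(or_tab) == 0) {
    or_tab <- tibble::tibble(case_group = character(), split = character(),
                             covariate = character(), or = numeric(),
                             ci_low = numeric(), ci_high = numeric())
  }
  sub_tab <- dplyr::bind_rows(sub_all)
  if (nrow(sub_tab) == 0) {
    sub_tab <- dplyr::mutate(or_tab[0, ], level = character())
  }
  structure(list(
    hwe = hwe,
    model_choices = model_choices,
    ld_pairs = dplyr::bind_rows(ld_all),
    covariates = dplyr::bind_rows(cov_all),
    or_table = or_tab,
    subgroup_or = sub_tab,
    config = config,
    version = as.character(utils::packageVersion("marsbif"))
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> case group(s): ",
      paste(unique(x$model_choices$case_group), collapse = ", "), "\n", sep = "")
  cat("-- model choices --\n")
  print(x$model_choices[, c("case_group", "snp_id", "model", "wald_p",
                            "adjusted_p")])
  if (nrow(x$ld_pairs) > 0) {
    cat("-- strong LD pairs --\n"); print(x$ld_pairs)
  }
  cat("-- covariates --\n")
  if (nrow(x$covariates) > 0) {
    print(x$covariates[, c("case_group", "split", "identity", "logistic_p",
                           "bif", "retained_step3", "retained_step4")])
  } else cat("  (none proposed)\n")
  if (nrow(x$or_table) > 0) {
    cat("-- odds ratios (retained covariates) --\n")
    print(x$or_table[, c("case_group", "covariate", "or", "ci_low", "ci_high",
                         "exposure_label")])
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (all tables plus configuration and seed, so the run
#' is regenerable) and one TSV per table.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("hwe", "model_choices", "ld_pairs", "covariates", "or_table",
            "subgroup_or")
  for (t in tabs) {
    tab <- report[[t]]
    tab <- tab[, !vapply(tab, is.list, logical(1)), drop = FALSE]
    readr::write_tsv(tab, file.path(dir, paste0(t, ".tsv")), progress = FALSE)
  }
  payload <- c(lapply(stats::setNames(tabs, tabs), function(t) {
    tab <- report[[t]]
    tab[, !vapply(tab, is.list, logical(1)), drop = FALSE]
  }), list(config = unclass(report$config), version = report$version))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
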