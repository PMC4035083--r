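inheritance_models <- c("additive", "dominant", "recessive")

#' Encode genotypes under an inheritance model
#'
#' Additive codes the minor-allele copy count (0/1/2); dominant codes
#' carrier status of the minor allele (0/1); recessive codes minor-allele
#' homozygosity (0/1). Missing genotypes encode to `NA` and are excluded
#' from downstream fits.
#'
#' @param genotypes Normalised genotype string vector.
#' @param snp One-row SNP definition.
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @return Numeric vector of codes.
#' @export
#' @examples
#' s <- snp_def("rs1", "A", "G")
#' encode_genotype(c("AA", "AG", "GG"), s, "dominant") # 0 1 1
encode_genotype <- function(genotypes, snp, model) {
  model <- match.arg(model, inheritance_models)
  cnt <- minor_allele_count(genotypes, snp)
  switch(model,
         additive = cnt,
         dominant = as.numeric(cnt >= 1),
         recessive = as.numeric(cnt == 2))
}

# Wald p for the genotype slope under one encoding; NA when the encoding is
# degenerate (zero variance) in the analysis subset.
model_wald_p <- function(code, outcome) {
  keep <- !is.na(code)
  code <- code[keep]; outcome <- outcome[keep]
  if (length(unique(code)) < 2) return(NA_real_)
  fit <- tryCatch(
    fit_logistic(cbind(intercept = 1, genotype = code), outcome),
    error = function(e) NULL)
  if (is.null(fit) || fit$separated) return(NA_real_)
  fit$coefficients$p_value[2]
}

#' Select the best inheritance model per SNP
#'
#' For each SNP, fits three single-covariate logistic regressions of
#' case/control status (case = 1) on the dominant, recessive and additive
#' encodings and keeps the model with the smallest Wald p-value.
#' Benjamini-Hochberg adjustment is applied to the per-SNP minimum p across
#' all SNPs in the analysis. Encodings with zero variance in the analysis
#' subset (e.g. no minor-allele homozygote) are skipped; a SNP with all
#' three encodings degenerate is an error. Ties in the minimum p break
#' deterministically as additive, then dominant, then recessive.
#'
#' @param cohort A `genotype_cohort`.
#' @param case_group `"sprint_power"` or `"endurance"`; compared against
#'   `status == "control"`.
#' @param snp_ids SNPs to analyse (default: all declared).
#' @return A tibble: `snp_id`, `p_additive`, `p_dominant`, `p_recessive`,
#'   `model`, `wald_p` (the minimum), `adjusted_p`, `encoding_rule`.
#' @export
select_models <- function(cohort, case_group = c("sprint_power", "endurance"),
                          snp_ids = NULL) {
  case_group <- match.arg(case_group)
  snps <- cohort_snps(cohort)
  if (is.null(snp_ids)) snp_ids <- snps$id
  collapsed <- intersect(snp_ids, attr(cohort, "collapsed_snps"))
  if (length(collapsed) > 0) {
    stop("collapsed genotype classes for ", paste(collapsed, collapse = ", "),
         ": inheritance-model encodings are not recoverable from a collapsed ",
         "fixture; use explicit genotype rules instead", call. = FALSE)
  }
  stopifnot(all(snp_ids %in% snps$id))
  data <- dplyr::filter(tibble::as_tibble(cohort),
                        .data$status %in% c(case_group, "control"))
  outcome <- as.numeric(data$status == case_group)

  rows <- purrr::map_dfr(snp_ids, function(id) {
    snp <- snps[snps$id == id, ]
    ps <- vapply(inheritance_models, function(m) {
      model_wald_p(encode_genotype(data[[id]], snp, m), outcome)
    }, numeric(1))
    if (all(is.na(ps))) {
      stop("all three inheritance encodings degenerate for ", id, call. = FALSE)
    }
    best <- inheritance_models[which.min(ps)] # preference order on ties
    rule <- switch(best,
                   additive = "minor-allele count 0/1/2",
                   dominant = "1 if >=1 minor allele",
                   recessive = "1 if homozygous minor")
    tibble::tibble(snp_id = id,
                   p_additive = ps[["additive"]],
                   p_dominant = ps[["dominant"]],
                   p_recessive = ps[["recessive"]],
                   model = best,
                   wald_p = min(ps, na.rm = TRUE),
                   encoding_rule = rule)
  })
  rows$adjusted_p <- bh_adjust(rows$wald_p)$adjusted_p
  rows
}

#' Encoded design matrix for the chosen models
#'
#' Builds the numeric predictor matrix used by the interaction search: one
#' column per SNP under its selected encoding, plus `sex` (female = 1).
#'
#' @param cohort A `genotype_cohort` (already subset to one analysis).
#' @param model_choices Output of [select_models()].
#' @param snp_ids SNPs to include (default: all in `model_choices`).
#' @param include_sex Append the sex column (default `TRUE`).
#' @return A numeric matrix with named columns; rows align with `cohort`.
#' @export
encoded_design <- function(cohort, model_choices, snp_ids = NULL,
                           include_sex = TRUE) {
  snps <- cohort_snps(cohort)
  if (is.null(snp_ids)) snp_ids <- model_choices$snp_id
  collapsed <- intersect(snp_ids, attr(cohort, "collapsed_snps"))
  if (length(collapsed) > 0) {
    stop("collapsed genotype classes for ", paste(collapsed, collapse = ", "),
         "; cannot build encoded design", call. = FALSE)
  }
  cols <- lapply(snp_ids, function(id) {
    model <- model_choices$model[model_choices$snp_id == id]
    encode_genotype(cohort[[id]], snps[snps$id == id, ], model)
  })
  names(cols) <- snp_ids
  if (include_sex) cols$sex <- as.numeric(cohort$sex == "female")
  do.call(cbind, cols)
}
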