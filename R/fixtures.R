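#' SNP definitions for the published athlete panel
#'
#' The three SNPs whose genotype counts are published with elite/sub-elite
#' splits: rs11689011 (T/C), rs4035887 (G/A) and rs1867785 (A/G),
#' major/minor as printed.
#'
#' @return A SNP definition tibble.
#' @export
athlete_panel_snps <- function() {
  snp_defs(snp_def("rs11689011", "T", "C"),
           snp_def("rs4035887", "G", "A"),
           snp_def("rs1867785", "A", "G"))
}

# One block of published counts for a single SNP in a single cohort.
# Heterozygote-or-minor-homozygote classes are published collapsed; they are
# stored under the heterozygote representative and flagged.
fixture_block <- function(cohort, snp, het_rep, hom,
                          ctrl_het, ctrl_hom,
                          end_het_elite, end_het_sub, end_hom_elite, end_hom_sub,
                          spr_het_elite, spr_het_sub, spr_hom_elite, spr_hom_sub) {
  tibble::tribble(
    ~status, ~level, ~genotype, ~n, ~collapsed,
    "control", "none", het_rep, ctrl_het, TRUE,
    "control", "none", hom, ctrl_hom, FALSE,
    "endurance", "elite", het_rep, end_het_elite, TRUE,
    "endurance", "sub_elite", het_rep, end_het_sub, TRUE,
    "endurance", "elite", hom, end_hom_elite, FALSE,
    "endurance", "sub_elite", hom, end_hom_sub, FALSE,
    "sprint_power", "elite", het_rep, spr_het_elite, TRUE,
    "sprint_power", "sub_elite", het_rep, spr_het_sub, TRUE,
    "sprint_power", "elite", hom, spr_hom_elite, FALSE,
    "sprint_power", "sub_elite", hom, spr_hom_sub, FALSE) |>
    dplyr::mutate(cohort = cohort, snp = snp, .before = 1)
}

#' Published genotype counts of the athlete panel
#'
#' Genotype counts for the three significantly associated SNPs in the
#' Russian (175 controls, 148 endurance, 246 sprint/power) and Polish
#' (428 controls, 106 endurance, 92 sprint/power) samples, with
#' elite/sub-elite splits for the athletes. The published tables collapse
#' the heterozygote and minor-homozygote classes (e.g. "GA or GG"); those
#' rows carry `collapsed = TRUE` and a heterozygote representative.
#'
#' @param cohort `"russian"`, `"polish"` or `"both"` (default).
#' @return A count tibble suitable for [fixture_from_counts()].
#' @export
athlete_genotype_counts <- function(cohort = c("both", "russian", "polish")) {
  cohort <- match.arg(cohort)
  russian <- dplyr::bind_rows(
    fixture_block("russian", "rs11689011", "TC", "TT",
                  139, 36,
                  18, 101, 7, 22,
                  97, 123, 9, 17),
    fixture_block("russian", "rs4035887", "GA", "AA",
                  130, 45,
                  19, 100, 6, 23,
                  88, 119, 18, 21),
    fixture_block("russian", "rs1867785", "AG", "AA",
                  142, 33,
                  18, 104, 7, 19,
                  98, 124, 8, 16))
  polish <- dplyr::bind_rows(
    fixture_block("polish", "rs11689011", "TC", "TT",
                  353, 75,
                  61, 35, 4, 6,
                  53, 29, 5, 5),
    fixture_block("polish", "rs4035887", "GA", "AA",
                  297, 131,
                  41, 27, 24, 14,
                  37, 25, 21, 9),
    fixture_block("polish", "rs1867785", "AG", "AA",
                  356, 72,
                  61, 35, 4, 6,
                  53, 29, 5, 5))
  switch(cohort,
         russian = russian,
         polish = polish,
         both = dplyr::bind_rows(russian, polish))
}

#' Cohort fixture rebuilt from the published genotype counts
#'
#' Expands one SNP's rows of [athlete_genotype_counts()] with
#' [fixture_from_counts()], so each individual appears exactly once and the
#' per-stratum sample sizes match the published cohort description
#' (Russian: 175 controls, 148 endurance, 246 sprint/power; Polish: 428,
#' 106, 92). Marginals for the chosen SNP are exact; joint genotypes
#' across SNPs are not published, so the fixture supports 2x2 odds-ratio
#' arithmetic but not multi-SNP model fitting.
#'
#' @inheritParams athlete_genotype_counts
#' @param snp_id Which SNP's genotype marginals to expand
#'   (default `"rs1867785"`).
#' @return A `genotype_cohort` declaring the single chosen SNP.
#' @export
athlete_cohort_fixture <- function(cohort = c("both", "russian", "polish"),
                                   snp_id = "rs1867785") {
  cohort <- match.arg(cohort)
  snps <- athlete_panel_snps()
  stopifnot(snp_id %in% snps$id)
  if (cohort == "both") {
    return(pool_cohorts(athlete_cohort_fixture("russian", snp_id),
                        athlete_cohort_fixture("polish", snp_id)))
  }
  counts <- dplyr::filter(athlete_genotype_counts(cohort), .data$snp == snp_id)
  fixture_from_counts(counts, snps[snps$id == snp_id, ])
}
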