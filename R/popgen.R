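# Minor-allele copy count (0/1/2) for a normalised genotype column.
minor_allele_count <- function(genotypes, snp) {
  hom_major <- paste0(sort(c(snp$major_allele, snp$major_allele)), collapse = "")
  hom_minor <- paste0(sort(c(snp$minor_allele, snp$minor_allele)), collapse = "")
  het <- paste0(sort(c(snp$major_allele, snp$minor_allele)), collapse = "")
  out <- rep(NA_real_, length(genotypes))
  out[genotypes == hom_major] <- 0
  out[genotypes == het] <- 1
  out[genotypes == hom_minor] <- 2
  out
}

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' Tests observed genotype counts against the proportions
#' \eqn{p^2 : 2pq : q^2} expected under random mating, with the allele
#' frequency estimated from the same counts
#' (\eqn{\hat p = (2 n_{AA} + n_{Aa}) / 2n}). One degree of freedom, no
#' continuity correction. A monomorphic input returns a flagged result with
#' `chi2 = 0` rather than an error.
#'
#' @param counts Numeric vector of three genotype counts
#'   `(n_AA, n_Aa, n_aa)` (major homozygote, heterozygote, minor homozygote).
#' @param snp_id Optional SNP label carried into the result.
#' @return A one-row tibble: `snp_id`, `chi2`, `p_value`, `monomorphic`,
#'   and list-columns `observed`, `expected`.
#' @export
#' @examples
#' hwe_test(c(25, 50, 25)) # exact HWE proportions: chi2 = 0
hwe_test <- function(counts, snp_id = NA_character_) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive", call. = FALSE)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) {
    return(tibble::tibble(snp_id = snp_id, chi2 = 0, p_value = 1,
                          monomorphic = TRUE,
                          observed = list(as.numeric(counts)),
                          expected = list(as.numeric(counts))))
  }
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  tibble::tibble(snp_id = snp_id, chi2 = chi2,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 monomorphic = FALSE,
                 observed = list(as.numeric(counts)),
                 expected = list(expected))
}

#' Hardy-Weinberg tests for every SNP of a cohort
#'
#' @param cohort A `genotype_cohort`.
#' @param controls_only Restrict to `status == "control"` (default), the
#'   usual QC convention for case-control panels.
#' @param by_cohort Run the test separately per cohort label (default).
#' @return A tibble with one row per SNP (and cohort label).
#' @export
hwe_cohort <- function(cohort, controls_only = TRUE, by_cohort = TRUE) {
  snps <- cohort_snps(cohort)
  data <- tibble::as_tibble(cohort)
  if (controls_only) data <- dplyr::filter(data, .data$status == "control")
  groups <- if (by_cohort) split(data, data$cohort) else list(pooled = data)
  purrr::imap_dfr(groups, function(d, label) {
    purrr::map_dfr(seq_len(nrow(snps)), function(i) {
      cnt <- minor_allele_count(d[[snps$id[i]]], snps[i, ])
      cnt <- cnt[!is.na(cnt)]
      res <- hwe_test(c(sum(cnt == 0), sum(cnt == 1), sum(cnt == 2)),
                      snp_id = snps$id[i])
      dplyr::mutate(res, cohort = label, .before = 1)
    })
  })
}

#' Pairwise linkage disequilibrium r-squared from unphased genotypes
#'
#' Estimates the four two-locus haplotype frequencies by
#' expectation-maximisation over the double-heterozygote phase ambiguity
#' (Hill-style gene counting), then
#' \eqn{r^2 = D^2 / (p_A(1-p_A)\,p_B(1-p_B))} with
#' \eqn{D = p_{AB} - p_A p_B}. Iteration stops when the largest haplotype
#' frequency change is below `tol` or after `max_iter` rounds.
#'
#' @param genotypes_a,genotypes_b Normalised genotype string vectors of equal
#'   length for the two SNPs.
#' @param snp_a,snp_b One-row SNP definitions for the two loci.
#' @param tol,max_iter EM convergence controls.
#' @return A one-row tibble: `snp_a`, `snp_b`, `r2`, `d`, a `haplotype_freqs`
#'   list-column (named `11`, `10`, `01`, `00` by minor-allele content), and
#'   `converged`.
#' @export
ld_r2 <- function(genotypes_a, genotypes_b, snp_a, snp_b,
                  tol = 1e-10, max_iter = 1000) {
  stopifnot(length(genotypes_a) == length(genotypes_b))
  ga <- minor_allele_count(genotypes_a, snp_a)
  gb <- minor_allele_count(genotypes_b, snp_b)
  keep <- !is.na(ga) & !is.na(gb)
  ga <- ga[keep]; gb <- gb[keep]
  if (length(ga) < 2) stop("need at least 2 individuals with both genotypes",
                           call. = FALSE)
  pa <- mean(ga) / 2
  pb <- mean(gb) / 2
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    stop("r² undefined: monomorphic SNP (",
         if (pa %in% c(0, 1)) snp_a$id else snp_b$id, ")", call. = FALSE)
  }
  n <- length(ga)
  cell <- table(factor(ga, 0:2), factor(gb, 0:2))
  # haplotype counts fixed by unambiguous cells; h = (h11, h10, h01, h00)
  # counted in copies of the minor allele at (a, b)
  base <- c(
    `11` = 2 * cell["2", "2"] + cell["2", "1"] + cell["1", "2"],
    `10` = 2 * cell["2", "0"] + cell["2", "1"] + cell["1", "0"],
    `01` = 2 * cell["0", "2"] + cell["1", "2"] + cell["0", "1"],
    `00` = 2 * cell["0", "0"] + cell["1", "0"] + cell["0", "1"]
  )
  ndh <- cell["1", "1"] # double heterozygotes: phase unknown
  f <- c(`11` = pa * pb, `10` = pa * (1 - pb), `01` = (1 - pa) * pb,
         `00` = (1 - pa) * (1 - pb))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cis <- f["11"] * f["00"]
    trans <- f["10"] * f["01"]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    h <- base + ndh * c(w, 1 - w, 1 - w, w)
    f_new <- h / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  d <- f[["11"]] - pa * pb
  r2 <- d^2 / (pa * (1 - pa) * pb * (1 - pb))
  tibble::tibble(snp_a = snp_a$id, snp_b = snp_b$id,
                 r2 = min(r2, 1), d = d,
                 haplotype_freqs = list(f), converged = converged)
}

#' All pairwise r-squared values in a cohort
#'
#' Computed on the full analysis sample (cases and controls together): the
#' LD screen's purpose here is collinearity control for the interaction
#' search, not population inference.
#'
#' @param cohort A `genotype_cohort`.
#' @return A tibble with one row per unordered SNP pair.
#' @export
ld_matrix <- function(cohort) {
  snps <- cohort_snps(cohort)
  if (nrow(snps) < 2) return(tibble::tibble(snp_a = character(), snp_b = character(),
                                            r2 = numeric()))
  pairs <- utils::combn(seq_len(nrow(snps)), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ld_r2(cohort[[snps$id[i]]], cohort[[snps$id[j]]], snps[i, ], snps[j, ]) |>
      dplyr::select("snp_a", "snp_b", "r2", "converged")
  })
}

#' SNP pairs in strong linkage disequilibrium
#'
#' @param cohort A `genotype_cohort`.
#' @param threshold r-squared cutoff in `(0, 1]`; pairs with `r2 > threshold`
#'   are returned (default 0.8).
#' @return A tibble `snp_a`, `snp_b`, `r2`.
#' @export
strong_ld_pairs <- function(cohort, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  ld_matrix(cohort) |>
    dplyr::filter(.data$r2 > threshold) |>
    dplyr::select("snp_a", "snp_b", "r2")
}
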