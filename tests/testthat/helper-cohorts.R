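# Shared fixture builders. All cohorts are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

two_snp_defs <- function() {
  snp_defs(snp_def("rs1", "A", "G"), snp_def("rs2", "T", "C"))
}

# small hand-written cohort covering both sexes, statuses and levels
toy_cohort <- function() {
  data <- tibble::tibble(
    sample_id = paste0("S", 1:8),
    cohort = rep(c("polish", "russian"), each = 4),
    sex = c("male", "male", "female", "male", "female", "male", "male", "female"),
    status = c("control", "sprint_power", "endurance", "control",
               "sprint_power", "control", "endurance", "sprint_power"),
    level = c("none", "elite", "sub_elite", "none",
              "elite", "none", "elite", "sub_elite"),
    rs1 = c("AA", "AG", "GA", "GG", "AA", "AG", "GG", "AA"),
    rs2 = c("TT", "TC", "CC", "TT", "CT", "TT", "TC", "CC"))
  genotype_cohort(data, two_snp_defs())
}

# cohort with genotypes built directly from haplotype pairs, so two-locus
# phase is known by construction (used as the EM oracle)
cohort_from_haplotypes <- function(hap_counts) {
  # hap_counts: named counts of "ab" haplotypes with a,b in 0/1 minor copies
  haps <- rep(names(hap_counts), hap_counts)
  haps <- matrix(as.integer(unlist(strsplit(haps, ""))), ncol = 2, byrow = TRUE)
  stopifnot(nrow(haps) %% 2 == 0)
  i1 <- seq(1, nrow(haps), by = 2)
  g <- haps[i1, ] + haps[i1 + 1, ]
  geno <- function(cnt, major, minor) {
    c(paste0(major, major),
      paste0(sort(c(major, minor)), collapse = ""),
      paste0(minor, minor))[cnt + 1]
  }
  data <- tibble::tibble(
    sample_id = paste0("H", seq_len(nrow(g))),
    cohort = "sim", sex = "male", status = "control", level = "none",
    rs1 = geno(g[, 1], "A", "G"),
    rs2 = vapply(g[, 2] + 1,
                 function(k) c("TT", "CT", "CC")[k], character(1)))
  genotype_cohort(data, two_snp_defs())
}

# design matrix + outcome with one planted log-OR effect on a binary column
planted_logistic_design <- function(n, beta, maf = 0.3, extra_null = 2) {
  x <- stats::rbinom(n, 1, maf)
  nulls <- matrix(stats::rbinom(n * extra_null, 1, 0.4), ncol = extra_null)
  colnames(nulls) <- paste0("null", seq_len(extra_null))
  eta <- -0.7 + beta * x
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  list(design = cbind(target = x, nulls), outcome = y)
}
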