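#' Simulation configuration for a synthetic case-control cohort
#'
#' Defaults emulate the structure of a two-cohort athlete panel: five
#' biallelic SNPs whose frequencies mirror the pooled control genotype
#' distribution, one pair in near-perfect LD (target r-squared 0.96), a
#' mostly-male sample, 338 cases and 603 controls, and a logistic case
#' model with a carrier main effect at the LD pair and a two-SNP
#' interaction (odds ratios about 1.9 and 0.61 on their encodings).
#'
#' @param n_cases,n_controls Individuals to simulate per arm.
#' @param snps SNP definition tibble ([snp_defs()]).
#' @param minor_freqs Named vector of minor-allele frequencies (declared
#'   minor allele; values above 0.5 are allowed and simply mean the
#'   declared minor allele is the commoner one, as in the panel emulated).
#' @param ld_targets Tibble `snp_a`, `snp_b`, `r2` of target pairwise LD;
#'   untargeted pairs are at linkage equilibrium.
#' @param effects Tibble `snp_a`, `model_a`, `snp_b`, `model_b`, `beta`:
#'   each row adds `beta` times the (product of the) encoded genotype(s)
#'   to the case log-odds. `snp_b = "sex"` uses the female indicator;
#'   `snp_b = NA` is a main effect.
#' @param sex_ratio Proportion female.
#' @param baseline_logit Intercept of the case model.
#' @param case_status,elite_ratio Status label given to cases and the
#'   proportion of cases labelled elite.
#' @param seed RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    n_cases = 338, n_controls = 603,
    snps = snp_defs(
      snp_def("rs1867785", "A", "G"),
      snp_def("rs11689011", "T", "C"),
      snp_def("rs895436", "C", "G"),
      snp_def("rs4035887", "G", "A"),
      snp_def("rs1867782", "C", "A")),
    minor_freqs = c(rs1867785 = 0.58, rs11689011 = 0.58, rs895436 = 0.35,
                    rs4035887 = 0.54, rs1867782 = 0.30),
    ld_targets = tibble::tibble(snp_a = "rs1867785", snp_b = "rs11689011",
                                r2 = 0.96),
    effects = tibble::tibble(
      snp_a = c("rs1867785", "rs4035887"),
      model_a = c("dominant", "recessive"),
      snp_b = c(NA, "rs1867785"),
      model_b = c(NA, "dominant"),
      beta = c(log(1 / 0.53), log(0.61))),
    sex_ratio = 0.13, baseline_logit = -1,
    case_status = "sprint_power", elite_ratio = 0.45, seed = 1L) {
  stopifnot(n_cases > 0, n_controls > 0,
            all(minor_freqs > 0 & minor_freqs < 1),
            all(names(minor_freqs) %in% snps$id),
            sex_ratio >= 0, sex_ratio <= 1)
  structure(list(n_cases = n_cases, n_controls = n_controls, snps = snps,
                 minor_freqs = minor_freqs, ld_targets = ld_targets,
                 effects = effects, sex_ratio = sex_ratio,
                 baseline_logit = baseline_logit, case_status = case_status,
                 elite_ratio = elite_ratio, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Haplotype pool with configured pairwise LD
#'
#' Builds the joint distribution over full-length haplotypes (minor allele
#' coded 1) such that every targeted pair attains
#' \eqn{D = \sqrt{r^2\, p_a q_a\, p_b q_b}} (positive association between
#' the two minor alleles) and every untargeted pair is at linkage
#' equilibrium. Target pairs must form a forest; the joint distribution is
#' assembled by chaining the pairwise conditionals through that dependency
#' tree. An infeasible target errors with the attainable bound
#' \eqn{r^2_{max} = \min(p_a q_b / (q_a p_b),\; q_a p_b / (p_a q_b))}.
#'
#' @param minor_freqs Named vector of minor-allele frequencies.
#' @param ld_targets Tibble `snp_a`, `snp_b`, `r2` (may be empty).
#' @return A tibble with one 0/1 column per SNP and a `prob` column
#'   summing to 1.
#' @export
#' @examples
#' simulate_haplotype_pool(c(a = 0.5, b = 0.5),
#'                         tibble::tibble(snp_a = "a", snp_b = "b", r2 = 0.36))
simulate_haplotype_pool <- function(minor_freqs,
                                    ld_targets = tibble::tibble(
                                      snp_a = character(), snp_b = character(),
                                      r2 = numeric())) {
  ids <- names(minor_freqs)
  stopifnot(!is.null(ids), all(ld_targets$snp_a %in% ids),
            all(ld_targets$snp_b %in% ids),
            all(ld_targets$r2 >= 0 & ld_targets$r2 <= 1))
  # forest check by union-find
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  pair_joint <- list()
  for (k in seq_len(nrow(ld_targets))) {
    a <- ld_targets$snp_a[k]; b <- ld_targets$snp_b[k]; r2 <- ld_targets$r2[k]
    if (find(a) == find(b)) stop("cyclic ld_targets", call. = FALSE)
    parent[find(a)] <- find(b)
    pa <- minor_freqs[[a]]; pb <- minor_freqs[[b]]
    qa <- 1 - pa; qb <- 1 - pb
    r2_max <- min(pa * qb / (qa * pb), qa * pb / (pa * qb))
    if (r2 > r2_max + 1e-12) {
      stop("target r² = ", r2, " for (", a, ", ", b,
           ") infeasible; attainable bound is ", signif(r2_max, 6), call. = FALSE)
    }
    d <- sqrt(r2 * pa * qa * pb * qb)
    pair_joint[[paste(a, b, sep = "|")]] <-
      c(`11` = pa * pb + d, `10` = pa * qb - d, `01` = qa * pb - d,
        `00` = qa * qb + d)
  }
  # adjacency for tree traversal
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(ld_targets))) {
    a <- ld_targets$snp_a[k]; b <- ld_targets$snp_b[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  hap <- as.matrix(expand.grid(rep(list(c(0, 1)), length(ids)),
                               KEEP.OUT.ATTRS = FALSE))
  colnames(hap) <- ids
  prob <- rep(1, nrow(hap))
  visited <- character(0)
  for (root in ids) {
    if (root %in% visited) next
    p_root <- minor_freqs[[root]]
    prob <- prob * ifelse(hap[, root] == 1, p_root, 1 - p_root)
    queue <- root; visited <- c(visited, root)
    while (length(queue) > 0) {
      node <- queue[1]; queue <- queue[-1]
      for (child in setdiff(adj[[node]], visited)) {
        key1 <- paste(node, child, sep = "|")
        j <- if (key1 %in% names(pair_joint)) pair_joint[[key1]] else {
          # stored as (child, node); transpose the 2x2
          jj <- pair_joint[[paste(child, node, sep = "|")]]
          c(`11` = jj[["11"]], `10` = jj[["01"]], `01` = jj[["10"]],
            `00` = jj[["00"]])
        }
        p_node <- minor_freqs[[node]]
        # key = (node allele, child allele); j indexed (node, child)
        cond <- c(`11` = j[["11"]] / p_node, `10` = j[["10"]] / p_node,
                  `01` = j[["01"]] / (1 - p_node), `00` = j[["00"]] / (1 - p_node))
        key <- paste0(hap[, node], hap[, child])
        prob <- prob * cond[key]
        visited <- c(visited, child); queue <- c(queue, child)
      }
    }
  }
  out <- tibble::as_tibble(as.data.frame(hap))
  out$prob <- as.numeric(prob)
  stopifnot(abs(sum(out$prob) - 1) < 1e-9, all(out$prob > -1e-12))
  out$prob <- pmax(out$prob, 0)
  out
}

# encoded value of one effect row given minor-allele count matrices
effect_column <- function(eff_row, counts, sex_female) {
  enc <- function(snp, model) {
    cnt <- counts[, snp]
    switch(model,
           additive = cnt,
           dominant = as.numeric(cnt >= 1),
           recessive = as.numeric(cnt == 2))
  }
  col <- enc(eff_row$snp_a, eff_row$model_a)
  if (!is.na(eff_row$snp_b)) {
    col <- col * if (eff_row$snp_b == "sex") sex_female else {
      enc(eff_row$snp_b, eff_row$model_b)
    }
  }
  col
}

#' Simulate a genotype cohort under a logistic case model
#'
#' Each individual receives two haplotypes drawn independently from the
#' configured pool (Hardy-Weinberg by construction within haplotype
#' classes), a sex, and a case probability
#' `plogis(baseline_logit + sum of effect terms)`; individuals are then
#' accepted by rejection sampling until the case and control quotas are
#' filled — the retrospective sampling scheme whose exposure odds ratios
#' the pipeline estimates. Fully seeded and reproducible.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_cohort` list: `cohort` (a `genotype_cohort`),
#'   `truth` (the config), and `attained_ld` (realised r-squared per
#'   targeted pair, computed by [ld_r2()] on the output).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  pool <- simulate_haplotype_pool(config$minor_freqs, config$ld_targets)
  ids <- config$snps$id
  hap_mat <- as.matrix(pool[, ids])
  want_cases <- config$n_cases; want_controls <- config$n_controls
  rows_case <- list(); rows_control <- list()
  got_cases <- 0L; got_controls <- 0L
  draws <- 0L
  chunk <- 2000L
  while (got_cases < want_cases || got_controls < want_controls) {
    if (draws > 1e6) {
      stop("rejection sampling exceeded 10^6 draws; adjust baseline_logit",
           call. = FALSE)
    }
    h1 <- sample.int(nrow(pool), chunk, replace = TRUE, prob = pool$prob)
    h2 <- sample.int(nrow(pool), chunk, replace = TRUE, prob = pool$prob)
    counts <- hap_mat[h1, , drop = FALSE] + hap_mat[h2, , drop = FALSE]
    female <- stats::rbinom(chunk, 1, config$sex_ratio)
    logit <- rep(config$baseline_logit, chunk)
    for (k in seq_len(nrow(config$effects))) {
      logit <- logit + config$effects$beta[k] *
        effect_column(config$effects[k, ], counts, female)
    }
    is_case <- stats::rbinom(chunk, 1, stats::plogis(logit)) == 1
    draws <- draws + chunk
    take_case <- which(is_case)[seq_len(min(sum(is_case), want_cases - got_cases))]
    take_ctrl <- which(!is_case)[seq_len(min(sum(!is_case),
                                             want_controls - got_controls))]
    keep <- c(take_case, take_ctrl)
    if (length(keep) > 0) {
      rows_case <- c(rows_case, list(cbind(counts[take_case, , drop = FALSE],
                                           female = female[take_case])))
      rows_control <- c(rows_control, list(cbind(counts[take_ctrl, , drop = FALSE],
                                                 female = female[take_ctrl])))
      got_cases <- got_cases + length(take_case)
      got_controls <- got_controls + length(take_ctrl)
    }
  }
  cases <- do.call(rbind, rows_case)
  controls <- do.call(rbind, rows_control)
  all_rows <- rbind(cases, controls)
  n <- nrow(all_rows)
  geno_cols <- lapply(seq_along(ids), function(i) {
    snp <- config$snps[i, ]
    cnt <- all_rows[, ids[i]]
    c(paste0(sort(rep(snp$major_allele, 2)), collapse = ""),
      paste0(sort(c(snp$major_allele, snp$minor_allele)), collapse = ""),
      paste0(sort(rep(snp$minor_allele, 2)), collapse = ""))[cnt + 1]
  })
  names(geno_cols) <- ids
  n_cases <- nrow(cases)
  status <- rep(c(config$case_status, "control"), c(n_cases, nrow(controls)))
  level <- ifelse(status == "control", "none",
                  ifelse(stats::runif(n) < config$elite_ratio, "elite", "sub_elite"))
  data <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("sim_%05d", seq_len(n)),
                   cohort = "simulated",
                   sex = ifelse(all_rows[, "female"] == 1, "female", "male"),
                   status = status, level = level),
    tibble::as_tibble(geno_cols))
  cohort <- genotype_cohort(data, config$snps, normalize = FALSE)
  attained <- purrr::map_dfr(seq_len(nrow(config$ld_targets)), function(k) {
    a <- config$ld_targets$snp_a[k]; b <- config$ld_targets$snp_b[k]
    res <- ld_r2(cohort[[a]], cohort[[b]],
                 config$snps[config$snps$id == a, ],
                 config$snps[config$snps$id == b, ])
    tibble::tibble(snp_a = a, snp_b = b,
                   target_r2 = config$ld_targets$r2[k], attained_r2 = res$r2)
  })
  structure(list(cohort = cohort, truth = config, attained_ld = attained),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("<simulated_cohort> ", nrow(x$cohort), " individuals (seed ",
      x$truth$seed, ")\n", sep = "")
  if (nrow(x$attained_ld) > 0) print(x$attained_ld)
  invisible(x)
}

#' Expand a published genotype-count table into a cohort
#'
#' Deterministically rebuilds per-individual records from marginal genotype
#' counts (one SNP at a time; the other SNPs are set missing), so that 2x2
#' odds-ratio arithmetic on published tables can be recomputed exactly.
#' Collapsed genotype classes (e.g. a count published as "GA or GG") are
#' stored under a representative genotype and flagged; analyses whose
#' encoding is not invariant to the collapse (the additive model) refuse
#' such SNPs.
#'
#' @param count_table Tibble with columns `cohort`, `status`, `level`
#'   (`"none"` for controls, `"all"` when no level split is published),
#'   `snp`, `genotype` (representative, order-insensitive), `n`, and
#'   optionally `collapsed` (logical) and `sex`.
#' @param snps SNP definition tibble covering every `snp` value.
#' @return A `genotype_cohort`; SNPs with any collapsed class are recorded
#'   in its `collapsed_snps` attribute.
#' @export
fixture_from_counts <- function(count_table, snps) {
  if (nrow(count_table) == 0) {
    empty <- tibble::as_tibble(stats::setNames(
      rep(list(character(0)), 5 + nrow(snps)), c(phenotype_cols, snps$id)))
    return(genotype_cohort(empty, snps, normalize = FALSE))
  }
  stopifnot(all(count_table$n >= 0), all(count_table$snp %in% snps$id))
  if (!"collapsed" %in% names(count_table)) count_table$collapsed <- FALSE
  if (!"sex" %in% names(count_table)) count_table$sex <- "male"
  rows <- purrr::map_dfr(seq_len(nrow(count_table)), function(i) {
    r <- count_table[i, ]
    if (r$n == 0) return(NULL)
    level <- if (r$level == "all") "sub_elite" else r$level
    if (r$status == "control") level <- "none"
    d <- tibble::tibble(cohort = r$cohort, sex = r$sex, status = r$status,
                        level = level)[rep(1, r$n), ]
    for (id in snps$id) d[[id]] <- if (id == r$snp) r$genotype else NA_character_
    d
  })
  rows <- dplyr::mutate(rows, sample_id = sprintf("fx_%05d", dplyr::row_number()),
                        .before = 1)
  cohort <- genotype_cohort(rows, snps, normalize = TRUE)
  attr(cohort, "collapsed_snps") <-
    unique(count_table$snp[count_table$collapsed])
  cohort
}
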