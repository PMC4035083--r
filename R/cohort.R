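#' Declare a biallelic SNP
#'
#' @param id SNP identifier (e.g. `"rs1867785"`).
#' @param major_allele,minor_allele Single characters in `A`, `C`, `G`, `T`;
#'   must differ.
#'
#' @return A one-row tibble with columns `id`, `major_allele`, `minor_allele`.
#' @export
#' @examples
#' snp_def("rs1867785", "A", "G")
snp_def <- function(id, major_allele, minor_allele) {
  stopifnot(is.character(id), length(id) == 1L)
  alleles <- c(major_allele, minor_allele)
  if (!all(alleles %in% c("A", "C", "G", "T"))) {
    stop("alleles must be single characters in {A,C,G,T}", call. = FALSE)
  }
  if (major_allele == minor_allele) {
    stop("major and minor allele must differ for ", id, call. = FALSE)
  }
  tibble::tibble(id = id, major_allele = major_allele, minor_allele = minor_allele)
}

#' Bind several SNP definitions into one table
#'
#' @param ... One-row tibbles from [snp_def()], or a single list of them.
#' @return A tibble with one row per SNP.
#' @export
snp_defs <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && !is.data.frame(dots[[1]])) {
    dots <- dots[[1]]
  }
  out <- dplyr::bind_rows(dots)
  if (anyDuplicated(out$id)) stop("duplicated SNP ids", call. = FALSE)
  out
}

phenotype_cols <- c("sample_id", "cohort", "sex", "status", "level")
missing_tokens <- c("", "NA", "--", ".", "./.")

#' Normalise a vector of genotype strings for one SNP
#'
#' Genotypes are two adjacent allele characters, order-insensitive
#' (`"AG"` and `"GA"` are the same genotype and are both stored with the
#' alleles sorted). `"NA"`, `""`, `"--"` and `NA` map to missing.
#'
#' @param x Character vector of raw genotype strings.
#' @param snp One row of a SNP definition table.
#' @param context Label used in error messages (e.g. a file name).
#' @return Character vector of normalised genotypes (`NA` for missing).
#' @keywords internal
normalize_genotypes <- function(x, snp, context = "genotype") {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  miss <- is.na(x) | trimws(x) %in% missing_tokens
  x <- trimws(x)
  ok_shape <- !miss & grepl("^[ACGT]{2}$", x)
  bad_shape <- !miss & !ok_shape
  if (any(bad_shape)) {
    warning(sum(bad_shape), " unparseable genotype string(s) for ", snp$id,
            " in ", context, " set to missing", call. = FALSE)
  }
  if (any(ok_shape)) {
    a1 <- substr(x[ok_shape], 1, 1)
    a2 <- substr(x[ok_shape], 2, 2)
    declared <- c(snp$major_allele, snp$minor_allele)
    bad <- !(a1 %in% declared) | !(a2 %in% declared)
    if (any(bad)) {
      row <- which(ok_shape)[which(bad)[1]]
      stop("unknown allele in genotype '", x[ok_shape][which(bad)[1]],
           "' for SNP ", snp$id, " (row ", row, " of ", context,
           "); declared alleles are ", declared[1], "/", declared[2],
           call. = FALSE)
    }
    sorted <- ifelse(a1 <= a2, paste0(a1, a2), paste0(a2, a1))
    out[ok_shape] <- sorted
  }
  out
}

#' Construct a genotype cohort
#'
#' A genotype cohort is a tibble with one row per individual: phenotype
#' columns `sample_id`, `cohort`, `sex`, `status`, `level`, then one column
#' per SNP holding a normalised genotype string (or `NA`). SNP definitions
#' travel with the tibble as the `"snps"` attribute.
#'
#' @param data A data frame with the phenotype columns and one column per
#'   declared SNP.
#' @param snps A SNP definition table from [snp_defs()].
#' @param normalize Normalise genotype strings (default `TRUE`); set `FALSE`
#'   when `data` is already normalised.
#'
#' @return A `genotype_cohort` tibble.
#' @export
genotype_cohort <- function(data, snps, normalize = TRUE) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c(phenotype_cols, snps$id), names(data))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(data$sample_id)) {
    dup <- data$sample_id[duplicated(data$sample_id)][1]
    stop("duplicated sample id: ", dup, call. = FALSE)
  }
  bad_sex <- !data$sex %in% c("male", "female")
  if (any(bad_sex)) stop("sex must be 'male' or 'female'", call. = FALSE)
  if (!all(data$status %in% c("control", "endurance", "sprint_power"))) {
    stop("status must be control, endurance or sprint_power", call. = FALSE)
  }
  if (!all(data$level %in% c("elite", "sub_elite", "none"))) {
    stop("level must be elite, sub_elite or none", call. = FALSE)
  }
  if (any(data$status == "control" & data$level != "none")) {
    stop("controls must have level 'none'", call. = FALSE)
  }
  data <- data[, c(phenotype_cols, snps$id)]
  if (normalize) {
    for (i in seq_len(nrow(snps))) {
      id <- snps$id[i]
      data[[id]] <- normalize_genotypes(data[[id]], snps[i, ], context = "data")
    }
  }
  structure(data,
            snps = snps,
            class = c("genotype_cohort", class(tibble::tibble())))
}

#' SNP definitions attached to a cohort
#' @param cohort A `genotype_cohort`.
#' @return The SNP definition tibble.
#' @export
cohort_snps <- function(cohort) attr(cohort, "snps")

#' @export
print.genotype_cohort <- function(x, ...) {
  snps <- cohort_snps(x)
  cat("<genotype_cohort> ", nrow(x), " individuals, ", nrow(snps), " SNPs (",
      paste(snps$id, collapse = ", "), ")\n", sep = "")
  NextMethod()
}

# dplyr/[ operations drop the subclass by design; re-attach with
# genotype_cohort() if needed. Row subsetting keeps the attribute.
#' @export
`[.genotype_cohort` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c(phenotype_cols, cohort_snps(x)$id) %in% names(out))) {
    attr(out, "snps") <- cohort_snps(x)
    class(out) <- class(x)
  }
  out
}

#' Per-SNP missingness of a cohort
#'
#' @param cohort A `genotype_cohort`.
#' @return A tibble with columns `snp_id`, `n_missing`, `rate`.
#' @export
missingness <- function(cohort) {
  snps <- cohort_snps(cohort)
  purrr::map_dfr(snps$id, function(id) {
    tibble::tibble(snp_id = id,
                   n_missing = sum(is.na(cohort[[id]])),
                   rate = mean(is.na(cohort[[id]])))
  })
}

#' Quality-control check on a cohort
#'
#' Fails (errors) when any SNP's missingness exceeds the ceiling. A call
#' rate below 100% is a data-quality signal in assay panels of this kind,
#' so the default ceiling is strict.
#'
#' @param cohort A `genotype_cohort`.
#' @param max_missing Per-SNP missingness ceiling (default 0.05).
#' @return Invisibly, the missingness table.
#' @export
check_cohort_qc <- function(cohort, max_missing = 0.05) {
  miss <- missingness(cohort)
  bad <- miss$rate > max_missing
  if (any(bad)) {
    stop("QC failure: missingness above ", max_missing, " for ",
         paste(miss$snp_id[bad], collapse = ", "), call. = FALSE)
  }
  invisible(miss)
}

#' Read a genotype table
#'
#' Reads the tab-separated genotype dialect: columns `sample_id`, `cohort`,
#' `sex`, `status`, `level`, then one column per SNP id; `#` lines are
#' skipped. Genotype strings are normalised to unordered pairs; unparseable
#' strings become missing with a warning; an allele outside the SNP's
#' declared pair is a hard error naming the row and SNP.
#'
#' @param path Path to the TSV file.
#' @param snps A SNP definition table from [snp_defs()].
#' @return A `genotype_cohort`.
#' @export
read_genotype_table <- function(path, snps) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(c(phenotype_cols, snps$id), names(raw))
  if (length(missing_cols) > 0) {
    stop("header of ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(snps))) {
    id <- snps$id[i]
    raw[[id]] <- normalize_genotypes(raw[[id]], snps[i, ], context = path)
  }
  genotype_cohort(raw, snps, normalize = FALSE)
}

#' Write a genotype table
#'
#' @param cohort A `genotype_cohort`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_genotype_table <- function(cohort, path) {
  readr::write_tsv(tibble::as_tibble(cohort), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Pool several cohorts into one
#'
#' Individuals are concatenated with their cohort labels preserved, so
#' per-stratum genotype counts are additive. All cohorts must declare the
#' same SNPs with the same alleles.
#'
#' @param ... `genotype_cohort` objects, or a single list of them.
#' @return A pooled `genotype_cohort`. Sample ids are de-duplicated with
#'   numeric suffixes when cohorts overlap.
#' @export
pool_cohorts <- function(...) {
  cohorts <- list(...)
  if (length(cohorts) == 1L && !inherits(cohorts[[1]], "genotype_cohort")) {
    cohorts <- cohorts[[1]]
  }
  stopifnot(length(cohorts) >= 1)
  canon <- function(s) dplyr::arrange(s, .data$id)
  ref <- canon(cohort_snps(cohorts[[1]]))
  for (ch in cohorts[-1]) {
    if (!identical(canon(cohort_snps(ch)), ref)) {
      stop("allele definitions differ between cohorts; cannot pool", call. = FALSE)
    }
  }
  snps <- cohort_snps(cohorts[[1]])
  data <- dplyr::bind_rows(lapply(cohorts, tibble::as_tibble))
  data$sample_id <- make.unique(data$sample_id, sep = "_dup")
  out <- genotype_cohort(data, snps, normalize = FALSE)
  collapsed <- unique(unlist(lapply(cohorts, attr, "collapsed_snps")))
  if (length(collapsed) > 0) attr(out, "collapsed_snps") <- collapsed
  out
}

#' Read a subset of sites from a VCF into a cohort
#'
#' Pulls the `GT` field for the requested SNP ids (matched against the VCF
#' `ID` column) and joins phenotypes from a sample-sheet TSV with columns
#' `sample_id`, `cohort`, `sex`, `status`, `level`. Diploid genotypes are
#' translated to allele pairs; half-calls and `./.` become missing.
#' Multi-allelic requested sites are an error.
#'
#' @param path Path to a VCF 4.x file (plain text).
#' @param snp_ids SNP ids to extract.
#' @param sample_sheet Path to the phenotype TSV.
#' @return A `genotype_cohort`.
#' @export
read_vcf_subset <- function(path, snp_ids, sample_sheet) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_subset requires the vcfR package", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  keep <- fix$ID %in% snp_ids
  if (!all(snp_ids %in% fix$ID)) {
    stop("VCF lacks requested sites: ",
         paste(setdiff(snp_ids, fix$ID), collapse = ", "), call. = FALSE)
  }
  fix <- fix[keep, , drop = FALSE]
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    stop("multi-allelic site(s) among requested SNPs: ",
         paste(fix$ID[multi], collapse = ", "), call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  pheno <- readr::read_tsv(sample_sheet, comment = "#",
                           col_types = readr::cols(.default = "c"), progress = FALSE)
  samples <- colnames(gt)
  if (!all(samples %in% pheno$sample_id)) {
    stop("sample sheet lacks entries for: ",
         paste(setdiff(samples, pheno$sample_id), collapse = ", "), call. = FALSE)
  }
  pheno <- pheno[match(samples, pheno$sample_id), ]
  snps <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    # REF taken as major allele by convention; the distinction only matters
    # for encodings, which consult observed frequencies downstream anyway
    snp_def(fix$ID[i], fix$REF[i], fix$ALT[i])
  })
  geno_cols <- purrr::map(seq_len(nrow(fix)), function(i) {
    g <- gt[i, ]
    alleles <- c(fix$REF[i], fix$ALT[i])
    parts <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    unname(vapply(parts, function(p) {
      if (length(p) != 2 || any(is.na(p)) || any(!p %in% c("0", "1"))) {
        return(NA_character_)
      }
      a <- sort(alleles[as.integer(p) + 1])
      paste0(a[1], a[2])
    }, character(1)))
  })
  names(geno_cols) <- fix$ID
  data <- dplyr::bind_cols(pheno[, phenotype_cols], tibble::as_tibble(geno_cols))
  genotype_cohort(data, snps, normalize = FALSE)
}

#' Genotype counts by stratum
#'
#' @param cohort A `genotype_cohort`.
#' @param snp_id One SNP id.
#' @param by Grouping columns (default `status`).
#' @return A tibble of counts per genotype per stratum (missing excluded).
#' @export
count_genotypes <- function(cohort, snp_id, by = "status") {
  stopifnot(snp_id %in% cohort_snps(cohort)$id)
  tibble::as_tibble(cohort) |>
    dplyr::filter(!is.na(.data[[snp_id]])) |>
    dplyr::count(dplyr::across(dplyr::all_of(by)), genotype = .data[[snp_id]],
                 name = "n")
}
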