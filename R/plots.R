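#' Linkage-disequilibrium heatmap
#'
#' @param cohort A `genotype_cohort`, or a tibble from [ld_matrix()].
#' @return A ggplot object (tile map of pairwise r-squared).
#' @export
plot_ld_heatmap <- function(cohort) {
  ld <- if (inherits(cohort, "genotype_cohort")) ld_matrix(cohort) else cohort
  both <- dplyr::bind_rows(
    ld,
    dplyr::rename(ld, snp_a = "snp_b", snp_b = "snp_a"),
    tibble::tibble(snp_a = unique(c(ld$snp_a, ld$snp_b)),
                   snp_b = unique(c(ld$snp_a, ld$snp_b)), r2 = 1))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$snp_a, y = .data$snp_b,
                                     fill = .data$r2)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r2)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "#fff7ec", high = "#d7301f",
                                 limits = c(0, 1), name = expression(r^2)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Pairwise linkage disequilibrium") +
    ggplot2::theme_minimal()
}

#' Genotype distribution bars per stratum
#'
#' @param cohort A `genotype_cohort`.
#' @param snp_id One SNP id.
#' @return A ggplot object: within-stratum genotype proportions.
#' @export
plot_genotype_distribution <- function(cohort, snp_id) {
  counts <- count_genotypes(cohort, snp_id, by = "status")
  counts <- dplyr::mutate(dplyr::group_by(counts, .data$status),
                          prop = .data$n / sum(.data$n))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$status, y = .data$prop,
                                       fill = .data$genotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "genotype frequency", title = snp_id) +
    ggplot2::theme_minimal()
}

#' Forest plot of an odds-ratio table
#'
#' @param object A tibble from [or_table()] or the `or_table` element of a
#'   pipeline report (columns `covariate`, `or`, `ci_low`, `ci_high`, and
#'   optionally `level`).
#' @param ... Unused.
#' @return A ggplot object on a log odds-ratio axis.
#' @method autoplot or_table
#' @export
autoplot.or_table <- function(object, ...) {
  d <- tibble::as_tibble(object)
  if (!"level" %in% names(d)) d$level <- "all"
  d$label <- paste0(d$covariate, " [", d$level, "]")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of the retained covariates of a pipeline report
#'
#' @param object A `pipeline_report`.
#' @param ... Unused.
#' @method autoplot pipeline_report
#' @export
autoplot.pipeline_report <- function(object, ...) {
  if (nrow(object$or_table) == 0) {
    stop("no retained covariates to plot", call. = FALSE)
  }
  d <- dplyr::bind_rows(
    dplyr::mutate(object$or_table, level = "all"),
    object$subgroup_or)
  class(d) <- c("or_table", class(d))
  autoplot.or_table(d)
}
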