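#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a logistic fit
#'
#' @param x A `logistic_fit`.
#' @param exponentiate Report odds-ratio scale estimates (default `FALSE`).
#' @param ... Unused.
#' @return A tibble with one row per coefficient.
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, exponentiate = FALSE, ...) {
  out <- x$coefficients
  if (exponentiate) out$estimate <- exp(out$estimate)
  out
}

#' One-row summary of a logistic fit
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(n = x$n_used, log_lik = x$loglik,
                 converged = x$converged, separated = x$separated)
}

#' Tidy a MARS model
#'
#' @param x A `mars_model`.
#' @param ... Unused.
#' @return A tibble with one row per basis function: `basis`, `identity`
#'   (canonical variable set, `NA` for the intercept), `degree`,
#'   `estimate`.
#' @method tidy mars_model
#' @export
tidy.mars_model <- function(x, ...) {
  tibble::tibble(
    basis = x$basis_labels,
    identity = vapply(x$basis, identity_of, character(1)),
    degree = vapply(x$basis, length, integer(1)),
    estimate = unname(x$coefficients))
}

#' One-row summary of a MARS model
#' @param x A `mars_model`.
#' @param ... Unused.
#' @method glance mars_model
#' @export
glance.mars_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_basis = length(x$basis),
                 n_basis_forward = x$forward_n_basis,
                 rss = x$rss, gcv = x$gcv)
}

#' Tidy a pipeline report
#'
#' Returns the covariate decision table — identity, logistic p, BIF and
#' retention flags per analysis and MARS split.
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @method tidy pipeline_report
#' @export
tidy.pipeline_report <- function(x, ...) {
  x$covariates
}

#' One-row-per-analysis summary of a pipeline report
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @method glance pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  if (nrow(x$covariates) == 0) {
    return(tibble::tibble(case_group = character(), n_proposed = integer(),
                          n_retained = integer()))
  }
  x$covariates |>
    dplyr::group_by(.data$case_group) |>
    dplyr::summarise(
      n_proposed = dplyr::n_distinct(.data$identity),
      n_retained = dplyr::n_distinct(.data$identity[.data$retained_step3 &
                                                      .data$retained_step4]),
      .groups = "drop")
}
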