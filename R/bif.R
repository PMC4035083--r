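# One design column per canonical identity: the encoded column itself for a
# main effect, the elementwise product for a degree-2 identity.
identity_columns <- function(design, identities) {
  cols <- lapply(identities, function(id) {
    v <- strsplit(id, ":", fixed = TRUE)[[1]]
    missing <- setdiff(v, colnames(design))
    if (length(missing) > 0) {
      stop("identity '", id, "' references unknown column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    apply(design[, v, drop = FALSE], 1, prod)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- identities
  out
}

#' Filter MARS-proposed covariates by logistic significance
#'
#' Joint logistic refit of case/control status on one column per canonical
#' identity (product column for interactions) plus an intercept; each
#' identity's Wald p is recorded and identities with `p > alpha` are
#' dropped. Zero-variance identity columns are recorded as non-retained
#' with a note; a separated joint fit marks every identity non-retained
#' with a `"separation"` note.
#'
#' @param design Numeric predictor matrix (encoded genotypes and sex).
#' @param outcome Binary 0/1 vector.
#' @param identities Character vector of canonical identities, or the
#'   tibble from [propose_covariates()].
#' @param alpha Retention threshold (default 0.05).
#' @return A tibble: `identity`, `logistic_p`, `retained_step3`, `note`.
#' @export
filter_covariates <- function(design, outcome, identities, alpha = 0.05) {
  if (is.data.frame(identities)) identities <- identities$identity
  if (length(identities) == 0) {
    return(tibble::tibble(identity = character(), logistic_p = numeric(),
                          retained_step3 = logical(), note = character()))
  }
  cols <- identity_columns(as.matrix(design), identities)
  variance_ok <- apply(cols, 2, function(x) length(unique(x[!is.na(x)])) > 1)
  out <- tibble::tibble(identity = identities, logistic_p = NA_real_,
                        retained_step3 = FALSE, note = NA_character_)
  out$note[!variance_ok] <- "degenerate"
  if (!any(variance_ok)) return(out)
  # duplicate or collinear proposals (e.g. a hinge pair proxying the same
  # contrast) are recorded as non-retained instead of aborting the stage
  X <- cbind(intercept = 1, cols[, variance_ok, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    out$note[out$identity %in% drop_cols] <- "collinear"
    variance_ok <- variance_ok & !(identities %in% drop_cols)
    if (!any(variance_ok)) return(out)
    X <- cbind(intercept = 1, cols[, variance_ok, drop = FALSE])
  }
  fit <- fit_logistic(X, outcome)
  if (fit$separated) {
    out$note[variance_ok] <- "separation"
    return(out)
  }
  p <- fit$coefficients$p_value[match(identities[variance_ok],
                                      fit$coefficients$term)]
  out$logistic_p[variance_ok] <- p
  out$retained_step3[variance_ok] <- p <= alpha
  out
}

#' Bootstrap inclusion fraction of selected covariates
#'
#' Stability validation of the covariates surviving the logistic filter:
#' the full MARS search is rerun on `B` bootstrap resamples of the rows
#' (plain sampling with replacement by default) and, for each tracked
#' identity, the percentage of converged replicates whose MARS model
#' proposes that identity is reported as the BIF. Identities with
#' `BIF > threshold` (50% by default) are retained. Significance is
#' established once on the original data; by default a replicate "includes"
#' a covariate as soon as its own forward/backward pass proposes it
#' (`count = "appearance"`). Setting `count = "appearance_and_significant"`
#' additionally requires the identity to pass the logistic filter inside
#' the replicate.
#'
#' Replicates with a degenerate resample (constant outcome) or a failed
#' fit are excluded from the denominator; if fewer than half of the
#' replicates survive, the run aborts.
#'
#' @param design Numeric predictor matrix for one MARS split.
#' @param outcome Binary 0/1 vector.
#' @param identities Character vector of identities retained at step 3.
#' @param B Number of bootstrap replicates (default 10000, the reference
#'   setting; scale down for exploratory runs).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param threshold Retention threshold in percent (default 50).
#' @param stratified Resample within case and control strata, preserving
#'   their sizes (default `FALSE`, plain resampling).
#' @param count `"appearance"` (default) or `"appearance_and_significant"`.
#' @param alpha Significance level used when `count` includes the
#'   replicate-level filter.
#' @param max_basis,max_degree,penalty MARS settings, passed to [mars_fit()].
#' @return A tibble: `identity`, `appearances`, `b_effective`, `bif`
#'   (percent), `retained_step4`.
#' @export
bootstrap_inclusion_fraction <- function(design, outcome, identities,
                                         B = 10000, seed = NULL,
                                         threshold = 50, stratified = FALSE,
                                         count = c("appearance",
                                                   "appearance_and_significant"),
                                         alpha = 0.05,
                                         max_basis = 100, max_degree = 2,
                                         penalty = 3) {
  count <- match.arg(count)
  stopifnot(B >= 1, length(identities) > 0)
  if (!is.null(seed)) set.seed(seed)
  design <- as.matrix(design)
  keep <- stats::complete.cases(design) & !is.na(outcome)
  design <- design[keep, , drop = FALSE]
  outcome <- outcome[keep]
  n <- nrow(design)
  hits <- stats::setNames(rep(0L, length(identities)), identities)
  b_eff <- 0L
  for (b in seq_len(B)) {
    idx <- if (stratified) {
      c(sample(which(outcome == 1), sum(outcome == 1), replace = TRUE),
        sample(which(outcome == 0), sum(outcome == 0), replace = TRUE))
    } else {
      sample.int(n, n, replace = TRUE)
    }
    y <- outcome[idx]
    if (all(y == y[1])) next # degenerate resample
    model <- tryCatch(
      mars_fit(design[idx, , drop = FALSE], y, max_basis = max_basis,
               max_degree = max_degree, penalty = penalty),
      error = function(e) NULL)
    if (is.null(model)) next
    b_eff <- b_eff + 1L
    present <- intersect(identities, model$selected_terms)
    if (count == "appearance_and_significant" && length(present) > 0) {
      dec <- tryCatch(
        filter_covariates(design[idx, , drop = FALSE], y,
                          model$selected_terms, alpha = alpha),
        error = function(e) NULL)
      present <- if (is.null(dec)) character(0) else {
        intersect(present, dec$identity[dec$retained_step3])
      }
    }
    hits[present] <- hits[present] + 1L
  }
  if (b_eff < 0.5 * B) {
    stop("fewer than half of the bootstrap replicates converged (",
         b_eff, "/", B, ")", call. = FALSE)
  }
  tibble::tibble(identity = identities,
                 appearances = as.integer(hits),
                 b_effective = b_eff,
                 bif = 100 * hits / b_eff,
                 retained_step4 = 100 * hits / b_eff > threshold)
}
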