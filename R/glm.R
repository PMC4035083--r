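# overflow-safe log(1 + exp(x))
log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

#' Logistic regression by iteratively reweighted least squares
#'
#' The significance engine behind inheritance-model selection and the
#' post-MARS covariate filter. Fits \eqn{\mathrm{logit}\,P(y=1) = X\beta} by
#' IRLS, with Wald z statistics and two-sided normal p-values per
#' coefficient. Standard errors come from the inverse observed information
#' \eqn{(X^\top W X)^{-1}}. Complete separation (a coefficient diverging
#' without convergence) is flagged rather than raised, so bootstrap callers
#' can skip-and-count such replicates.
#'
#' @param design Numeric matrix including an intercept column; column names
#'   become coefficient terms.
#' @param outcome Binary 0/1 vector (1 = case).
#' @param max_iter Maximum IRLS iterations (default 50).
#' @param grad_tol Convergence threshold on the score max-norm
#'   (default 1e-8).
#' @return A `logistic_fit` object: tibble of coefficients
#'   (`term`, `estimate`, `std_error`, `statistic`, `p_value`), plus
#'   `converged`, `separated`, `n_used`, `loglik` and the coefficient
#'   covariance matrix.
#' @export
#' @examples
#' x <- cbind(intercept = 1)
#' y <- rep(c(1, 0), c(30, 70))
#' fit_logistic(x[rep(1, 100), , drop = FALSE], y)$coefficients$estimate
#' # log(30/70)
fit_logistic <- function(design, outcome, max_iter = 50, grad_tol = 1e-8) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  keep <- stats::complete.cases(design) & !is.na(outcome)
  design <- design[keep, , drop = FALSE]
  outcome <- outcome[keep]
  if (!all(outcome %in% c(0, 1))) stop("outcome must be 0/1", call. = FALSE)
  n <- nrow(design); p <- ncol(design)
  if (all(outcome == 0) || all(outcome == 1)) {
    stop("outcome is constant (all ", outcome[1], ")", call. = FALSE)
  }
  if (n <= p) stop("more coefficients than complete cases", call. = FALSE)
  qr_x <- qr(design)
  if (qr_x$rank < p) {
    bad <- colnames(design)[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(design %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(design, outcome - mu))
    if (max(abs(score)) < grad_tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-12)
    info <- crossprod(design * w, design)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving keeps IRLS stable near separation
    ll_old <- sum(outcome * eta - log1pexp(eta))
    for (h in 0:5) {
      cand <- beta + step / 2^h
      eta_c <- drop(design %*% cand)
      ll_new <- sum(outcome * eta_c - log1pexp(eta_c))
      if (is.finite(ll_new) && (ll_new >= ll_old || h == 5)) break
    }
    beta <- cand
  }
  eta <- drop(design %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(design * w, design)
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vc), 0))
  z <- beta / se
  # a diverging coefficient with boundary fitted probabilities marks
  # (quasi-)complete separation even when the score norm went to zero
  separated <- any(abs(beta) > 15) &&
    (!converged || any(mu < 1e-8 | mu > 1 - 1e-8))
  if (separated) converged <- FALSE
  structure(list(
    coefficients = tibble::tibble(
      term = colnames(design), estimate = unname(beta),
      std_error = unname(se), statistic = unname(z),
      p_value = unname(2 * stats::pnorm(-abs(z)))),
    vcov = vc,
    converged = converged,
    separated = separated,
    n_used = n,
    loglik = sum(outcome * eta - log1pexp(eta))
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> n =", x$n_used,
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment \eqn{\tilde p_{(i)} = \min_{j \ge i} m\,p_{(j)}/j}
#' capped at 1, via [stats::p.adjust()].
#'
#' @param raw_p Vector of p-values in `[0, 1]`.
#' @return A tibble `raw_p`, `adjusted_p` in the input order, with the
#'   family size as attribute `m`. Empty input gives an empty tibble.
#' @export
bh_adjust <- function(raw_p) {
  if (length(raw_p) == 0) {
    return(structure(tibble::tibble(raw_p = numeric(), adjusted_p = numeric()),
                     m = 0L))
  }
  stopifnot(all(raw_p >= 0 & raw_p <= 1, na.rm = TRUE))
  structure(tibble::tibble(raw_p = raw_p,
                           adjusted_p = stats::p.adjust(raw_p, method = "BH")),
            m = length(raw_p))
}
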