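# --- basis-function representation -----------------------------------------
# A basis function is a list of factors, each factor a list(variable,
# direction (+1/-1), knot). The intercept is the empty factor list. Products
# never repeat a variable and degree is capped by max_degree.

basis_column <- function(design, factors) {
  col <- rep(1, nrow(design))
  for (f in factors) {
    x <- design[, f$variable]
    col <- col * pmax(0, f$direction * (x - f$knot))
  }
  col
}

basis_label <- function(factors) {
  if (length(factors) == 0) return("(intercept)")
  paste(vapply(factors, function(f) {
    sprintf("h(%s%s%s)", if (f$direction > 0) "" else "-",
            f$variable,
            if (f$direction > 0) paste0("-", signif(f$knot, 6))
            else paste0("+", signif(f$knot, 6)))
  }, character(1)), collapse = " * ")
}

basis_variables <- function(factors) {
  vapply(factors, function(f) f$variable, character(1))
}

# canonical covariate identity: the sorted variable set, knots dropped
identity_of <- function(factors) {
  v <- basis_variables(factors)
  if (length(v) == 0) return(NA_character_)
  paste(sort(unique(v)), collapse = ":")
}

# RSS reduction from adding one or two candidate columns, computed in Gram
# space: with Q orthonormal and r = y - QQ'y, the projection of candidate c
# onto the orthogonal complement has Gram entries c_i'c_j - (Q'c_i)'(Q'c_j)
# and response inner product c_i'r (since Q'r = 0). `g` is that 2x2 (or
# 1x1) Gram block, `b` the inner products, `cn` the raw column norms used
# for the degeneracy tolerance.
pair_reduction <- function(g, b, cn) {
  keep <- diag(g) > 1e-9 * pmax(cn, 1e-12)
  if (!any(keep)) return(list(reduction = 0, keep = keep))
  if (length(b) == 2 && all(keep) &&
      g[1, 2]^2 >= (1 - 1e-9) * g[1, 1] * g[2, 2]) {
    keep[2] <- FALSE # reflected partner adds nothing beyond the first
  }
  if (sum(keep) == 1) {
    i <- which(keep)
    return(list(reduction = b[i]^2 / g[i, i], keep = keep))
  }
  det <- g[1, 1] * g[2, 2] - g[1, 2]^2
  list(reduction = (b[1]^2 * g[2, 2] - 2 * b[1] * b[2] * g[1, 2] +
                      b[2]^2 * g[1, 1]) / det,
       keep = keep)
}

mars_gcv <- function(rss, n, m, penalty) {
  c_m <- m + penalty * (m - 1) / 2
  if (c_m >= n) return(Inf)
  (rss / n) / (1 - c_m / n)^2
}

#' Multivariate adaptive regression splines (least squares)
#'
#' Classic two-stage MARS: a forward pass that greedily adds reflected
#' hinge-function pairs \eqn{\max(0, x-t)}, \eqn{\max(0, t-x)} (products
#' with an existing parent basis up to interaction degree `max_degree`,
#' knots restricted to observed predictor values), followed by a backward
#' pruning pass that deletes basis functions one at a time and keeps the
#' subset minimising the generalised cross-validation score
#' \deqn{GCV(M) = \frac{RSS/n}{(1 - C(M)/n)^2},\quad
#'       C(M) = M + \mathrm{penalty}\,(M-1)/2.}
#'
#' The response is fit by least squares even when binary; here MARS is a
#' covariate *selector* whose proposals are re-tested by logistic
#' regression, so least squares on 0/1 is the appropriate search engine.
#' Predictors with two observed values (encoded dominant/recessive
#' genotypes, sex) enter as a single linear-indicator basis instead of a
#' hinge pair. Tie-breaks in the forward search are deterministic: earliest
#' parent, lowest variable index, smallest knot.
#'
#' @param design Numeric predictor matrix with named columns (encoded
#'   genotypes and sex); no intercept column.
#' @param response Numeric response vector (0/1 case status).
#' @param max_basis Maximum number of basis functions including the
#'   intercept (default 100).
#' @param max_degree Maximum interaction degree (default 2).
#' @param penalty GCV cost per knot (default 3, the standard value when
#'   interactions are allowed).
#' @param rel_tol Forward pass stops when the best candidate's relative RSS
#'   improvement falls below this (default 0.001, the conventional MARS
#'   forward threshold; smaller values admit ever more collinear
#'   near-null terms for the backward pass to sift).
#' @return A `mars_model`: basis-function list (intercept first), fitted
#'   `coefficients`, `rss`, `gcv`, `n`, the forward-pass RSS history, and
#'   `selected_terms` (canonical variable identities).
#' @export
mars_fit <- function(design, response, max_basis = 100, max_degree = 2,
                     penalty = 3, rel_tol = 0.001) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  stopifnot(max_basis >= 1, max_degree >= 1)
  keep <- stats::complete.cases(design) & !is.na(response)
  design <- design[keep, , drop = FALSE]
  response <- response[keep]
  n <- nrow(design)
  if (n <= max_degree + 1) stop("too few rows for the requested degree", call. = FALSE)

  vars <- colnames(design)
  uniq <- lapply(vars, function(v) sort(unique(design[, v])))
  names(uniq) <- vars

  # Precompute hinge columns per variable: binary predictors contribute a
  # single linear-indicator column, others a reflected pair per observed
  # knot. Candidate basis columns are parent * hinge.
  hinges <- lapply(vars, function(v) {
    u <- uniq[[v]]
    if (length(u) < 2) return(NULL)
    x <- design[, v]
    if (length(u) == 2) {
      list(H = matrix(pmax(0, x - u[1]), ncol = 1),
           groups = list(list(cols = 1L,
                              factors = list(list(variable = v, direction = 1,
                                                  knot = u[1])))))
    } else {
      cols <- list(); groups <- list()
      for (k in seq_along(u)) {
        t <- u[k]
        cols[[2 * k - 1]] <- pmax(0, x - t)
        cols[[2 * k]] <- pmax(0, t - x)
        groups[[k]] <- list(
          cols = c(2L * k - 1L, 2L * k),
          factors = list(list(variable = v, direction = 1, knot = t),
                         list(variable = v, direction = -1, knot = t)))
      }
      list(H = do.call(cbind, cols), groups = groups)
    }
  })
  names(hinges) <- vars

  bases <- list(list())                       # intercept
  B <- matrix(1, n, 1)
  Q <- matrix(1 / sqrt(n), n, 1)              # orthonormal basis of span(B)
  r <- response - Q %*% crossprod(Q, response)
  r <- drop(r)
  rss <- sum(r^2)
  forward_rss <- rss

  repeat {
    if (length(bases) >= min(max_basis, n - 1)) break
    if (rss <= 1e-12) break
    best <- NULL
    best_red <- 0
    for (m in seq_along(bases)) {
      parent <- bases[[m]]
      if (length(parent) >= max_degree) next
      used <- basis_variables(parent)
      bm <- B[, m]
      for (v in vars) {
        if (v %in% used) next
        hv <- hinges[[v]]
        if (is.null(hv)) next
        C <- hv$H * bm
        A <- crossprod(Q, C)              # M x K
        M2 <- crossprod(C) - crossprod(A) # Gram of orthogonalised candidates
        b <- drop(crossprod(C, r))
        cn <- colSums(C^2)
        for (grp in hv$groups) {
          cols <- grp$cols
          res <- pair_reduction(M2[cols, cols, drop = FALSE], b[cols], cn[cols])
          if (res$reduction > best_red * (1 + 1e-9) + 1e-12) {
            best_red <- res$reduction
            fl <- lapply(grp$factors[res$keep], function(f) c(parent, list(f)))
            best <- list(factors_pair = fl,
                         C = C[, cols[res$keep], drop = FALSE])
          }
        }
      }
    }
    if (is.null(best) || best_red / max(rss, 1e-300) < rel_tol) break
    new_factors <- best[["factors_pair"]]
    k <- length(new_factors)
    if (length(bases) + k > max_basis) break
    bases <- c(bases, new_factors)
    B <- cbind(B, best$C)
    # extend Q by twice-orthogonalised, normalised copies of the new columns
    for (j in seq_len(ncol(best$C))) {
      u <- best$C[, j]
      u <- u - Q %*% crossprod(Q, u)
      u <- u - Q %*% crossprod(Q, u)
      nu <- sqrt(sum(u^2))
      if (nu > 1e-10) Q <- cbind(Q, u / nu)
    }
    r <- drop(response - Q %*% crossprod(Q, response))
    rss <- sum(r^2)
    forward_rss <- c(forward_rss, rss)
  }

  # backward pass: best subset by one-at-a-time deletion under GCV.
  # RSS(S) = y'y - g_S' G_S^{-1} g_S needs only the Gram matrix, so each
  # subset costs O(M^3) independent of n.
  G <- crossprod(B)
  gy <- drop(crossprod(B, response))
  yty <- sum(response^2)
  subset_rss <- function(idx) {
    Gs <- G[idx, idx, drop = FALSE]
    sol <- tryCatch(solve(Gs, gy[idx]), error = function(e) {
      qr.coef(qr(Gs), gy[idx])
    })
    sol[is.na(sol)] <- 0
    max(yty - sum(gy[idx] * sol), 0)
  }
  current <- seq_along(bases)
  best_idx <- current
  best_gcv <- mars_gcv(rss, n, length(current), penalty)
  cur_idx <- current
  while (length(cur_idx) > 1) {
    gcvs <- vapply(cur_idx[-1], function(j) {
      mars_gcv(subset_rss(setdiff(cur_idx, j)), n, length(cur_idx) - 1, penalty)
    }, numeric(1))
    drop_j <- cur_idx[-1][which.min(gcvs)]
    cur_idx <- setdiff(cur_idx, drop_j)
    g <- min(gcvs)
    if (g <= best_gcv) { best_gcv <- g; best_idx <- cur_idx }
  }
  if (is.infinite(best_gcv)) stop("sample too small for GCV", call. = FALSE)

  final_bases <- bases[best_idx]
  Bf <- B[, best_idx, drop = FALSE]
  qf <- qr(Bf)
  coefs <- qr.coef(qf, response)
  coefs[is.na(coefs)] <- 0
  final_rss <- sum(qr.resid(qf, response)^2)
  labels <- vapply(final_bases, basis_label, character(1))
  idents <- vapply(final_bases, identity_of, character(1))

  structure(list(
    basis = final_bases,
    basis_labels = labels,
    coefficients = stats::setNames(drop(coefs), labels),
    rss = final_rss,
    gcv = mars_gcv(final_rss, n, length(final_bases), penalty),
    n = n,
    forward_rss = forward_rss,
    forward_n_basis = length(bases),
    selected_terms = unique(idents[!is.na(idents)]),
    max_basis = max_basis, max_degree = max_degree, penalty = penalty,
    variables = vars
  ), class = "mars_model")
}

#' @export
print.mars_model <- function(x, ...) {
  cat("<mars_model> ", length(x$basis), " basis function(s), n = ", x$n,
      ", RSS = ", signif(x$rss, 6), ", GCV = ", signif(x$gcv, 6), "\n", sep = "")
  for (i in seq_along(x$basis)) {
    cat(sprintf("  %+.4g * %s\n", x$coefficients[i], x$basis_labels[i]))
  }
  invisible(x)
}

#' Predict from a fitted MARS model
#'
#' @param object A `mars_model`.
#' @param newdata Numeric matrix with the model's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.mars_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  B <- vapply(object$basis, function(f) basis_column(newdata, f),
              numeric(nrow(newdata)))
  drop(matrix(B, nrow = nrow(newdata)) %*% object$coefficients)
}

#' Canonical covariates proposed by a MARS model
#'
#' Maps each non-intercept basis function to its canonical covariate
#' identity — the unordered set of variables it involves, knots and hinge
#' directions dropped — and merges duplicates. This knot-free notion of
#' "variable" is what the bootstrap inclusion fraction counts.
#'
#' @param model A `mars_model`.
#' @return A tibble: `identity` (e.g. `"rs4035887:sex"`), `degree`, and a
#'   `variables` list-column.
#' @export
propose_covariates <- function(model) {
  idents <- model$selected_terms
  if (length(idents) == 0) {
    return(tibble::tibble(identity = character(), degree = integer(),
                          variables = list()))
  }
  vars <- strsplit(idents, ":", fixed = TRUE)
  tibble::tibble(identity = idents,
                 degree = lengths(vars),
                 variables = vars)
}
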