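#' Per-feature linear models, moderation, contrasts and FDR
#'
#' Every feature (peptidoform or summarized PTM) is modeled separately. With
#' one predictor the model is
#' \deqn{y_{cs} = \beta_0 + \beta_c\,\mathrm{condition} + \varepsilon_{cs},
#'       \qquad \varepsilon_{cs} \sim N(0, \sigma^2),}
#' and richer fixed-effect formulas or a single random intercept can be
#' requested. Estimates can be stabilized by Huber M-estimation, ridge
#' shrinkage of the non-intercept coefficients, and empirical-Bayes variance
#' moderation across features. A deliberate single-model policy applies: a
#' feature is either fitted with the full requested model or reported as
#' `no_fit` — it is never silently downgraded to a simpler model, because
#' adaptive downgrading ignores known variance components and underestimates
#' standard errors.
#'
#' @name inference
NULL

new_model_fit <- function(beta = NULL, sigma = NA_real_,
                          df_residual = NA_real_, vcov_unscaled = NULL,
                          status = "no_fit", n_obs = 0L, extra = list()) {
  structure(c(list(beta = beta, sigma = sigma, df_residual = df_residual,
                   vcov_unscaled = vcov_unscaled, status = status,
                   n_obs = n_obs), extra),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> status=%s n_obs=%d df=%s\n", x$status, x$n_obs,
              format(x$df_residual)))
  invisible(x)
}

huber_weights <- function(r, k) {
  s <- stats::median(abs(r)) / 0.6745
  if (s < .Machine$double.eps^0.5) return(rep(1, length(r)))
  pmin(1, k * s / abs(r))
}

#' Fit the requested fixed-effect model to one feature
#'
#' Samples with a missing response are dropped. If the design matrix on the
#' remaining samples is rank-deficient for the requested coefficients (e.g. a
#' condition level lost all its observations), or fewer than one residual
#' degree of freedom remains, the feature gets `status = "no_fit"` — no
#' silent model simplification. `no_fit` is a status, not an error.
#'
#' @param y Named numeric vector of responses per sample (missing allowed).
#' @param design Sample-annotation data frame (`sample_id` plus design
#'   columns), rows matching `names(y)` by `sample_id`.
#' @param formula Fixed-effect formula over design columns, e.g.
#'   `~ condition`.
#' @param robust Use Huber IRLS (tuning constant `huber_k`) instead of OLS.
#' @param ridge Penalize the non-intercept coefficients; the penalty is
#'   chosen by generalized cross-validation over a log-spaced grid.
#' @param huber_k,tol,max_iter IRLS controls.
#' @return A `model_fit` with coefficients, residual SD `sigma`, residual
#'   degrees of freedom, unscaled covariance (`Var(beta) = sigma^2 *
#'   vcov_unscaled`) and a status flag.
#' @export
fit_feature <- function(y, design, formula = ~ condition, robust = FALSE,
                        ridge = FALSE, huber_k = 1.345, tol = 1e-6,
                        max_iter = 100L) {
  idx <- match(design$sample_id, names(y))
  yy <- y[idx]
  keep <- !is.na(yy)
  n <- sum(keep)
  if (n < 2L) return(new_model_fit(n_obs = n))
  dd <- design[keep, , drop = FALSE]
  X <- tryCatch(stats::model.matrix(formula, dd), error = function(e) NULL)
  if (is.null(X) || nrow(X) != n) return(new_model_fit(n_obs = n))
  yy <- yy[keep]
  p <- ncol(X)

  if (ridge) return(fit_ridge(yy, X, n))

  qrX <- qr(X)
  if (qrX$rank < p || n - p < 1L) return(new_model_fit(n_obs = n))

  w <- rep(1, n)
  beta <- rep(0, p)
  for (iter in seq_len(if (robust) max_iter else 1L)) {
    fit <- stats::lm.wfit(X, yy, w)
    b <- fit$coefficients
    r <- yy - drop(X %*% b)
    if (max(abs(b - beta)) < tol) { beta <- b; break }
    beta <- b
    if (robust) w <- huber_weights(r, huber_k)
  }
  df <- n - p
  sigma <- sqrt(sum(w * r^2) / df)
  XtWX <- crossprod(X * sqrt(w))
  vcov_u <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(vcov_u)) return(new_model_fit(n_obs = n))
  dimnames(vcov_u) <- list(colnames(X), colnames(X))
  new_model_fit(beta = stats::setNames(beta, colnames(X)), sigma = sigma,
                df_residual = df, vcov_unscaled = vcov_u, status = "ok",
                n_obs = n)
}

# Ridge with GCV-chosen penalty on the non-intercept coefficients.
# Effective residual df = n - tr(H); documented as an approximation.
fit_ridge <- function(yy, X, n) {
  p <- ncol(X)
  pen <- rep(1, p)
  pen[colnames(X) == "(Intercept)"] <- 0
  D <- diag(pen, p)
  XtX <- crossprod(X)
  Xty <- crossprod(X, yy)
  lambdas <- 10^seq(-6, 6, length.out = 49L)
  best <- NULL
  for (lam in lambdas) {
    A <- tryCatch(solve(XtX + lam * D), error = function(e) NULL)
    if (is.null(A)) next
    b <- drop(A %*% Xty)
    H_tr <- sum(diag(X %*% A %*% t(X)))
    r <- yy - drop(X %*% b)
    gcv <- n * sum(r^2) / (n - H_tr)^2
    if (is.null(best) || gcv < best$gcv)
      best <- list(gcv = gcv, b = b, A = A, H_tr = H_tr, r = r, lam = lam)
  }
  if (is.null(best)) return(new_model_fit(n_obs = n))
  df <- n - best$H_tr
  if (df < 1) return(new_model_fit(n_obs = n))
  sigma <- sqrt(sum(best$r^2) / df)
  vcov_u <- best$A %*% XtX %*% best$A
  dimnames(vcov_u) <- list(colnames(X), colnames(X))
  new_model_fit(beta = stats::setNames(best$b, colnames(X)), sigma = sigma,
                df_residual = df, vcov_unscaled = vcov_u, status = "ok",
                n_obs = n, extra = list(lambda = best$lam))
}

#' Fit a fixed-effect model plus one random intercept to one feature
#'
#' The model is \eqn{y = X\beta + Zb + \varepsilon} with
#' \eqn{b \sim N(0, \sigma^2\gamma I)} for a single grouping factor (e.g.
#' biological repeat). The variance ratio \eqn{\gamma} is estimated by
#' profiled REML (one-dimensional optimization over \eqn{\log\gamma}); the
#' fixed effects follow by generalized least squares at the optimum. Residual
#' degrees of freedom use the convention `n_obs - rank(X) - 1` (one df spent
#' on the variance component); this is approximate, not Satterthwaite.
#' `status = "no_fit"` when the grouping has fewer than two observed levels,
#' when every group holds a single observation (the component is
#' unidentifiable), or when the fixed design is rank-deficient.
#'
#' @param y Named numeric vector per sample.
#' @param design Sample-annotation data frame.
#' @param formula Fixed-effect formula.
#' @param random Name of the grouping column for the random intercept.
#' @return A `model_fit`; `extra` fields `gamma` (variance ratio) and
#'   `sigma_b` (random-intercept SD).
#' @export
fit_mixed_feature <- function(y, design, formula = ~ condition,
                              random = "biorepeat") {
  idx <- match(design$sample_id, names(y))
  yy <- y[idx]
  keep <- !is.na(yy)
  n <- sum(keep)
  if (n < 3L) return(new_model_fit(n_obs = n))
  dd <- design[keep, , drop = FALSE]
  g <- droplevels(factor(dd[[random]]))
  if (nlevels(g) < 2L || all(tabulate(g) <= 1L))
    return(new_model_fit(n_obs = n))
  X <- tryCatch(stats::model.matrix(formula, dd), error = function(e) NULL)
  if (is.null(X)) return(new_model_fit(n_obs = n))
  p <- ncol(X)
  if (qr(X)$rank < p) return(new_model_fit(n_obs = n))
  df <- n - p - 1
  if (df < 1) return(new_model_fit(n_obs = n))
  yy <- yy[keep]
  Z <- stats::model.matrix(~ 0 + g)

  reml_parts <- function(loggamma) {
    gam <- exp(loggamma)
    V <- diag(n) + gam * tcrossprod(Z)
    cV <- chol(V)
    Vi_y <- backsolve(cV, forwardsolve(t(cV), yy))
    Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
    XtViX <- crossprod(X, Vi_X)
    beta <- solve(XtViX, crossprod(X, Vi_y))
    r <- yy - drop(X %*% beta)
    Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
    q <- sum(r * Vi_r)
    crit <- 2 * sum(log(diag(cV))) + determinant(XtViX)$modulus +
      (n - p) * log(q)
    list(crit = as.numeric(crit), beta = drop(beta), q = q, XtViX = XtViX)
  }
  opt <- stats::optimize(function(lg) reml_parts(lg)$crit,
                         interval = c(-15, 10))
  parts <- reml_parts(opt$minimum)
  gam <- exp(opt$minimum)
  sigma2 <- parts$q / (n - p)
  vcov_u <- solve(parts$XtViX)
  dimnames(vcov_u) <- list(colnames(X), colnames(X))
  new_model_fit(beta = stats::setNames(parts$beta, colnames(X)),
                sigma = sqrt(sigma2), df_residual = df,
                vcov_unscaled = vcov_u, status = "ok", n_obs = n,
                extra = list(gamma = gam, sigma_b = sqrt(gam * sigma2)))
}

#' Fit a model to every feature of an assay
#'
#' @param assay An `intensity_assay`.
#' @param design Sample-annotation data frame.
#' @param formula Fixed-effect formula.
#' @param random Optional grouping column: fits the single-random-intercept
#'   mixed model instead.
#' @param robust,ridge Passed to [fit_feature()].
#' @return Named list of `model_fit` objects, one per feature.
#' @export
fit_models <- function(assay, design, formula = ~ condition, random = NULL,
                       robust = FALSE, ridge = FALSE) {
  stopifnot(inherits(assay, "intensity_assay"))
  ids <- feature_ids(assay)
  fits <- vector("list", length(ids))
  names(fits) <- ids
  for (i in seq_along(ids)) {
    y <- assay$values[i, ]
    fits[[i]] <- if (is.null(random)) {
      fit_feature(y, design, formula, robust = robust, ridge = ridge)
    } else {
      fit_mixed_feature(y, design, formula, random = random)
    }
  }
  fits
}

#' Empirical-Bayes squeezing of residual variances
#'
#' Shrinks per-feature residual variances toward a common prior by fitting a
#' scaled-F distribution across features (moment matching), yielding
#' posterior variances `s2_post = (df_prior*s2_prior + df*s2) / (df_prior +
#' df)` and augmented degrees of freedom for moderated t-tests. Features with
#' zero residual df are excluded from estimation and keep their own variance.
#' With fewer than two usable variances no moderation is applied
#' (`df_prior = 0`).
#'
#' @param sigmas Numeric vector of residual SDs.
#' @param dfs Numeric vector of residual degrees of freedom.
#' @return List with `s2_prior`, `df_prior` (possibly `Inf`) and the
#'   per-feature `s2_post` vector (aligned with the input).
#' @export
squeeze_variances <- function(sigmas, dfs) {
  s2 <- sigmas^2
  usable <- which(!is.na(s2) & !is.na(dfs) & dfs >= 1)
  if (length(usable) < 2L)
    return(list(s2_prior = NA_real_, df_prior = 0, s2_post = s2))
  sq <- limma::squeezeVar(s2[usable], dfs[usable])
  s2_post <- s2
  s2_post[usable] <- sq$var.post
  list(s2_prior = sq$var.prior, df_prior = sq$df.prior, s2_post = s2_post)
}

#' Build a contrast vector from a linear expression
#'
#' Parses expressions such as `"conditionB - conditionA = 0"` or
#' `"0.5*condB + 0.5*condC"` into a vector `L` over the coefficient names
#' (null hypothesis `L'beta = 0`). Only linear combinations with numeric
#' multipliers are accepted.
#'
#' @param expression Contrast string; an optional `= 0` right-hand side is
#'   allowed.
#' @param coefficient_names Names of the model coefficients.
#' @param name Optional display name; defaults to the expression.
#' @return Named list with `name` and numeric vector `L`.
#' @export
make_contrast <- function(expression, coefficient_names, name = NULL) {
  raw <- expression
  e <- gsub("[[:space:]]", "", expression)
  if (grepl("=", e, fixed = TRUE)) {
    sides <- strsplit(e, "=", fixed = TRUE)[[1]]
    if (length(sides) != 2L || sides[2] != "0")
      stop("right-hand side must be 0: ", raw)
    e <- sides[1]
  }
  terms <- regmatches(e, gregexpr("[+-]?[^+-]+", e))[[1]]
  if (!length(terms)) stop("empty contrast expression")
  L <- stats::setNames(numeric(length(coefficient_names)), coefficient_names)
  for (term in terms) {
    sign <- 1
    body <- term
    if (startsWith(body, "+")) body <- substring(body, 2)
    if (startsWith(body, "-")) { sign <- -1; body <- substring(body, 2) }
    mult <- 1
    if (grepl("*", body, fixed = TRUE)) {
      parts <- strsplit(body, "*", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("nonlinear term in contrast: ", term)
      mult <- suppressWarnings(as.numeric(parts[1]))
      if (is.na(mult)) stop("non-numeric multiplier in contrast: ", term)
      body <- parts[2]
    }
    if (!body %in% coefficient_names)
      stop("unknown coefficient '", body, "' in contrast; available: ",
           paste(coefficient_names, collapse = ", "))
    L[body] <- L[body] + sign * mult
  }
  if (all(L == 0)) stop("contrast vector is all zero")
  list(name = if (is.null(name)) raw else name, L = L)
}

#' Test contrasts across fitted features
#'
#' For each feature and contrast: `logFC = L'beta`, `se = sqrt(s2_post * L'
#' vcov_unscaled L)`, `t = logFC/se`, with `df = df_residual + df_prior`
#' (an infinite prior df gives a normal reference), two-sided p-values, and
#' Benjamini-Hochberg adjustment per contrast across the features with a
#' valid p-value. Features with `status = "no_fit"` are reported with missing
#' statistics and are excluded from the BH denominator. With
#' `moderation = FALSE` (or a degenerate prior) the ordinary t-test is
#' recovered exactly.
#'
#' @param fits Named list of `model_fit` objects.
#' @param contrasts A contrast from [make_contrast()] or a list of them.
#' @param moderation Apply [squeeze_variances()] across features first.
#' @return Data frame of inference rows: `feature_id`, `contrast`, `logFC`,
#'   `se`, `t`, `df`, `pval`, `adj_pval`.
#' @export
test_contrasts <- function(fits, contrasts, moderation = TRUE) {
  if (!is.null(contrasts$L)) contrasts <- list(contrasts)
  ok <- vapply(fits, function(f) identical(f$status, "ok"), logical(1))
  sigmas <- vapply(fits, function(f) f$sigma %||% NA_real_, numeric(1))
  dfs <- vapply(fits, function(f) f$df_residual %||% NA_real_, numeric(1))
  sigmas[!ok] <- NA_real_
  dfs[!ok] <- NA_real_
  if (moderation) {
    sq <- squeeze_variances(sigmas, dfs)
  } else {
    sq <- list(s2_prior = NA_real_, df_prior = 0, s2_post = sigmas^2)
  }
  out <- list()
  for (ct in contrasts) {
    logFC <- se <- tt <- df <- pv <- rep(NA_real_, length(fits))
    for (i in seq_along(fits)) {
      f <- fits[[i]]
      if (!ok[i]) next
      L <- ct$L
      if (!all(names(L) %in% names(f$beta))) next
      Lf <- L[names(f$beta)]
      Lf[is.na(Lf)] <- 0
      varu <- drop(t(Lf) %*% f$vcov_unscaled %*% Lf)
      if (!is.finite(varu) || varu <= 0) next
      logFC[i] <- sum(Lf * f$beta)
      se[i] <- sqrt(sq$s2_post[i] * varu)
      df[i] <- f$df_residual + sq$df_prior
      tt[i] <- logFC[i] / se[i]
      pv[i] <- 2 * stats::pt(-abs(tt[i]), df = df[i])
    }
    adj <- rep(NA_real_, length(fits))
    has_p <- !is.na(pv)
    adj[has_p] <- stats::p.adjust(pv[has_p], method = "BH")
    out[[length(out) + 1L]] <- data.frame(
      feature_id = names(fits), contrast = ct$name, logFC = logFC, se = se,
      t = tt, df = df, pval = pv, adj_pval = adj,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
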