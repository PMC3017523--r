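#' Ordinary least squares on a predictor subset
#'
#' Exact OLS fit of the outcome on an arbitrary subset of predictor columns,
#' always including an intercept, via QR decomposition with column pivoting.
#' Returns classical standard errors, t statistics and two-sided p values
#' (t distribution with `n - k_params` degrees of freedom), the residual sum
#' of squares, and the information criteria used by the selectors.
#'
#' Rank deficiency is detected at QR's relative tolerance (1e-7); the error
#' message names the offending columns.
#'
#' @param dataset a `sim_dataset` (see [simulate_dataset()], [as_sim_dataset()])
#' @param variables integer indices of the predictors to include (possibly
#'   empty for the intercept-only model); duplicates are an error
#' @return object of class `ols_fit`: list with `variables`, `coefficients`
#'   (intercept first), `standard_errors`, `t_values`, `p_values`, `rss`,
#'   `n`, `k_params` (slopes + intercept), `aic`, `bic`, `df_residual`
#' @examples
#' ds <- simulate_dataset(make_dgp_spec(2), sigma = 1, seed = 7)
#' fit <- fit_ols(ds, c(1, 5))
#' fit$coefficients
#' @export
fit_ols <- function(dataset, variables = integer(0)) {
  stopifnot(inherits(dataset, "sim_dataset"))
  p <- ncol(dataset$X)
  variables <- as.integer(variables)
  if (anyDuplicated(variables)) stop("duplicate variable indices in subset")
  if (length(variables) && (min(variables) < 1 || max(variables) > p)) {
    stop("variable indices must lie in 1..", p)
  }
  n <- length(dataset$y)
  k <- length(variables) + 1L
  if (n <= k) stop("need n > number of parameters (n = ", n, ", k = ", k, ")")
  M <- cbind(`(Intercept)` = 1, dataset$X[, variables, drop = FALSE])
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- sort(qrM$pivot[seq.int(qrM$rank + 1L, ncol(M))])
    bad_vars <- variables[bad - 1L]  # never the intercept column
    stop("design is rank deficient; collinear columns: ",
         paste0("x", bad_vars, collapse = ", "))
  }
  coef <- qr.coef(qrM, dataset$y)
  res <- qr.resid(qrM, dataset$y)
  rss <- sum(res^2)
  tss <- sum((dataset$y - mean(dataset$y))^2)
  df <- n - k
  sigma2 <- rss / df
  # unscaled covariance (X'X)^{-1}, undoing the pivot
  R <- qr.R(qrM)
  xtx_inv <- chol2inv(R)
  un <- order(qrM$pivot)
  xtx_inv <- xtx_inv[un, un, drop = FALSE]
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  names(se) <- names(coef)
  tval <- ifelse(se > 0, coef / se, Inf * sign(coef))
  pval <- 2 * pt(-abs(tval), df)
  fit <- structure(
    list(variables = variables, coefficients = coef, standard_errors = se,
         t_values = tval, p_values = pval, rss = rss, tss = tss, n = n,
         k_params = k, df_residual = df, aic = NA_real_, bic = NA_real_),
    class = "ols_fit")
  if (!.is_degenerate(fit)) {
    fit$aic <- aic(fit)
    fit$bic <- bic(fit)
  }
  fit
}

# a fit is a degenerate perfect fit when its RSS vanishes relative to the
# outcome's total sum of squares (floating-point zero)
.is_degenerate <- function(fit) {
  tss <- if (is.null(fit$tss)) 1 else fit$tss
  fit$rss <= 1e-12 * max(tss, .Machine$double.xmin)
}

# shared validity check for the information criteria
.check_ic <- function(fit) {
  stopifnot(inherits(fit, "ols_fit"))
  if (.is_degenerate(fit)) {
    stop("degenerate perfect fit: rss = 0, information criteria undefined ",
         "under the Gaussian profile likelihood")
  }
}

#' Akaike information criterion of an OLS fit
#'
#' Gaussian AIC up to an additive constant:
#' `n * log(rss / n) + 2 * k_params`, where `k_params` counts the intercept
#' and the slopes but *not* the error variance. The constant
#' `n * (log(2 pi) + 1)` is omitted; only differences between models on the
#' same data matter for selection, and this convention matches
#' `stats::extractAIC`, so cross-checks against `stats::step` are exact.
#'
#' @param fit an `ols_fit`
#' @return numeric AIC value
#' @seealso [bic()], [aic_from_rss()]
#' @export
aic <- function(fit) {
  .check_ic(fit)
  aic_from_rss(fit$rss, fit$n, fit$k_params)
}

#' Bayesian information criterion of an OLS fit
#'
#' `n * log(rss / n) + k_params * log(n)`, same constant convention and
#' parameter count as [aic()]. `exp(-BIC/2)` approximates the integrated
#' likelihood under a unit-information prior and is the model weight used
#' by the BMA selector.
#'
#' @inheritParams aic
#' @return numeric BIC value
#' @export
bic <- function(fit) {
  .check_ic(fit)
  bic_from_rss(fit$rss, fit$n, fit$k_params)
}

#' @rdname aic
#' @param rss residual sum of squares (> 0)
#' @param n number of observations
#' @param k_params parameter count (slopes + intercept)
#' @export
aic_from_rss <- function(rss, n, k_params) {
  stopifnot(all(rss > 0))
  n * log(rss / n) + 2 * k_params
}

#' @rdname bic
#' @inheritParams aic_from_rss
#' @export
bic_from_rss <- function(rss, n, k_params) {
  stopifnot(all(rss > 0))
  n * log(rss / n) + k_params * log(n)
}

#' @export
print.ols_fit <- function(x, digits = 4, ...) {
  cat("OLS fit on {",
      if (length(x$variables)) paste0("x", x$variables, collapse = ", ")
      else "intercept only", "}\n", sep = "")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$standard_errors,
               `t value` = x$t_values, `Pr(>|t|)` = x$p_values)
  print(round(tab, digits))
  cat("rss =", format(x$rss, digits = digits),
      " AIC =", format(x$aic, digits = digits),
      " BIC =", format(x$bic, digits = digits), "\n")
  invisible(x)
}

# Centered cross-products used by the compiled subset search and the forward
# stepper. Centering absorbs the intercept: the RSS of y on (1, X_S) equals
# the RSS of centered y on centered X_S.
.dataset_gram <- function(dataset) {
  X <- dataset$X
  y <- dataset$y
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  list(G = crossprod(Xc), g = drop(crossprod(Xc, yc)), yy = sum(yc^2),
       n = length(y), p = ncol(X))
}
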