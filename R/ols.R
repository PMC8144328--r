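#' Ordinary (or weighted) least squares on explicit model terms
#'
#' Fits `outcome ~ 1 + terms` by QR-based least squares with the
#' classical Normal-theory covariance `sigma^2 (X'X)^{-1}` (or its
#' weighted analogue). Terms are strings; `"a:b"` denotes the product of
#' columns `a` and `b`. Rank-deficient designs are an error naming the
#' aliased columns.
#'
#' @param data A data frame (complete cases for the used columns).
#' @param outcome Name of the outcome column.
#' @param terms Character vector of model terms (intercept implicit).
#' @param weights Optional non-negative case weights (WLS).
#' @param transform Outcome transform applied before fitting:
#'   `"identity"`, `"log"` or `"logit"`.
#' @return An object of class `ols_fit`: list with `coefficients`,
#'   `vcov`, `sigma2`, `residuals`, `fitted`, `n`, `df_residual`,
#'   `loglik`, `aic` (`-2 loglik + 2 (k + 1)`), `outcome`, `terms`,
#'   `transform`. Supports [tidy()][generics::tidy], [glance()],
#'   `coef()`, `vcov()`.
#' @export
#' @examples
#' d <- tibble::tibble(x = 1:10, z = rnorm(10), y = 2 + 3 * (1:10))
#' coef(fit_ols(d, "y", "x"))
fit_ols <- function(data, outcome, terms, weights = NULL,
                    transform = c("identity", "log", "logit")) {
  transform <- match.arg(transform)
  y <- transform_outcome(as.numeric(data[[outcome]]), transform)
  X <- design_matrix(data, terms)
  if (nrow(X) < ncol(X) + 2) {
    stop("too few complete-case rows (", nrow(X), ") for ", ncol(X),
         " coefficients", call. = FALSE)
  }
  fit <- lstsq(X, y, weights)
  n <- length(y)
  k <- ncol(X)
  sigma2 <- fit$rss / (n - k)
  XtX <- if (is.null(weights)) crossprod(X) else crossprod(X * sqrt(weights))
  vc <- sigma2 * solve(XtX)
  dimnames(vc) <- list(colnames(X), colnames(X))
  ll <- gaussian_loglik(fit$rss, n, weights)
  structure(list(
    coefficients = fit$coef, vcov = vc, sigma2 = sigma2,
    residuals = fit$resid, fitted = fit$fitted,
    n = n, df_residual = n - k,
    loglik = ll, aic = -2 * ll + 2 * (k + 1),
    outcome = outcome, terms = terms, transform = transform,
    weighted = !is.null(weights)
  ), class = "ols_fit")
}

transform_outcome <- function(y, transform) {
  switch(transform,
    identity = y,
    log = {
      if (any(y <= 0)) stop("log transform requires positive outcome", call. = FALSE)
      log(y)
    },
    logit = {
      if (any(y <= 0 | y >= 1)) {
        stop("logit transform requires outcome in (0, 1)", call. = FALSE)
      }
      stats::qlogis(y)
    }
  )
}

#' @export
coef.ols_fit <- function(object, ...) object$coefficients

#' @export
vcov.ols_fit <- function(object, ...) object$vcov

#' @export
print.ols_fit <- function(x, ...) {
  cat("<ols_fit> ", x$outcome,
      if (x$transform != "identity") paste0(" (", x$transform, ")"),
      " ~ ", paste(x$terms, collapse = " + "), "\n", sep = "")
  cat("  n =", x$n, " sigma =", signif(sqrt(x$sigma2), 4),
      " AIC =", round(x$aic, 1), "\n")
  print(round(x$coefficients, 5))
  invisible(x)
}
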