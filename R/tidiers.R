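#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a least-squares or 2SLS fit
#'
#' One row per coefficient with Wald z statistics and Normal-theory
#' p-values and confidence intervals (asymptotic Normality, matching the
#' reporting of the causal models).
#'
#' @param x An `ols_fit` or `iv_fit`.
#' @param conf.int Add Wald confidence limits?
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (and `conf.low`/`conf.high`).
#' @export
tidy.ols_fit <- function(x, conf.int = TRUE, conf.level = 0.95, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- est / se
  out <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(z), p.value = 2 * stats::pnorm(-abs(unname(z)))
  )
  if (conf.int) {
    q <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - q * out$std.error
    out$conf.high <- out$estimate + q * out$std.error
  }
  out
}

#' @rdname tidy.ols_fit
#' @export
tidy.iv_fit <- function(x, conf.int = TRUE, conf.level = 0.95, ...) {
  out <- tidy.ols_fit(x, conf.int = conf.int, conf.level = conf.level, ...)
  out$causal <- out$term %in% x$causal
  out
}

#' One-row summaries of a fit
#'
#' @param x An `ols_fit` or `iv_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `sigma`, `logLik`, `AIC` and, for
#'   IV fits, the minimum first-stage F (`weak_f`).
#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(n = x$n, sigma = sqrt(x$sigma2), logLik = x$loglik,
                 AIC = x$aic, df.residual = x$df_residual)
}

#' @rdname glance.ols_fit
#' @export
glance.iv_fit <- function(x, ...) {
  out <- glance.ols_fit(x, ...)
  out$weak_f <- min(x$first_stage$f_statistic)
  out
}

#' Serialize a fit to JSON
#'
#' Writes coefficients, covariance and diagnostics in a stable layout
#' for downstream tooling.
#'
#' @param fit An `ols_fit` or `iv_fit`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return `path` (invisibly) or a JSON string.
#' @export
write_fit_json <- function(fit, path = NULL) {
  obj <- list(
    class = class(fit)[1],
    outcome = fit$outcome,
    transform = fit$transform,
    n = fit$n,
    coefficients = as.list(fit$coefficients),
    std_error = as.list(stats::setNames(sqrt(diag(fit$vcov)),
                                        names(fit$coefficients))),
    vcov = unname(fit$vcov),
    sigma2 = fit$sigma2,
    aic = fit$aic
  )
  if (inherits(fit, "iv_fit")) {
    obj$first_stage <- list(term = fit$first_stage$term,
                            f_statistic = fit$first_stage$f_statistic,
                            r_squared = fit$first_stage$r_squared)
    obj$instruments <- fit$instruments
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
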