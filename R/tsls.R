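#' Two-stage least squares with multiple instrumented terms
#'
#' Estimates the causal model
#' `outcome ~ 1 + exogenous + causal` where the `causal` terms (e.g. log
#' BMI and its product with centered age) are endogenous and instrumented
#' by the `instruments` (e.g. the allele score and its product with
#' centered age). The first stage regresses every causal term on the
#' intercept, all exogenous covariates and all instruments; the second
#' stage regresses the outcome on the fitted causal terms and the
#' exogenous covariates. The coefficient covariance uses second-stage
#' residuals recomputed with the observed (not fitted) causal terms — the
#' standard 2SLS variance `sigma^2 (Xhat' Xhat)^{-1}` — and equals the
#' closed-form IV solution in the just-identified case.
#'
#' @inheritParams fit_ols
#' @param causal Character vector of endogenous model terms.
#' @param instruments Character vector of excluded instruments; at least
#'   as many as `causal` (just-identified designs allowed).
#' @param exogenous Character vector of exogenous covariate terms.
#' @param weak_f_floor First-stage partial F below this (default 10)
#'   triggers a weak-instrument warning (not an error). A constant
#'   instrument is an error.
#' @param vcov_type `"classical"` homoskedastic covariance (default,
#'   Normal-error theory) or `"robust"` (HC0 sandwich).
#' @return An object of class `iv_fit` (inherits the `ols_fit` accessor
#'   surface): everything in [fit_ols()] plus `causal`, `instruments`,
#'   `exogenous` and `first_stage`, a tibble with one row per causal term
#'   holding the partial F statistic, the first-stage R-squared and the
#'   first-stage coefficients (list column).
#' @export
#' @examples
#' sim <- simulate_cohort(default_config(n_individuals = 800, seed = 3))
#' fr <- add_score(build_frame(sim$cohort, "long_term"),
#'                 compute_score(sim$genotypes, sim_weight_table(sim)))
#' fit <- fit_2sls(fr, "fev1fvc",
#'                 causal = c("log_bmi", "log_bmi:age_c"),
#'                 instruments = c("score", "score:age_c"),
#'                 exogenous = c("age_c", "sex", "height", "packyears"))
#' tidy(fit)
fit_2sls <- function(data, outcome, causal, instruments, exogenous,
                     weights = NULL, weak_f_floor = 10,
                     vcov_type = c("classical", "robust"),
                     transform = c("identity", "log", "logit")) {
  vcov_type <- match.arg(vcov_type)
  transform <- match.arg(transform)
  if (length(instruments) < length(causal)) {
    stop("need at least as many instruments (", length(instruments),
         ") as causal terms (", length(causal), ")", call. = FALSE)
  }
  if (length(intersect(causal, exogenous))) {
    stop("term(s) listed both causal and exogenous: ",
         paste(intersect(causal, exogenous), collapse = ", "), call. = FALSE)
  }
  y <- transform_outcome(as.numeric(data[[outcome]]), transform)
  Xc <- term_matrix(data, causal)
  Xe <- term_matrix(data, exogenous)
  Zi <- term_matrix(data, instruments)
  if (anyNA(cbind(Xc, Xe, Zi, y))) {
    stop("missing values in model variables; restrict to complete cases first",
         call. = FALSE)
  }
  const <- apply(Zi, 2, function(z) stats::sd(z) == 0)
  if (any(const)) {
    stop("constant instrument column(s): ",
         paste(colnames(Zi)[const], collapse = ", "), call. = FALSE)
  }
  n <- length(y)
  Z <- cbind(`(Intercept)` = rep(1, n), Xe, Zi)
  X <- cbind(`(Intercept)` = rep(1, n), Xe, Xc)
  qrZ <- check_full_rank(Z, "instrument")
  qrW <- check_full_rank(cbind(`(Intercept)` = rep(1, n), Xe),
                         "exogenous-covariate")

  # first-stage diagnostics: partial F of the excluded instruments for
  # each causal term
  q <- ncol(Zi)
  kz <- ncol(Z)
  fs <- purrr::map_dfr(seq_along(causal), function(j) {
    x <- Xc[, j]
    r1 <- qr.resid(qrZ, x)
    r0 <- qr.resid(qrW, x)
    rss1 <- sum(r1^2)
    rss0 <- sum(r0^2)
    f <- ((rss0 - rss1) / q) / (rss1 / (n - kz))
    co <- qr.coef(qrZ, x)
    names(co) <- colnames(Z)
    tibble::tibble(term = causal[j], f_statistic = f,
                   r_squared = 1 - rss1 / sum((x - mean(x))^2),
                   coefficients = list(co))
  })
  weak <- fs$term[fs$f_statistic < weak_f_floor]
  if (length(weak)) {
    warning("weak instrument(s): first-stage F below ", weak_f_floor,
            " for ", paste(weak, collapse = ", "), call. = FALSE)
  }

  Xhat <- X
  Xhat[, causal] <- qr.fitted(qrZ, Xc)
  fit2 <- lstsq(Xhat, y, what = "second-stage")
  beta <- fit2$coef
  resid_obs <- y - drop(X %*% beta)          # observed causal terms
  k <- ncol(X)
  sigma2 <- sum(resid_obs^2) / (n - k)
  bread <- solve(crossprod(Xhat))
  vc <- if (vcov_type == "classical") {
    sigma2 * bread
  } else {
    bread %*% crossprod(Xhat * resid_obs) %*% bread
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  rss <- sum(resid_obs^2)
  ll <- gaussian_loglik(rss, n)
  structure(list(
    coefficients = beta, vcov = vc, sigma2 = sigma2,
    residuals = resid_obs, fitted = drop(X %*% beta),
    n = n, df_residual = n - k,
    loglik = ll, aic = -2 * ll + 2 * (k + 1),
    outcome = outcome, terms = c(exogenous, causal), transform = transform,
    causal = causal, instruments = instruments, exogenous = exogenous,
    first_stage = fs, vcov_type = vcov_type
  ), class = c("iv_fit", "ols_fit"))
}

#' @export
print.iv_fit <- function(x, ...) {
  cat("<iv_fit> ", x$outcome,
      if (x$transform != "identity") paste0(" (", x$transform, ")"),
      " ~ ", paste(x$exogenous, collapse = " + "),
      " + [", paste(x$causal, collapse = ", "), " | ",
      paste(x$instruments, collapse = ", "), "]\n", sep = "")
  cat("  n =", x$n, " sigma =", signif(sqrt(x$sigma2), 4),
      " first-stage F:",
      paste(sprintf("%s %.1f", x$first_stage$term, x$first_stage$f_statistic),
            collapse = ", "), "\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' First-stage partial F statistic
#'
#' Partial F comparing the first-stage regression of a causal term on
#' intercept + exogenous covariates + instruments against the nested
#' model without the instruments; numerator degrees of freedom equal the
#' number of instruments.
#'
#' @inheritParams fit_2sls
#' @param causal_term Single causal (endogenous) term.
#' @return The F statistic (numeric scalar) with attributes `df1`, `df2`.
#' @export
first_stage_f <- function(data, causal_term, instruments, exogenous) {
  x <- drop(term_matrix(data, causal_term))
  n <- length(x)
  W <- cbind(`(Intercept)` = rep(1, n), term_matrix(data, exogenous))
  Z <- cbind(W, term_matrix(data, instruments))
  qrW <- check_full_rank(W, "exogenous-covariate")
  qrZ <- check_full_rank(Z, "instrument")
  rss0 <- sum(qr.resid(qrW, x)^2)
  rss1 <- sum(qr.resid(qrZ, x)^2)
  q <- length(instruments)
  f <- ((rss0 - rss1) / q) / (rss1 / (n - ncol(Z)))
  structure(f, df1 = q, df2 = n - ncol(Z))
}

#' Add a product instrument for an instrumented interaction
#'
#' Causal interactions with a concomitant variable (e.g. log BMI x age)
#' are instrumented by the product of the instrument with that same
#' variable (e.g. score x age). This helper materialises the product as a
#' named column; the fitters also accept `"a:b"` terms directly, in which
#' case the product is formed on the fly.
#'
#' @param frame Data frame with the instrument and the concomitant
#'   variable.
#' @param instrument,with Column names.
#' @return `frame` with an added column named `<instrument>:<with>`.
#' @export
add_interaction_instrument <- function(frame, instrument = "score",
                                       with = "age_c") {
  stopifnot(instrument %in% names(frame), with %in% names(frame))
  frame[[paste0(instrument, ":", with)]] <-
    as.numeric(frame[[instrument]]) * as.numeric(frame[[with]])
  frame
}
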