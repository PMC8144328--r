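#' Causal BMI effect at a given centered age
#'
#' The model's causal effect of log BMI on the outcome at centered age
#' `a` is `beta_c1 + beta_c2 * a` (the main effect plus the age
#' interaction). The standard error carries the joint covariance of the
#' two coefficients through the delta method:
#' `SE^2 = Var(b1) + a^2 Var(b2) + 2 a Cov(b1, b2)`; confidence intervals
#' are Wald intervals from asymptotic Normality.
#'
#' @param fit An `iv_fit` or `ols_fit` containing the main and
#'   interaction coefficients and their covariance.
#' @param age_c Centered age(s) in years (age minus 18); vectorized.
#' @param main,interaction Names of the main-effect and interaction
#'   terms.
#' @param level Confidence level.
#' @return Tibble with `age_c`, `estimate`, `se`, `conf.low`,
#'   `conf.high`.
#' @export
effect_at_age <- function(fit, age_c, main = "log_bmi",
                          interaction = "log_bmi:age_c", level = 0.95) {
  co <- coef(fit)
  vc <- vcov(fit)
  if (!all(c(main, interaction) %in% names(co))) {
    stop("fit lacks term(s) ", main, " / ", interaction, call. = FALSE)
  }
  if (is.null(vc) || anyNA(vc[c(main, interaction), c(main, interaction)])) {
    stop("fit lacks the joint covariance of the causal coefficients",
         call. = FALSE)
  }
  est <- co[[main]] + co[[interaction]] * age_c
  se <- sqrt(vc[main, main] + age_c^2 * vc[interaction, interaction] +
               2 * age_c * vc[main, interaction])
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(age_c = age_c, estimate = est, se = se,
                 conf.low = est - z * se, conf.high = est + z * se)
}

#' Predicted lung-function change for a BMI change
#'
#' For a BMI change from `bmi_from` to `bmi_to` at centered age `a`, the
#' model-implied change in expected outcome is
#' `(beta_c1 + beta_c2 * a + beta_sex * sex) * (ln(bmi_to) - ln(bmi_from))`.
#' The sex term enters only for models that contain a log-BMI x sex
#' interaction (long-term models); for a male reference individual
#' (`sex = 0`) it vanishes, and the remaining profile covariates (height,
#' smoking) cancel in the difference.
#'
#' @param fit An `iv_fit`/`ols_fit`, or a named numeric vector of
#'   coefficients (e.g. published point estimates) containing at least
#'   `main` and `interaction`; with a bare vector no standard error is
#'   available and `se` is `NA`.
#' @param bmi_from,bmi_to Positive BMI values in kg/m2.
#' @param age_c Centered age (years beyond 18); vectorized.
#' @param sex 0 = male, 1 = female.
#' @param main,interaction,sex_term Coefficient names.
#' @param level Confidence level.
#' @return Tibble with `age_c`, `delta` (change in expected outcome),
#'   `se`, `conf.low`, `conf.high`.
#' @export
#' @examples
#' # published long-term coefficients: decrease of ~0.10 at mean age 28
#' predict_bmi_delta(c(log_bmi = -0.752, `log_bmi:age_c` = 0.021),
#'                   bmi_from = 25, bmi_to = 30, age_c = 10)
predict_bmi_delta <- function(fit, bmi_from, bmi_to, age_c, sex = 0,
                              main = "log_bmi",
                              interaction = "log_bmi:age_c",
                              sex_term = "log_bmi:sex", level = 0.95) {
  if (any(bmi_from <= 0) || any(bmi_to <= 0)) {
    stop("BMI values must be positive", call. = FALSE)
  }
  co <- if (is.numeric(fit)) fit else coef(fit)
  vc <- if (is.numeric(fit)) NULL else vcov(fit)
  if (!all(c(main, interaction) %in% names(co))) {
    stop("coefficients lack term(s) ", main, " / ", interaction, call. = FALSE)
  }
  lr <- log(bmi_to) - log(bmi_from)
  has_sex <- sex_term %in% names(co)
  mult <- co[[main]] + co[[interaction]] * age_c +
    (if (has_sex) co[[sex_term]] * sex else 0)
  delta <- mult * lr
  se <- rep(NA_real_, length(delta))
  if (!is.null(vc)) {
    nm <- c(main, interaction, if (has_sex) sex_term)
    V <- vc[nm, nm, drop = FALSE]
    se <- vapply(seq_along(age_c), function(i) {
      g <- c(1, age_c[i], if (has_sex) sex) * lr
      sqrt(drop(t(g) %*% V %*% g))
    }, numeric(1))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(age_c = age_c, delta = delta, se = se,
                 conf.low = delta - z * se, conf.high = delta + z * se)
}

#' AIC comparison across fitted models
#'
#' Ranks fits by AIC (`-2 loglik + 2 (k + 1)` under Normal errors).
#' Comparisons require identical sample sizes, and outcome transforms
#' must agree: AIC values on differently transformed outcomes are not
#' comparable without a Jacobian correction, which this function refuses
#' to guess (it errors, naming the transforms).
#'
#' @param fits Named list of `ols_fit`/`iv_fit` objects.
#' @return Tibble sorted by AIC with `model`, `outcome`, `n`, `aic`,
#'   `delta_aic` (relative to the best model).
#' @export
aic_compare <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) > 1) {
    stop("fits use differing sample sizes: ",
         paste(unique(ns), collapse = ", "), call. = FALSE)
  }
  tr <- vapply(fits, function(f) f$transform, character(1))
  if (length(unique(tr)) > 1) {
    stop("fits use differing outcome transforms (",
         paste(unique(tr), collapse = ", "),
         "); AIC is not comparable across transformed outcomes without a ",
         "Jacobian correction", call. = FALSE)
  }
  out <- tibble::tibble(
    model = names(fits),
    outcome = vapply(fits, function(f) f$outcome, character(1)),
    n = unname(ns),
    aic = unname(vapply(fits, function(f) f$aic, numeric(1)))
  ) |>
    dplyr::arrange(.data$aic) |>
    dplyr::mutate(delta_aic = .data$aic - .data$aic[1])
  out
}
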