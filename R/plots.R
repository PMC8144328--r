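#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Predicted lung-function change versus BMI, by age
#'
#' Curves of the model-implied change in expected outcome when BMI moves
#' from `ref_bmi` to each value on the x axis, one curve per attained
#' age, for a reference individual (male, covariates cancel in the
#' difference).
#'
#' @param fit An `iv_fit`/`ols_fit` (or named coefficient vector).
#' @param ages Attained ages in years (converted internally to centered
#'   age, age minus 18).
#' @param bmi BMI grid (kg/m2).
#' @param ref_bmi Reference BMI at which the change is zero.
#' @param sex Profile sex (0 = male).
#' @return A ggplot object.
#' @export
plot_effect_curve <- function(fit, ages = c(28, 38, 48, 58, 68),
                              bmi = seq(20, 35, by = 0.25), ref_bmi = 25,
                              sex = 0) {
  grid <- tidyr::expand_grid(age = ages, bmi = bmi)
  grid$delta <- purrr::map2_dbl(grid$age, grid$bmi, function(a, b) {
    predict_bmi_delta(fit, ref_bmi, b, age_c = a - 18, sex = sex)$delta
  })
  grid$age <- factor(grid$age)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$bmi, y = .data$delta,
                                     colour = .data$age)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "BMI (kg/m²)",
                  y = sprintf("Predicted change vs BMI = %g", ref_bmi),
                  colour = "Age (years)") +
    ggplot2::theme_minimal()
}

#' Causal effect of log BMI across age, with Wald band
#'
#' @param object An `iv_fit` with log-BMI main and age-interaction terms.
#' @param ages Attained ages (years).
#' @param ... Passed to [effect_at_age()].
#' @return A ggplot object.
#' @export
autoplot.iv_fit <- function(object, ages = 18:70, ...) {
  eff <- effect_at_age(object, age_c = ages - 18, ...)
  eff$age <- ages
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$age, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue4", linewidth = 0.9) +
    ggplot2::labs(x = "Age (years)",
                  y = "Causal effect of log BMI on outcome") +
    ggplot2::theme_minimal()
}

#' Forest plot of causal versus observational estimates
#'
#' @param fits Named list of `ols_fit`/`iv_fit` objects (e.g. causal and
#'   observational fits of both survey schemes).
#' @param terms Coefficients to display.
#' @return A ggplot object.
#' @export
plot_forest <- function(fits, terms = c("log_bmi", "log_bmi:age_c")) {
  tab <- purrr::imap_dfr(fits, function(f, nm) {
    td <- tidy(f)
    td <- td[td$term %in% terms, ]
    td$model <- nm
    td
  })
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$model)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "Estimate (95% Wald CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Lung function by obesity stratum across surveys
#'
#' @param object Output of [obesity_strata_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_obesity_strata <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$survey), y = .data$mean,
                               colour = .data$stratum, group = .data$stratum)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                             position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "Survey", y = "Mean (IQR)", colour = "Stratum") +
    ggplot2::theme_minimal()
}
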