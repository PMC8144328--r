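#' Sensitivity-analysis suite
#'
#' Re-examines the causal conclusions under the standard perturbations:
#'
#' * `transformed`: final causal models re-fitted with log-transformed
#'   FEF25-75 and logit-transformed FEV1/FVC outcomes, with the sign of
#'   the causal main effect compared against the untransformed fit;
#' * `ratio_outcome`: the causal model with FEF25-75/FVC (a dysanapsis
#'   indicator) as outcome;
#' * `non_asthmatic`: the causal model restricted to individuals who
#'   never reported doctor-diagnosed asthma;
#' * `score_bmi_by_survey`: per-survey regressions of log BMI on the
#'   score (checking the reliability of baseline self-reported weight by
#'   comparing coefficients and R-squared across surveys);
#' * `change_on_change`: observational regression of the change in lung
#'   function (survey 3 minus survey 1) on the change in BMI with
#'   baseline covariates.
#'
#' Items that error are reported as such and the suite continues.
#'
#' @param cohort Long cohort table.
#' @param frame Analysis frame with a `score` column.
#' @param which Survey scheme; defaults to the frame's attribute.
#' @return List of class `mr_sensitivity` with one element per item
#'   (tibbles, or a character error message).
#' @export
sensitivity_suite <- function(cohort, frame, which = NULL) {
  if (is.null(which)) which <- attr(frame, "which") %||% "long_term"
  res <- list()
  run_item <- function(expr) {
    tryCatch(expr, error = function(e) paste("item failed:", conditionMessage(e)))
  }

  res$transformed <- run_item({
    purrr::map_dfr(
      list(c("fev1fvc", "identity"), c("fev1fvc", "logit"),
           c("fef2575", "identity"), c("fef2575", "log")),
      function(it) {
        ft <- run_model(frame, which, "causal", outcome = it[1],
                        transform = it[2])
        td <- tidy(ft)
        td <- td[td$term == "log_bmi", ]
        tibble::tibble(outcome = it[1], transform = it[2],
                       estimate = td$estimate, std.error = td$std.error,
                       p.value = td$p.value)
      }) |>
      dplyr::group_by(.data$outcome) |>
      dplyr::mutate(sign_matches_identity =
                      sign(.data$estimate) ==
                      sign(.data$estimate[.data$transform == "identity"])) |>
      dplyr::ungroup()
  })

  res$ratio_outcome <- run_item({
    ft <- run_model(frame, which, "causal", outcome = "fef2575_fvc")
    td <- tidy(ft)
    td[td$causal, c("term", "estimate", "std.error", "p.value")]
  })

  res$non_asthmatic <- run_item({
    sub <- dplyr::filter(frame, .data$asthma_ever == 0)
    ft <- run_model(sub, which, "causal")
    td <- tidy(ft)
    out <- td[td$causal, c("term", "estimate", "std.error", "p.value")]
    out$n <- nrow(sub)
    out
  })

  res$score_bmi_by_survey <- run_item({
    purrr::map_dfr(1:3, function(s) {
      bcol <- paste0("bmi_s", s)
      d <- frame[!is.na(frame[[bcol]]), ]
      d$log_bmi_s <- log(d[[bcol]])
      d$age_s <- d$age_s1 + 10 * (s - 1) - 18
      ft <- fit_ols(d, "log_bmi_s", c("score", "age_s", "sex"))
      td <- tidy(ft)
      sc <- td[td$term == "score", ]
      fs <- fit_ols(d, "log_bmi_s", "score")
      r2 <- 1 - sum(fs$residuals^2) /
        sum((d$log_bmi_s - mean(d$log_bmi_s))^2)
      tibble::tibble(survey = s, n = nrow(d), estimate = sc$estimate,
                     std.error = sc$std.error, r_squared = r2)
    })
  })

  res$change_on_change <- run_item({
    d <- frame |>
      dplyr::mutate(d_lf = .data$fev1fvc_s3 - .data$fev1fvc_s1,
                    d_bmi = .data$bmi_s3 - .data$bmi_s1) |>
      dplyr::filter(!is.na(.data$d_lf), !is.na(.data$d_bmi))
    ft <- fit_ols(d, "d_lf", c("d_bmi", "age_s1", "sex", "height",
                               "packyears"))
    td <- tidy(ft)
    out <- td[td$term == "d_bmi", c("term", "estimate", "std.error", "p.value")]
    out$n <- nrow(d)
    out
  })

  structure(res, class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat("<mr_sensitivity> items:", paste(names(x), collapse = ", "), "\n")
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    print(x[[nm]])
  }
  invisible(x)
}
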