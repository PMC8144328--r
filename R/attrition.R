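#' Inverse-probability-weighted observational analysis
#'
#' Interrogates attrition bias by re-fitting the observational final
#' model with inverse-probability-of-participation weights under two
#' weighting schemes:
#' 1. probability of participating in surveys 2 *and* 3 given the model
#'    variables measured at survey 1;
#' 2. probability of participating in survey 3 given the model variables
#'    averaged over surveys 1-2 (fitted among survey-1-and-2
#'    participants).
#'
#' Participation probabilities come from logistic regressions; weights
#' are their reciprocals, truncated at a configurable upper quantile
#' (default the 99th percentile). With uniform participation all weights
#' are equal and the weighted fits coincide with the unweighted fit.
#'
#' @param cohort Long cohort table (provides the participation flags and
#'   the survey-1 / survey-1-2 covariates).
#' @param frame Analysis frame (the complete cases to re-fit).
#' @param which Survey scheme of the frame.
#' @param outcome Lung-function outcome column (also used, at its
#'   baseline value, in the participation models).
#' @param truncate_quantile Upper quantile at which weights are capped;
#'   `NULL` disables truncation.
#' @return List of class `ipw_result`: `unweighted`, `scheme1`,
#'   `scheme2` (each an `ols_fit`), `weights` (per-id tibble with both
#'   weights), `truncation` (the caps applied).
#' @export
ipw_analysis <- function(cohort, frame, which = NULL, outcome = "fev1fvc",
                         truncate_quantile = 0.99) {
  if (is.null(which)) which <- attr(frame, "which") %||% "long_term"
  cohort <- tibble::as_tibble(cohort)

  s1 <- dplyr::filter(cohort, .data$survey == 1)
  part <- cohort |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      in_s2 = any(.data$survey == 2 & .data$participated == 1),
      in_s3 = any(.data$survey == 3 & .data$participated == 1),
      .groups = "drop")
  d1 <- dplyr::inner_join(s1, part, by = "id") |>
    dplyr::mutate(both = as.integer(.data$in_s2 & .data$in_s3),
                  lf = .data[[outcome]]) |>
    dplyr::filter(!is.na(.data$bmi), !is.na(.data$lf),
                  !is.na(.data$packyears))
  p1 <- fit_participation(d1, "both",
                          c("bmi", "lf", "age", "sex", "height", "packyears"))

  s12 <- cohort |>
    dplyr::filter(.data$survey %in% 1:2, .data$participated == 1) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n12 = dplyr::n(),
      bmi = mean(.data$bmi, na.rm = TRUE),
      lf = mean(.data[[outcome]], na.rm = TRUE),
      age = mean(.data$age, na.rm = TRUE),
      sex = .data$sex[1],
      height = mean(.data$height, na.rm = TRUE),
      packyears = max(.data$packyears, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::filter(.data$n12 == 2L) |>
    dplyr::inner_join(part, by = "id") |>
    dplyr::mutate(s3 = as.integer(.data$in_s3)) |>
    dplyr::filter(!is.na(.data$bmi), !is.na(.data$lf),
                  is.finite(.data$packyears))
  p2 <- fit_participation(s12, "s3",
                          c("bmi", "lf", "age", "sex", "height", "packyears"))

  wtab <- tibble::tibble(id = frame$id) |>
    dplyr::left_join(tibble::tibble(id = d1$id, w1 = 1 / p1), by = "id") |>
    dplyr::left_join(tibble::tibble(id = s12$id, w2 = 1 / p2), by = "id")
  caps <- c(w1 = NA_real_, w2 = NA_real_)
  if (!is.null(truncate_quantile)) {
    for (wc in c("w1", "w2")) {
      caps[wc] <- stats::quantile(wtab[[wc]], truncate_quantile,
                                  na.rm = TRUE, names = FALSE)
      wtab[[wc]] <- pmin(wtab[[wc]], caps[wc])
    }
  }
  if (anyNA(wtab$w1) || anyNA(wtab$w2)) {
    stop("some complete-case individuals lack a participation probability",
         call. = FALSE)
  }

  unweighted <- run_model(frame, which, "observational", outcome)
  scheme1 <- run_model(frame, which, "observational", outcome,
                       weights = wtab$w1)
  scheme2 <- run_model(frame, which, "observational", outcome,
                       weights = wtab$w2)
  structure(list(unweighted = unweighted, scheme1 = scheme1,
                 scheme2 = scheme2, weights = wtab,
                 truncation = caps, truncate_quantile = truncate_quantile),
            class = "ipw_result")
}

fit_participation <- function(d, flag, covars) {
  if (all(d[[flag]] == 1)) return(rep(1, nrow(d)))
  fml <- stats::as.formula(paste(flag, "~", paste(covars, collapse = " + ")))
  gfit <- stats::glm(fml, data = d, family = stats::binomial())
  co <- stats::coef(gfit)[-1]
  big <- abs(co) * vapply(d[covars], stats::sd, numeric(1)) > 15
  if (any(big, na.rm = TRUE)) {
    stop("separation in the participation model; offending covariate(s): ",
         paste(names(co)[which(big)], collapse = ", "), call. = FALSE)
  }
  stats::fitted(gfit)
}

#' @export
print.ipw_result <- function(x, ...) {
  cat("<ipw_result>\n")
  pick <- function(f) stats::coef(f)[["log_bmi"]]
  cat(sprintf("  log-BMI main effect: unweighted %.4g, scheme1 %.4g, scheme2 %.4g\n",
              pick(x$unweighted), pick(x$scheme1), pick(x$scheme2)))
  if (!is.null(x$truncate_quantile)) {
    cat(sprintf("  weights truncated at the %.0fth percentile (caps %.2f / %.2f)\n",
                100 * x$truncate_quantile, x$truncation[["w1"]],
                x$truncation[["w2"]]))
  }
  invisible(x)
}

#' Age-tertile stratified causal fits
#'
#' Fits the final causal model, without the BMI x age interaction,
#' separately in strata defined by tertiles of baseline age (empirical
#' quantiles; interval boundaries are closed on the left stratum, i.e.
#' ties go to the lower stratum).
#'
#' @param frame Analysis frame with `score` and `age_s1` columns.
#' @param outcome Outcome column.
#' @param n_min Strata smaller than this trigger a warning.
#' @return Tibble of class `age_strata`: one row per stratum with the
#'   age range, n, the causal log-BMI estimate, SE, Wald CI and
#'   first-stage F; attribute `fits` holds the three `iv_fit`s and
#'   `cutpoints` the tertile boundaries.
#' @export
stratified_by_age <- function(frame, outcome = "fev1fvc", n_min = 100) {
  stopifnot(all(c("score", "age_s1") %in% names(frame)))
  a <- frame$age_s1
  q <- stats::quantile(a, c(1 / 3, 2 / 3), names = FALSE)
  if (stats::sd(a) == 0 || q[1] == q[2]) {
    stop("baseline age (near-)constant; age tertiles undefined", call. = FALSE)
  }
  stratum <- 1L + (a > q[1]) + (a > q[2])
  fits <- vector("list", 3)
  rows <- purrr::map_dfr(1:3, function(s) {
    d <- frame[stratum == s, ]
    if (nrow(d) < n_min) {
      warning("age stratum ", s, " has only ", nrow(d), " individuals",
              call. = FALSE)
    }
    ft <- fit_2sls(d, outcome, causal = "log_bmi", instruments = "score",
                   exogenous = c("age_c", "sex", "height", "packyears",
                                 "age_c:sex", "age_c:height"))
    fits[[s]] <<- ft
    td <- tidy(ft)
    td <- td[td$term == "log_bmi", ]
    tibble::tibble(stratum = s,
                   age_min = min(d$age_s1), age_max = max(d$age_s1),
                   n = nrow(d), estimate = td$estimate,
                   std.error = td$std.error,
                   conf.low = td$conf.low, conf.high = td$conf.high,
                   first_stage_f = ft$first_stage$f_statistic[1])
  })
  attr(rows, "cutpoints") <- q
  attr(rows, "fits") <- fits
  class(rows) <- c("age_strata", class(rows))
  rows
}
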