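#' Final-model term sets
#'
#' The selected causal model retains (instrumented) log BMI and its age
#' interaction plus age, sex, height, packyears and the age x sex and
#' age x height interactions; the long-term model additionally carries a
#' log-BMI x sex interaction, which — like every BMI interaction — is
#' itself instrumented by the product of the score with the concomitant
#' variable.
#'
#' @param which `"predictive"` or `"long_term"`.
#' @param include_interaction Keep the instrumented BMI x age term?
#'   (Age-stratified fits drop it.)
#' @return List with `causal`, `instruments`, `exogenous`.
#' @export
model_terms <- function(which = c("predictive", "long_term"),
                        include_interaction = TRUE) {
  which <- match.arg(which)
  causal <- "log_bmi"
  instruments <- "score"
  if (include_interaction) {
    causal <- c(causal, "log_bmi:age_c")
    instruments <- c(instruments, "score:age_c")
  }
  if (which == "long_term") {
    causal <- c(causal, "log_bmi:sex")
    instruments <- c(instruments, "score:sex")
  }
  list(causal = causal, instruments = instruments,
       exogenous = c("age_c", "sex", "height", "packyears",
                     "age_c:sex", "age_c:height"))
}

#' Fit a final causal or observational model
#'
#' Dispatches the selected model for the requested survey-averaging
#' scheme: in `"causal"` mode the BMI terms are instrumented by the
#' allele score (and its products with the concomitant variables) via
#' [fit_2sls()]; in `"observational"` mode the identical term set is
#' re-fitted by OLS using observed BMI.
#'
#' @param frame Analysis frame from [build_frame()] + [add_score()].
#' @param which Survey scheme; defaults to the frame's `which` attribute.
#' @param mode `"causal"` (2SLS) or `"observational"` (OLS).
#' @param outcome Outcome column (default FEV1/FVC).
#' @param transform Outcome transform (sensitivity analyses use `"log"`
#'   for FEF25-75 and `"logit"` for FEV1/FVC).
#' @param include_interaction Keep the BMI x age term?
#' @param extra_exogenous Additional exogenous covariate terms (hook for
#'   e.g. study-center or education adjustment checks).
#' @param ... Passed to [fit_2sls()] / [fit_ols()].
#' @return An `iv_fit` (causal) or `ols_fit` (observational).
#' @export
run_model <- function(frame, which = NULL,
                      mode = c("causal", "observational"),
                      outcome = "fev1fvc",
                      transform = c("identity", "log", "logit"),
                      include_interaction = TRUE,
                      extra_exogenous = character(), ...) {
  mode <- match.arg(mode)
  transform <- match.arg(transform)
  if (is.null(which)) which <- attr(frame, "which") %||% "long_term"
  tm <- model_terms(which, include_interaction)
  exog <- c(tm$exogenous, extra_exogenous)
  if (mode == "causal") {
    fit_2sls(frame, outcome, causal = tm$causal,
             instruments = tm$instruments, exogenous = exog,
             transform = transform, ...)
  } else {
    fit_ols(frame, outcome, terms = c(exog, tm$causal),
            transform = transform, ...)
  }
}

verdict_from_p <- function(p, alpha) {
  dplyr::case_when(p < alpha ~ "fail", p < 2 * alpha ~ "warn",
                   TRUE ~ "pass")
}

#' Check the instrumental-variable assumptions
#'
#' Runs the core checks for using the allele score as an instrument:
#' (1) relevance — first-stage partial F of the score on log BMI;
#' (2a) no association of the score with the observed confounders
#' packyears and height; (2b) no age/sex modification of the score-BMI
#' association (joint F test of all score interactions in the full
#' score x age x sex regression); (3) exclusion — no association of the
#' score with the outcome conditional on BMI and observed confounders;
#' and, when genotypes and weights are supplied, an MR-Egger pleiotropy
#' check. Verdicts are three-valued (`pass`/`warn`/`fail`) with the
#' thresholds recorded alongside; upstream SNP exclusions (phenotype
#' lists) are assumed done in the score-construction step and can be
#' attached via the `filter_log` argument.
#'
#' @param frame Analysis frame with a `score` column.
#' @param outcome Outcome column.
#' @param genotypes Optional genotype tibble for the Egger check.
#' @param weights Optional weight table naming the SNPs of the score.
#' @param filter_log Optional filter log from [filter_snps()], recorded
#'   in the report.
#' @param alpha Significance level for the null checks; `p < alpha`
#'   fails, `p < 2 alpha` warns.
#' @param f_floor Weak-instrument floor for the relevance check.
#' @return A tibble of class `assumption_report`: `check`, `model`,
#'   `estimate`, `statistic`, `p_value`, `threshold`, `verdict`.
#' @export
run_assumption_checks <- function(frame, outcome = "fev1fvc",
                                  genotypes = NULL, weights = NULL,
                                  filter_log = NULL,
                                  alpha = 0.05, f_floor = 10) {
  stopifnot("score" %in% names(frame))
  base_cov <- c("age_c", "sex", "height", "packyears")
  rows <- list()

  # (1) relevance
  f <- first_stage_f(frame, "log_bmi", "score",
                     setdiff(base_cov, character(0)))
  rows$relevance <- tibble::tibble(
    check = "1: score-exposure association",
    model = "log_bmi ~ score + covariates",
    estimate = NA_real_, statistic = as.numeric(f),
    p_value = stats::pf(as.numeric(f), attr(f, "df1"), attr(f, "df2"),
                        lower.tail = FALSE),
    threshold = sprintf("F > %g", f_floor),
    verdict = dplyr::case_when(as.numeric(f) > f_floor ~ "pass",
                               as.numeric(f) > f_floor / 2 ~ "warn",
                               TRUE ~ "fail"))

  # (2.1) observed confounders
  for (conf in c("packyears", "height")) {
    ft <- fit_ols(frame, conf, c("score", setdiff(base_cov, conf)))
    td <- tidy(ft)
    sc <- td[td$term == "score", ]
    rows[[paste0("conf_", conf)]] <- tibble::tibble(
      check = paste0("2.1: score-", conf, " association"),
      model = paste0(conf, " ~ score + covariates"),
      estimate = sc$estimate, statistic = sc$statistic,
      p_value = sc$p.value,
      threshold = sprintf("p > %g", alpha),
      verdict = verdict_from_p(sc$p.value, alpha))
  }

  # (2.4) age/sex modification of the score-BMI association
  full_terms <- c("score", "age_c", "sex", "score:age_c", "score:sex",
                  "age_c:sex", "score:age_c:sex")
  red_terms <- c("score", "age_c", "sex", "age_c:sex")
  f_full <- fit_ols(frame, "log_bmi", full_terms)
  f_red <- fit_ols(frame, "log_bmi", red_terms)
  rss1 <- sum(f_full$residuals^2)
  rss0 <- sum(f_red$residuals^2)
  q <- length(full_terms) - length(red_terms)
  df2 <- f_full$df_residual
  fmod <- ((rss0 - rss1) / q) / (rss1 / df2)
  pmod <- stats::pf(fmod, q, df2, lower.tail = FALSE)
  rows$modification <- tibble::tibble(
    check = "2.4: age/sex modification of score-BMI association",
    model = "log_bmi ~ score * age_c * sex (joint F on score interactions)",
    estimate = NA_real_, statistic = fmod, p_value = pmod,
    threshold = sprintf("p > %g", alpha),
    verdict = verdict_from_p(pmod, alpha))

  # (3) exclusion: score-outcome association conditional on exposure
  ft3 <- fit_ols(frame, outcome, c("score", "log_bmi", base_cov))
  sc3 <- tidy(ft3)
  sc3 <- sc3[sc3$term == "score", ]
  rows$exclusion <- tibble::tibble(
    check = "3: score-outcome association given exposure",
    model = paste0(outcome, " ~ score + log_bmi + covariates"),
    estimate = sc3$estimate, statistic = sc3$statistic,
    p_value = sc3$p.value,
    threshold = sprintf("p > %g", alpha),
    verdict = verdict_from_p(sc3$p.value, alpha))

  # (2.3) MR-Egger pleiotropy, when per-SNP data are available
  if (!is.null(genotypes)) {
    snp <- per_snp_associations(genotypes, frame, weights = weights,
                                outcome = outcome)
    # dosages from a weight table are pre-oriented to the BMI-increasing
    # allele; do not re-orient on estimated signs
    eg <- mr_egger(snp, orient_by_sign = is.null(weights))
    rows$egger <- tibble::tibble(
      check = "2.3: MR-Egger pleiotropy (intercept)",
      model = sprintf("Egger over %d SNPs", eg$n_snps),
      estimate = eg$intercept, statistic = eg$intercept / eg$intercept_se,
      p_value = eg$intercept_p,
      threshold = sprintf("p > %g", alpha),
      verdict = verdict_from_p(eg$intercept_p, alpha))
  }

  out <- dplyr::bind_rows(rows)
  if (!is.null(filter_log)) attr(out, "filter_log") <- filter_log
  class(out) <- c("assumption_report", class(out))
  out
}

#' Per-SNP exposure and outcome associations
#'
#' For each SNP, covariate-adjusted least-squares regressions of the
#' exposure and of the outcome on the dosage (one-sample construction:
#' both regressions use the same individuals). Monomorphic SNPs are
#' dropped with a log entry. With `interaction_with`, the per-SNP
#' coefficients are instead those of the dosage x variable product in
#' regressions of the exposure x variable (respectively outcome) on
#' covariates, dosage and the product — the generalization used for
#' interaction pleiotropy checks.
#'
#' @param genotypes Genotype tibble (`id` + dosage columns).
#' @param frame Analysis frame (provides exposure, outcome, covariates).
#' @param weights Optional weight table restricting and ordering the
#'   SNPs.
#' @param outcome,exposure Column names in `frame`.
#' @param covariates Adjustment terms.
#' @param interaction_with Optional concomitant variable (e.g.
#'   `"age_c"`) for the interaction construction.
#' @return Tibble `snp_id`, `exposure_beta`, `exposure_se`,
#'   `outcome_beta`, `outcome_se`, `n`; attribute `dropped` lists
#'   monomorphic SNPs.
#' @export
per_snp_associations <- function(genotypes, frame, weights = NULL,
                                 outcome = "fev1fvc", exposure = "log_bmi",
                                 covariates = c("age_c", "sex", "height",
                                                "packyears"),
                                 interaction_with = NULL) {
  snp_ids <- if (!is.null(weights)) weights$snp_id
             else setdiff(names(genotypes), "id")
  absent <- setdiff(snp_ids, names(genotypes))
  if (length(absent)) {
    stop("SNP(s) absent from genotype matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  d <- dplyr::inner_join(frame, genotypes[c("id", snp_ids)], by = "id")
  G <- as.matrix(d[snp_ids])
  mono <- apply(G, 2, function(g) stats::sd(g) == 0)
  if (any(mono)) {
    rlang::inform(paste("dropping monomorphic SNP(s):",
                        paste(snp_ids[mono], collapse = ", ")),
                  class = "mrlung_exclusions")
    snp_ids <- snp_ids[!mono]
    G <- G[, !mono, drop = FALSE]
  }
  n <- nrow(d)
  y <- as.numeric(d[[outcome]])
  x <- as.numeric(d[[exposure]])
  C <- design_matrix(d, covariates)

  if (is.null(interaction_with)) {
    # Frisch-Waugh: residualize exposure, outcome and all dosages on the
    # covariates once, then per-SNP simple regressions on the residuals
    qrC <- check_full_rank(C, "covariate")
    ry <- qr.resid(qrC, y)
    rx <- qr.resid(qrC, x)
    RG <- qr.resid(qrC, G)
    ss <- colSums(RG^2)
    df <- n - ncol(C) - 1L
    slope_se <- function(r) {
      b <- colSums(RG * r) / ss
      s2 <- (sum(r^2) - b^2 * ss) / df
      list(beta = b, se = sqrt(s2 / ss))
    }
    ex <- slope_se(rx)
    ou <- slope_se(ry)
    out <- tibble::tibble(snp_id = snp_ids,
                          exposure_beta = unname(ex$beta),
                          exposure_se = unname(ex$se),
                          outcome_beta = unname(ou$beta),
                          outcome_se = unname(ou$se), n = n)
  } else {
    a <- as.numeric(d[[interaction_with]])
    xi <- x * a
    yi <- y
    out <- purrr::map_dfr(seq_along(snp_ids), function(j) {
      g <- G[, j]
      X <- cbind(C, g = g, gxa = g * a)
      k <- ncol(X)
      fx <- lstsq(X, xi)
      fy <- lstsq(X, yi)
      XtXi <- chol2inv(chol(crossprod(X)))
      vjj <- XtXi[k, k]
      tibble::tibble(
        snp_id = snp_ids[j],
        exposure_beta = fx$coef[[k]],
        exposure_se = sqrt(fx$rss / (n - k) * vjj),
        outcome_beta = fy$coef[[k]],
        outcome_se = sqrt(fy$rss / (n - k) * vjj),
        n = n)
    })
  }
  attr(out, "dropped") <- names(mono)[mono]
  out
}

#' MR-Egger regression
#'
#' Regresses per-SNP outcome associations on per-SNP exposure
#' associations with an intercept; a non-zero intercept indicates
#' directional pleiotropy. SNPs are oriented so that all exposure
#' associations are positive (sign pairs flipped); with
#' `weighted = TRUE` the regression is inverse-variance weighted by the
#' outcome-association variances. Intercept and slope are tested with t
#' statistics on `n_snps - 2` degrees of freedom.
#'
#' @param per_snp Output of [per_snp_associations()].
#' @param weighted Inverse-variance weighting?
#' @param orient_by_sign Force exposure betas positive by flipping SNP
#'   sign pairs. Use this when allele orientation is unknown; when the
#'   dosages are already oriented to the trait-increasing allele by a
#'   weight table, set it to `FALSE` — flipping on noisy estimated signs
#'   attenuates the intercept when per-SNP instruments are individually
#'   weak (sign errors carry the direct effect with the wrong sign).
#' @return List of class `egger_result`: `intercept`, `intercept_se`,
#'   `intercept_p`, `slope`, `slope_se`, `slope_p`, `n_snps`, `table`
#'   (the oriented per-SNP table used).
#' @export
mr_egger <- function(per_snp, weighted = TRUE, orient_by_sign = TRUE) {
  stopifnot(all(c("exposure_beta", "exposure_se", "outcome_beta",
                  "outcome_se") %in% names(per_snp)))
  if (nrow(per_snp) < 3) {
    stop("MR-Egger requires at least 3 SNPs, got ", nrow(per_snp),
         call. = FALSE)
  }
  tab <- tibble::as_tibble(per_snp)
  if (orient_by_sign) {
    flip <- sign(tab$exposure_beta)
    flip[flip == 0] <- 1
    tab$exposure_beta <- tab$exposure_beta * flip
    tab$outcome_beta <- tab$outcome_beta * flip
  }
  w <- if (weighted) 1 / tab$outcome_se^2 else NULL
  X <- cbind(`(Intercept)` = 1, exposure_beta = tab$exposure_beta)
  fit <- lstsq(X, tab$outcome_beta, w)
  m <- nrow(tab)
  s2 <- fit$rss / (m - 2)
  XtX <- if (is.null(w)) crossprod(X) else crossprod(X * sqrt(w))
  vc <- s2 * solve(XtX)
  se <- sqrt(diag(vc))
  tt <- fit$coef / se
  pp <- 2 * stats::pt(-abs(tt), df = m - 2)
  structure(list(
    intercept = fit$coef[[1]], intercept_se = se[[1]], intercept_p = pp[[1]],
    slope = fit$coef[[2]], slope_se = se[[2]], slope_p = pp[[2]],
    n_snps = m, weighted = weighted, table = tab
  ), class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  cat("<egger_result> ", x$n_snps, "SNPs",
      if (x$weighted) "(inverse-variance weighted)" else "(unweighted)", "\n")
  cat(sprintf("  intercept %.4g (SE %.3g, p = %.3g)  [pleiotropy test]\n",
              x$intercept, x$intercept_se, x$intercept_p))
  cat(sprintf("  slope     %.4g (SE %.3g, p = %.3g)\n",
              x$slope, x$slope_se, x$slope_p))
  invisible(x)
}

#' @export
tidy.egger_result <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "exposure_beta"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se),
    statistic = c(x$intercept / x$intercept_se, x$slope / x$slope_se),
    p.value = c(x$intercept_p, x$slope_p))
}

#' Instrumented/residual BMI decomposition
#'
#' Splits log BMI into the score-determined part (the fitted values of
#' the score-only first stage, `bmi_inst`) and the residual part
#' (`bmi_resid = log_bmi - bmi_inst`, the non-genetically determined BMI
#' variability), refits the second-stage model with both components (and
#' their age interactions), and reports the two main coefficients along
#' with the orthogonal variance split of observed log BMI.
#'
#' @param frame Analysis frame with a `score` column.
#' @param outcome Outcome column.
#' @return List of class `bmi_decomposition`: `coefficients` (tibble for
#'   `bmi_inst` and `bmi_resid` with SEs and p-values), `share_inst`,
#'   `share_resid` (variance shares summing to 1), `fit` (the refitted
#'   `ols_fit`), `first_stage_r2`.
#' @export
decompose_bmi <- function(frame, outcome = "fev1fvc") {
  stopifnot(all(c("score", "log_bmi") %in% names(frame)))
  fs <- fit_ols(frame, "log_bmi", "score")
  x <- as.numeric(frame$log_bmi)
  share_inst <- stats::var(fs$fitted) / stats::var(x)
  if (share_inst >= 0.99) {
    stop("score explains >= 99% of log-BMI variance; residual component ",
         "degenerate", call. = FALSE)
  }
  d <- dplyr::mutate(frame, bmi_inst = fs$fitted, bmi_resid = fs$residuals)
  fit <- fit_ols(d, outcome,
                 c("bmi_inst", "bmi_resid", "bmi_inst:age_c",
                   "bmi_resid:age_c", "age_c", "sex", "height", "packyears",
                   "age_c:sex", "age_c:height"))
  td <- tidy(fit)
  structure(list(
    coefficients = td[td$term %in% c("bmi_inst", "bmi_resid"), ],
    share_inst = share_inst,
    share_resid = 1 - share_inst,
    first_stage_r2 = share_inst,
    fit = fit
  ), class = "bmi_decomposition")
}

#' @export
print.bmi_decomposition <- function(x, ...) {
  cat("<bmi_decomposition> residual share of log-BMI variance:",
      sprintf("%.3f", x$share_resid), "\n")
  print(x$coefficients)
  invisible(x)
}
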