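#' Build an analysis frame from per-survey phenotypes
#'
#' Collapses the three-survey cohort table into one row per individual
#' for one of two survey-averaging schemes:
#'
#' * `"predictive"`: exposure (BMI) averaged over surveys 1-2, outcomes
#'   (lung function) averaged over surveys 2-3, packyears cumulative at
#'   survey 2;
#' * `"long_term"`: exposure and outcomes both averaged over all three
#'   surveys, packyears cumulative at survey 3.
#'
#' Averages use only surveys with participation and non-missing values,
#' and the frame is restricted to complete cases for the respective
#' model: attendance at every exposure survey (so the BMI average and the
#' covariates are fully observed — all three surveys for the long-term
#' frame, surveys 1-2 for the predictive frame), at least one non-missing
#' value of each outcome over the outcome surveys, and non-missing
#' covariates including cumulative packyears at the model's reference
#' survey. `age_c` is the mean
#' age over the exposure surveys centered at 18 years (the minimum
#' baseline age); `log_bmi` is the natural log of the BMI average.
#'
#' @param cohort Long cohort table (see [simulate_cohort()]): columns
#'   `id, sex, survey, participated, age, height, bmi, fev1, fvc,
#'   fev1fvc, fef2575, packyears, asthma`.
#' @param which `"predictive"` or `"long_term"`.
#' @return One-row-per-individual tibble with columns `id`, `sex`,
#'   `bmi_mean`, `log_bmi`, `age_c`, `age_s1`, `height`, `packyears`,
#'   `asthma_ever`, the averaged outcomes `fev1fvc`, `fef2575`, `fev1`,
#'   `fvc`, `fef2575_fvc`, and the per-survey columns `bmi_s1..s3`,
#'   `fev1fvc_s1..s3`, `fef2575_s1..s3` kept for sensitivity analyses.
#'   Attributes: `which`, `n_excluded` (individuals dropped by the
#'   complete-case restriction).
#' @export
#' @examples
#' sim <- simulate_cohort(default_config(n_individuals = 400, seed = 2))
#' frame <- build_frame(sim$cohort, "long_term")
#' nrow(frame)
build_frame <- function(cohort, which = c("predictive", "long_term")) {
  which <- match.arg(which)
  exp_surveys <- if (which == "predictive") 1:2 else 1:3
  out_surveys <- if (which == "predictive") 2:3 else 1:3
  py_survey <- if (which == "predictive") 2L else 3L

  cohort <- tibble::as_tibble(cohort)
  stopifnot(all(c("id", "sex", "survey", "participated", "age", "height",
                  "bmi", "fev1fvc", "fef2575", "packyears") %in% names(cohort)))
  check_cohort_invariants(cohort)

  cohort <- dplyr::mutate(cohort, fef2575_fvc_ps = .data$fef2575 / .data$fvc)
  wide <- tidyr::pivot_wider(
    cohort,
    id_cols = c("id", "sex"),
    names_from = "survey", names_prefix = "s",
    values_from = c("participated", "age", "height", "bmi", "fev1", "fvc",
                    "fev1fvc", "fef2575", "fef2575_fvc_ps", "packyears",
                    "asthma"),
    names_sep = "_"
  )
  pick <- function(stem, surveys) {
    as.matrix(wide[paste0(stem, "_s", surveys)])
  }
  part <- pick("participated", 1:3)
  part[is.na(part)] <- 0
  masked <- function(stem, surveys) {
    m <- pick(stem, surveys)
    m[part[, surveys, drop = FALSE] == 0] <- NA_real_
    m
  }
  row_mean <- function(stem, surveys) {
    out <- rowMeans(masked(stem, surveys), na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    out
  }
  fr <- tibble::tibble(
    id = wide$id,
    sex = wide$sex,
    n_surveys = rowSums(part),
    bmi_mean = row_mean("bmi", exp_surveys),
    age_c = row_mean("age", exp_surveys) - 18,
    age_s1 = wide$age_s1,
    height = row_mean("height", exp_surveys),
    packyears = masked("packyears", 1:3)[, py_survey],
    asthma_ever = as.integer(rowSums(pick("asthma", 1:3) == 1,
                                     na.rm = TRUE) > 0),
    fev1fvc = row_mean("fev1fvc", out_surveys),
    fef2575 = row_mean("fef2575", out_surveys),
    fev1 = row_mean("fev1", out_surveys),
    fvc = row_mean("fvc", out_surveys),
    fef2575_fvc = row_mean("fef2575_fvc_ps", out_surveys),
    bmi_s1 = masked("bmi", 1:3)[, 1],
    bmi_s2 = masked("bmi", 1:3)[, 2],
    bmi_s3 = masked("bmi", 1:3)[, 3],
    fev1fvc_s1 = masked("fev1fvc", 1:3)[, 1],
    fev1fvc_s2 = masked("fev1fvc", 1:3)[, 2],
    fev1fvc_s3 = masked("fev1fvc", 1:3)[, 3],
    fef2575_s1 = masked("fef2575", 1:3)[, 1],
    fef2575_s2 = masked("fef2575", 1:3)[, 2],
    fef2575_s3 = masked("fef2575", 1:3)[, 3],
    packyears_s1 = masked("packyears", 1:3)[, 1]
  ) |>
    dplyr::mutate(log_bmi = log(.data$bmi_mean), .after = "bmi_mean")

  n_all <- nrow(fr)
  attended_exposure <- rowSums(part[, exp_surveys, drop = FALSE]) ==
    length(exp_surveys)
  fr <- fr[attended_exposure, ]
  fr <- dplyr::filter(
    fr,
    is.finite(.data$log_bmi),
    !is.na(.data$fev1fvc), !is.na(.data$fef2575),
    !is.na(.data$age_c), !is.na(.data$height), !is.na(.data$packyears)
  ) |>
    dplyr::select(-"n_surveys")
  n_excluded <- n_all - nrow(fr)
  if (n_excluded > 0) {
    rlang::inform(sprintf(
      "build_frame(%s): %d of %d individuals excluded (incomplete surveys or missing model variables)",
      which, n_excluded, n_all), class = "mrlung_exclusions")
  }
  attr(fr, "which") <- which
  attr(fr, "n_excluded") <- n_excluded
  fr
}

check_cohort_invariants <- function(cohort) {
  r <- cohort$fev1fvc
  if (any(r <= 0 | r > 1, na.rm = TRUE)) {
    stop("FEV1/FVC outside (0, 1]", call. = FALSE)
  }
  if (any(cohort$bmi <= 10, na.rm = TRUE)) stop("BMI <= 10", call. = FALSE)
  srt <- cohort[order(cohort$id, cohort$survey), c("id", "age")]
  same <- srt$id[-1] == srt$id[-nrow(srt)]
  step <- srt$age[-1] - srt$age[-nrow(srt)]
  if (any(same & !is.na(step) & step < 0)) {
    stop("ages not non-decreasing across surveys for some individuals",
         call. = FALSE)
  }
  invisible(cohort)
}

#' Attach an allele score to an analysis frame
#'
#' @param frame Output of [build_frame()].
#' @param score Output of [compute_score()] (or a tibble `id`, `score`).
#' @return The frame with a `score` column, individuals without a score
#'   dropped.
#' @export
add_score <- function(frame, score) {
  out <- dplyr::inner_join(frame,
                           dplyr::select(score, "id", "score"), by = "id")
  attributes(out)[c("which", "n_excluded")] <-
    attributes(frame)[c("which", "n_excluded")]
  out
}

#' Partial correlations between lung-function variables
#'
#' Each variable instance (a lung-function variable at one survey, or its
#' derived mean over several surveys) is residualized by least squares on
#' age, age squared, height, height squared, sex and all their pairwise
#' interactions (using the concurrent, respectively averaged, age and
#' height), and the residuals are Pearson-correlated on pairwise-complete
#' rows.
#'
#' @param cohort Long cohort table.
#' @param vars Lung-function variables to include.
#' @param surveys Which surveys to include as single-survey instances.
#' @param means Named list of survey sets to include as derived means,
#'   e.g. `list(s1s2s3 = 1:3)`; `NULL` for none.
#' @param min_pairs Pairs with fewer pairwise-complete observations are
#'   set to `NA` and flagged with a warning.
#' @return A symmetric correlation matrix with unit diagonal; rownames
#'   are `<var>_s<k>` / `<var>_<mean label>`.
#' @export
partial_correlations <- function(cohort,
                                 vars = c("fev1fvc", "fef2575", "fev1", "fvc"),
                                 surveys = 1:3,
                                 means = list(s1s2s3 = 1:3),
                                 min_pairs = 30) {
  cohort <- dplyr::filter(tibble::as_tibble(cohort), .data$participated == 1)
  inst <- list()
  for (v in vars) {
    for (s in surveys) {
      rows <- cohort[cohort$survey == s, ]
      inst[[paste0(v, "_s", s)]] <-
        tibble::tibble(id = rows$id, y = rows[[v]],
                       age = rows$age, height = rows$height, sex = rows$sex)
    }
    for (lab in names(means)) {
      rows <- cohort[cohort$survey %in% means[[lab]], ] |>
        dplyr::group_by(.data$id) |>
        dplyr::summarise(y = mean(.data[[v]], na.rm = TRUE),
                         age = mean(.data$age, na.rm = TRUE),
                         height = mean(.data$height, na.rm = TRUE),
                         sex = .data$sex[1], .groups = "drop")
      inst[[paste0(v, "_", lab)]] <-
        tibble::tibble(id = rows$id, y = rows$y, age = rows$age,
                       height = rows$height, sex = rows$sex)
    }
  }
  ids <- sort(unique(cohort$id))
  resid_mat <- vapply(names(inst), function(nm) {
    d <- inst[[nm]]
    out <- rep(NA_real_, length(ids))
    cc <- stats::complete.cases(d)
    d <- d[cc, ]
    if (!nrow(d)) return(out)
    X <- residualization_design(d)
    # column scaling for numerical conditioning (residuals are invariant)
    X <- sweep(X, 2, pmax(apply(abs(X), 2, max), 1e-12), "/")
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      stop("singular residualization design for ", nm, "; collinear term(s): ",
           paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
                 collapse = ", "), call. = FALSE)
    }
    out[match(d$id, ids)] <- qr.resid(qrX, d$y)
    out
  }, numeric(length(ids)))

  n_pair <- crossprod(!is.na(resid_mat))
  cm <- suppressWarnings(
    stats::cor(resid_mat, use = "pairwise.complete.obs"))
  if (any(n_pair < min_pairs & n_pair > 0)) {
    warning("some pairs have fewer than ", min_pairs,
            " pairwise-complete observations; their correlations are set to NA",
            call. = FALSE)
    cm[n_pair < min_pairs] <- NA_real_
  }
  diag(cm) <- 1
  cm
}

residualization_design <- function(d) {
  base <- cbind(age = d$age, age2 = d$age^2, height = d$height,
                height2 = d$height^2, sex = d$sex)
  k <- ncol(base)
  inter <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      inter[[paste0(colnames(base)[i], ":", colnames(base)[j])]] <-
        base[, i] * base[, j]
    }
  }
  X <- cbind(`(Intercept)` = 1, base, do.call(cbind, inter))
  colnames(X) <- c("(Intercept)", colnames(base), names(inter))
  X
}

#' Lung-function summaries by obesity stratum
#'
#' Per survey and obesity stratum (BMI below vs at/above `bmi_cut`):
#' sample size, mean, SD and quartiles of each lung-function variable.
#'
#' @param cohort Long cohort table.
#' @param vars Lung-function variables to summarise.
#' @param bmi_cut Obesity threshold in kg/m2 (default 30).
#' @return Tibble with columns `survey`, `stratum`, `variable`, `n`,
#'   `mean`, `sd`, `q25`, `median`, `q75`. Empty strata produce `NaN`
#'   summaries with a warning.
#' @export
obesity_strata_summary <- function(cohort, vars = c("fev1fvc", "fef2575"),
                                   bmi_cut = 30) {
  obs <- dplyr::filter(tibble::as_tibble(cohort),
                       .data$participated == 1, !is.na(.data$bmi))
  grid <- tidyr::expand_grid(survey = sort(unique(obs$survey)),
                             stratum = c("non_obese", "obese"),
                             variable = vars)
  out <- purrr::pmap_dfr(grid, function(survey, stratum, variable) {
    rows <- obs[obs$survey == survey &
                  ((obs$bmi >= bmi_cut) == (stratum == "obese")), ]
    x <- rows[[variable]]
    x <- x[!is.na(x)]
    q <- if (length(x)) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
         else rep(NaN, 3)
    tibble::tibble(survey = survey, stratum = stratum, variable = variable,
                   n = length(x),
                   mean = if (length(x)) mean(x) else NaN,
                   sd = if (length(x) > 1) stats::sd(x) else NaN,
                   q25 = q[1], median = q[2], q75 = q[3])
  })
  if (any(out$n == 0)) {
    warning("empty obesity stratum for some survey/variable combinations",
            call. = FALSE)
  }
  out
}
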