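#' Simulate a three-survey cohort with genotypes and known causal truth
#'
#' Draws independent biallelic genotypes in Hardy-Weinberg proportions,
#' builds per-survey log BMI from the weighted allele burden, covariates,
#' a latent confounder and noise, generates FEV1/FVC and FEF25-75 from the
#' configured causal model (the exposure coefficient at age `a` is
#' `beta_c1 + beta_c2 * (a - 18)`), and draws participation at surveys 2
#' and 3 from the attrition logistic model. Identical configs (including
#' the seed stored in the config) give bit-identical output; the global
#' RNG state is left untouched.
#'
#' Phenotype measurements are `NA` at surveys the individual did not
#' attend; `age`, `sex` and `asthma` are always known. Survey spacing is
#' fixed at 10 years.
#'
#' @param config A [default_config()] object (or a list with the same
#'   fields).
#' @return A list of class `mrlung_sim` with elements
#'   * `genotypes`: tibble, one row per individual, `id` plus one dosage
#'     column per SNP (0/1/2),
#'   * `cohort`: long tibble, one row per individual-survey, with columns
#'     `id, sex, survey, participated, age, height, weight, bmi, fev1,
#'     fvc, fev1fvc, fef2575, packyears, asthma`,
#'   * `truth`: list of class `sim_truth` holding the realized config, the
#'     per-individual latent confounder, the true allele score and genetic
#'     log-BMI component, and the noise-free expected per-survey log BMI
#'     and FEV1/FVC.
#' @export
#' @examples
#' sim <- simulate_cohort(default_config(n_individuals = 300, seed = 7))
#' head(sim$cohort)
simulate_cohort <- function(config) {
  cfg <- validate_config(unclass(config))
  withr::with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_individuals
  m <- cfg$n_snps
  ids <- sprintf("id%05d", seq_len(n))
  snp_ids <- sprintf("rs%06d", 100000L + seq_len(m))

  G <- matrix(
    stats::rbinom(n * m, 2L, rep(cfg$allele_freqs, each = n)),
    nrow = n, ncol = m, dimnames = list(NULL, snp_ids)
  )
  score <- drop(G %*% cfg$snp_weights)
  score_c <- score - sum(cfg$snp_weights * 2 * cfg$allele_freqs)

  sex <- stats::rbinom(n, 1L, 0.5)              # 0 = male, 1 = female
  height <- ifelse(sex == 0,
                   stats::rnorm(n, 176, 7),
                   stats::rnorm(n, 164, 6.5))
  age_s1 <- stats::runif(n, 18, 60)
  ages <- outer(age_s1, c(0, 10, 20), `+`)      # n x 3
  age_c <- ages - 18

  smoker <- stats::rbinom(n, 1L, 0.45)
  py1 <- smoker * stats::rgamma(n, shape = 1.2, scale = 10)
  py2 <- py1 + smoker * stats::rgamma(n, shape = 1, scale = 5)
  py3 <- py2 + smoker * stats::rgamma(n, shape = 1, scale = 4)
  packyears <- cbind(py1, py2, py3)
  if (cfg$score_to_packyears != 0) {
    # injected instrument-validity violation: the allele burden shifts
    # smoking exposure directly
    packyears <- pmax(packyears + cfg$score_to_packyears * score_c, 0)
  }

  U <- stats::rnorm(n, 0, cfg$confounder_sd)
  person <- stats::rnorm(n, 0, cfg$person_sd)

  mu_logbmi <- cfg$log_bmi0 + score_c + cfg$conf_to_bmi * U +
    cfg$bmi_sex * sex + person
  exp_logbmi <- mu_logbmi + cfg$bmi_age * age_c      # n x 3, noise-free
  log_bmi <- exp_logbmi +
    matrix(stats::rnorm(n * 3, 0, cfg$survey_noise_sd), n, 3)
  if (cfg$s1_report_sd > 0) {
    # self-reported weight at baseline: extra measurement error at s1 only
    log_bmi[, 1] <- log_bmi[, 1] + stats::rnorm(n, 0, cfg$s1_report_sd)
  }
  bmi <- exp(log_bmi)

  # which part of log BMI carries the causal effect
  xc <- switch(cfg$causal_part,
    total   = log_bmi - log(25),
    genetic = matrix(score_c, n, 3)
  )
  slope_lf <- cfg$beta_c1 + cfg$beta_c2 * age_c
  pleio <- drop((G - matrix(2 * cfg$allele_freqs, n, m, byrow = TRUE)) %*%
                  cfg$pleiotropy)
  exp_fev1fvc <- cfg$lf0 + slope_lf * xc +
    cfg$lf_age * (age_c - 30) + cfg$lf_sex * sex +
    cfg$lf_height * (height - 170) + cfg$lf_packyears * packyears +
    cfg$conf_to_lf * U + pleio
  fev1fvc <- exp_fev1fvc + matrix(stats::rnorm(n * 3, 0, cfg$lf_noise_sd), n, 3)
  fev1fvc <- pmin(pmax(fev1fvc, 0.2), 0.999)

  slope_fef <- cfg$fef_c1 + cfg$fef_c2 * age_c
  fef2575 <- cfg$fef0 + slope_fef * xc +
    cfg$fef_age * (age_c - 30) + cfg$fef_sex * sex +
    cfg$fef_height * (height - 170) + cfg$fef_packyears * packyears +
    cfg$conf_to_fef * U +
    matrix(stats::rnorm(n * 3, 0, cfg$fef_noise_sd), n, 3)
  fef2575 <- pmax(fef2575, 0.1)

  fvc <- 3.2 + 0.045 * (height - 170) - 0.022 * age_c +
    0.75 * (sex == 0) + matrix(stats::rnorm(n * 3, 0, 0.45), n, 3)
  fvc <- pmax(fvc, 0.8)
  fev1 <- fev1fvc * fvc

  asthma <- stats::rbinom(n, 1L, 0.13)

  part <- matrix(1L, n, 3)
  if (!is.null(cfg$attrition)) {
    eta <- function(co) {
      co[["intercept"]] + co[["bmi"]] * (bmi[, 1] - 25) +
        co[["lf"]] * (fev1fvc[, 1] - 0.76) + co[["packyears"]] * py1
    }
    part[, 2] <- stats::rbinom(n, 1L, stats::plogis(eta(cfg$attrition$s2)))
    part[, 3] <- part[, 2] *
      stats::rbinom(n, 1L, stats::plogis(eta(cfg$attrition$s3)))
  }

  mask <- function(x) {
    x[part == 0L] <- NA_real_
    x
  }
  height3 <- mask(matrix(height, n, 3))
  bmi_m <- mask(bmi)
  cohort <- tibble::tibble(
    id = rep(ids, times = 3),
    sex = rep(sex, times = 3),
    survey = rep(1:3, each = n),
    participated = as.integer(part),
    age = as.vector(ages),
    height = as.vector(height3),
    weight = as.vector(bmi_m * (height3 / 100)^2),
    bmi = as.vector(bmi_m),
    fev1 = as.vector(mask(fev1)),
    fvc = as.vector(mask(fvc)),
    fev1fvc = as.vector(mask(fev1fvc)),
    fef2575 = as.vector(mask(fef2575)),
    packyears = as.vector(mask(packyears)),
    asthma = rep(asthma, times = 3)
  )

  genotypes <- tibble::as_tibble(as.data.frame(G)) |>
    dplyr::mutate(id = ids, .before = 1)

  truth <- structure(list(
    config = structure(cfg, class = "sim_config"),
    id = ids,
    confounder = U,
    score = score,
    genetic_logbmi = score_c,
    expected_log_bmi = exp_logbmi,
    expected_fev1fvc = exp_fev1fvc,
    snp_ids = snp_ids
  ), class = "sim_truth")

  structure(list(genotypes = genotypes, cohort = cohort, truth = truth),
            class = "mrlung_sim")
}

#' @export
print.mrlung_sim <- function(x, ...) {
  cat("<mrlung_sim> ", nrow(x$genotypes), "individuals,",
      ncol(x$genotypes) - 1L, "SNPs, 3 surveys\n")
  part <- tapply(x$cohort$participated, x$cohort$survey, mean)
  cat("  participation: ", paste(sprintf("s%d %.0f%%", 1:3, 100 * part),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> beta_c1 =", x$config$beta_c1,
      ", beta_c2 =", x$config$beta_c2,
      "(", x$config$causal_part, "log-BMI )\n")
  invisible(x)
}

#' True weight table of a simulated cohort
#'
#' Returns the generating per-SNP weights of a simulation as a weight
#' table suitable for [compute_score()], oriented to the BMI-increasing
#' allele (all generating weights are positive).
#'
#' @param truth A `sim_truth` object (or an `mrlung_sim`).
#' @param score_name Label recorded in the table.
#' @return A tibble with columns `snp_id`, `effect_allele`, `weight`.
#' @export
sim_weight_table <- function(truth, score_name = "simulated") {
  if (inherits(truth, "mrlung_sim")) truth <- truth$truth
  tibble::tibble(
    snp_id = truth$snp_ids,
    effect_allele = "A",
    weight = truth$config$snp_weights,
    score_name = score_name
  )
}

#' Write / read simulated tables
#'
#' `write_genotypes()` writes the dosage matrix as TSV (one row per
#' individual, one column per SNP). `write_cohort()` writes the long
#' cohort table as CSV. The readers invert them.
#'
#' @param x Tibble produced by [simulate_cohort()].
#' @param path File path.
#' @return The input (writers, invisibly) or a tibble (readers).
#' @name sim_io
NULL

#' @rdname sim_io
#' @export
write_genotypes <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname sim_io
#' @export
read_genotypes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(id = "c", .default = "d"))
}

#' @rdname sim_io
#' @export
write_cohort <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname sim_io
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(id = "c", .default = "d"))
}
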