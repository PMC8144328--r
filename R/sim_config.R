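#' Configuration of the synthetic cohort generator
#'
#' `default_config()` returns the generating parameters of a synthetic
#' three-survey cohort whose marginal distributions approximate a Swiss
#' adult population cohort (baseline ages 18-60, BMI around 25 kg/m2 with
#' SD around 3.7, mean FEV1/FVC around 0.76) and whose causal structure is
#' exactly the structure the two-stage least squares analysis assumes:
#'
#' * per-SNP genotypes in Hardy-Weinberg proportions,
#' * a weighted allele score entering log BMI additively (explaining
#'   roughly 2-3\% of log-BMI variance, i.e. a first-stage F in the
#'   50-400 range at n of a few thousand),
#' * a latent Normal confounder `U` loading on both log BMI and lung
#'   function, so that OLS is biased and 2SLS is consistent by construction,
#' * an age-attenuated causal effect of log BMI on FEV1/FVC with true
#'   coefficients `beta_c1` (at age 18) and `beta_c2` (per year), and an
#'   analogous pair for FEF25-75,
#' * optional direct (pleiotropic) SNP-to-outcome paths, and
#' * logistic participation (attrition) at surveys 2 and 3 depending on
#'   baseline BMI, lung function and packyears.
#'
#' Any field can be overridden by name, e.g.
#' `default_config(conf_to_lf = 0, attrition = NULL)`.
#'
#' @param n_individuals Number of individuals at baseline.
#' @param n_snps Number of independent biallelic SNPs.
#' @param seed Integer seed; `simulate_cohort()` is bit-reproducible given
#'   the full config (which includes the seed).
#' @param ... Named overrides of any other configuration field (see
#'   Details for the field list); unknown names are an error.
#'
#' @details Further fields: `allele_freqs` (per-SNP effect-allele
#'   frequency), `snp_weights` (per-allele effect on log BMI, log-spaced
#'   magnitudes), `beta_c1`/`beta_c2` (causal FEV1/FVC effects, the
#'   published long-term point estimates by default), `fef_c1`/`fef_c2`
#'   (same for FEF25-75), `causal_part` (`"total"`: all of log BMI carries
#'   the causal effect; `"genetic"`: only its score-determined component
#'   does), `confounder_sd`, `conf_to_bmi`, `conf_to_lf`, `conf_to_fef`,
#'   `pleiotropy` (scalar or per-SNP direct effects on FEV1/FVC),
#'   `score_to_packyears` (an instrument-validity violation used in
#'   assumption-check power experiments), covariate effects
#'   (`bmi_age`, `bmi_sex`, `lf_age`, `lf_sex`, `lf_height`, `lf_packyears`,
#'   `fef_age`, `fef_sex`, `fef_height`, `fef_packyears`), noise scales
#'   (`person_sd`, `survey_noise_sd`, `lf_noise_sd`, `fef_noise_sd`), the
#'   intercepts `log_bmi0`, `lf0`, `fef0`, and `attrition` (a list with
#'   logistic coefficient vectors `s2` and `s3`, or `NULL` for full
#'   participation).
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' cfg <- default_config(n_individuals = 500, seed = 1)
#' sim <- simulate_cohort(cfg)
#' dplyr::count(sim$cohort, survey, participated)
default_config <- function(n_individuals = 3000, n_snps = 32, seed = 1L, ...) {
  freqs <- seq(0.12, 0.88, length.out = n_snps)
  # log-spaced per-allele weights; the resulting score explains ~2.5% of
  # log-BMI variance at the default noise scales (first-stage F ~ 60-120
  # at n ~ 2700)
  weights <- exp(seq(log(0.002), log(0.0128), length.out = n_snps))
  cfg <- list(
    n_individuals = n_individuals,
    n_snps = n_snps,
    allele_freqs = freqs,
    snp_weights = weights,
    # causal lung-function effects (FEV1/FVC units per log-BMI unit; the
    # interaction is per year of age beyond 18)
    beta_c1 = -0.752,
    beta_c2 = 0.021,
    fef_c1 = -9.251,
    fef_c2 = 0.242,
    causal_part = "total",
    # shared latent confounder
    confounder_sd = 1,
    conf_to_bmi = 0.06,
    conf_to_lf = 0.025,
    conf_to_fef = 0.95,
    # instrument-validity violations (off by default)
    pleiotropy = 0,
    score_to_packyears = 0,
    # covariate effects on log BMI (score and age enter centered, so the
    # intercept is close to the population mean of log BMI)
    log_bmi0 = log(24.0),
    bmi_age = 0.0015,
    bmi_sex = -0.02,
    s1_report_sd = 0,
    # covariate effects on FEV1/FVC
    lf0 = 0.74,
    lf_age = -0.0005,
    lf_sex = 0.005,
    lf_height = 0.0002,
    lf_packyears = -4e-04,
    # covariate effects on FEF25-75 (L/s)
    fef0 = 3.4,
    fef_age = -0.02,
    fef_sex = -0.1,
    fef_height = 0.01,
    fef_packyears = -0.012,
    # noise scales
    person_sd = 0.105,
    survey_noise_sd = 0.04,
    lf_noise_sd = 0.045,
    fef_noise_sd = 0.5,
    # logistic participation models at surveys 2 and 3 (s3 conditional on
    # s2 participation); covariate order: intercept, baseline BMI
    # (centered at 25), baseline FEV1/FVC (centered at 0.76), baseline
    # packyears. Calibrated to ~83% participation at s2 and ~64% overall
    # at s3 with strong dependence on lung function and BMI.
    attrition = list(
      s2 = c(intercept = 1.9, bmi = -0.05, lf = 8, packyears = -0.012),
      s3 = c(intercept = 1.5, bmi = -0.05, lf = 8, packyears = -0.012)
    ),
    seed = as.integer(seed)
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  cfg <- validate_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_config <- function(cfg) {
  if (cfg$n_snps < 1) stop("n_snps must be >= 1", call. = FALSE)
  if (cfg$n_individuals < 1) stop("n_individuals must be >= 1", call. = FALSE)
  cfg$allele_freqs <- rep_len(cfg$allele_freqs, cfg$n_snps)
  cfg$snp_weights <- rep_len(cfg$snp_weights, cfg$n_snps)
  cfg$pleiotropy <- rep_len(cfg$pleiotropy, cfg$n_snps)
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))], use.names = FALSE)
  if (any(!is.finite(num))) stop("config contains non-finite values", call. = FALSE)
  if (any(cfg$allele_freqs <= 0 | cfg$allele_freqs >= 1)) {
    stop("allele_freqs must lie strictly inside (0, 1)", call. = FALSE)
  }
  bad_sd <- c("survey_noise_sd", "person_sd", "lf_noise_sd", "fef_noise_sd",
              "confounder_sd")
  if (any(unlist(cfg[bad_sd]) < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  cfg$causal_part <- match.arg(cfg$causal_part, c("total", "genetic"))
  if (!is.null(cfg$attrition)) {
    stopifnot(is.list(cfg$attrition), all(c("s2", "s3") %in% names(cfg$attrition)))
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  individuals:", x$n_individuals, " SNPs:", x$n_snps,
      " seed:", x$seed, "\n")
  cat("  causal FEV1/FVC effects: beta_c1 =", x$beta_c1,
      ", beta_c2 =", x$beta_c2, "(", x$causal_part, "log-BMI )\n")
  cat("  confounding: conf_to_bmi =", x$conf_to_bmi,
      ", conf_to_lf =", x$conf_to_lf, "\n")
  cat("  score variance on log BMI:",
      signif(sum(x$snp_weights^2 * 2 * x$allele_freqs * (1 - x$allele_freqs)), 3),
      "\n")
  cat("  attrition:", if (is.null(x$attrition)) "none" else "logistic on baseline BMI/LF/packyears", "\n")
  invisible(x)
}
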