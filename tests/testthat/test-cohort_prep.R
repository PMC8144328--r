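test_that("frame averaging does the survey arithmetic", {
  co <- toy_cohort()
  lt <- build_frame(co, "long_term")
  a <- lt[lt$id == "a", ]
  expect_equal(a$bmi_mean, mean(c(24, 26, 28)))
  expect_equal(a$log_bmi, log(26))
  expect_equal(a$age_c, mean(c(28, 38, 48)) - 18)   # = 20
  expect_equal(a$packyears, 0)
  expect_equal(a$fev1fvc, mean(c(3.5 / 4.5, 3.4 / 4.4, 3.3 / 4.3)))

  pr <- build_frame(co, "predictive")
  b <- pr[pr$id == "b", ]
  expect_equal(b$bmi_mean, mean(c(22, 23)))
  expect_equal(b$age_c, mean(c(40, 50)) - 18)
  expect_equal(b$packyears, 10)                      # cumulative at s2
  expect_equal(b$fev1fvc, mean(c(2.7 / 3.5, 2.6 / 3.4)))
  lt_b <- lt[lt$id == "b", ]
  expect_equal(lt_b$packyears, 12)                   # cumulative at s3
})

test_that("a cohort without missingness keeps every individual", {
  sim <- quick_sim(n = 500, seed = 14, attrition = NULL)
  expect_silent(fr <- build_frame(sim$cohort, "long_term"))
  expect_equal(nrow(fr), 500)
  expect_true(all(fr$age_c >= 0))
  expect_true(all(is.finite(fr$log_bmi)))
})

test_that("attrition shrinks the long-term frame below the predictive frame", {
  sim <- quick_sim(n = 3000, seed = 15)   # default LF/BMI-dependent attrition
  pr <- suppressMessages(build_frame(sim$cohort, "predictive"))
  lt <- suppressMessages(build_frame(sim$cohort, "long_term"))
  expect_lt(nrow(lt), nrow(pr))
  expect_lt(nrow(pr), 3000)
  expect_equal(attr(lt, "n_excluded"), 3000 - nrow(lt))
})

test_that("cohort invariant violations are caught", {
  co <- toy_cohort()
  co$fev1fvc[1] <- 1.4
  expect_error(build_frame(co, "long_term"), "FEV1/FVC")
  co <- toy_cohort()
  co$age[2] <- 20   # age decreases within individual
  expect_error(build_frame(co, "long_term"), "non-decreasing")
  co <- toy_cohort()
  co$bmi[4] <- 9
  expect_error(build_frame(co, "long_term"), "BMI")
})

test_that("partial correlations match a brute-force residualization oracle", {
  set.seed(6)
  n <- 40
  co <- tibble::tibble(
    id = sprintf("i%02d", 1:n), sex = rep(0:1, n / 2), survey = 1L,
    participated = 1L,
    age = runif(n, -2, 2), height = runif(n, -2, 2),
    weight = NA_real_, bmi = runif(n, 20, 30),
    fev1 = rnorm(n, 3), fvc = rnorm(n, 4),
    fev1fvc = runif(n, 0.6, 0.9), fef2575 = rnorm(n, 3),
    packyears = 0, asthma = 0L
  )
  pc <- partial_correlations(co, vars = c("fev1fvc", "fef2575"),
                             surveys = 1, means = NULL)
  X <- cbind(1, co$age, co$age^2, co$height, co$height^2, co$sex,
             co$age * co$age^2, co$age * co$height, co$age * co$height^2,
             co$age * co$sex, co$age^2 * co$height, co$age^2 * co$height^2,
             co$age^2 * co$sex, co$height * co$height^2, co$height * co$sex,
             co$height^2 * co$sex)
  r_oracle <- oracle_partial_cor(co$fev1fvc, co$fef2575, X, X)
  expect_equal(unname(pc["fev1fvc_s1", "fef2575_s1"]), r_oracle,
               tolerance = 1e-10)
  expect_equal(unname(diag(pc)), rep(1, 2))
  expect_equal(pc, t(pc))
})

test_that("residualization removes covariate-driven signal", {
  set.seed(11)
  n <- 5000
  age <- runif(n, 20, 60)
  height <- rnorm(n, 170, 9)
  noise <- rnorm(n)
  co <- tibble::tibble(
    id = sprintf("i%05d", 1:n), sex = rbinom(n, 1, 0.5), survey = 1L,
    participated = 1L, age = age, height = height, weight = NA_real_,
    bmi = 25,
    fev1 = rnorm(n, 3), fvc = rnorm(n, 4),
    fev1fvc = pmin(0.95, pmax(0.4, 0.9 - 0.003 * age + 0.0005 * height)),
    fef2575 = noise + 5,        # pure noise, independent of everything
    packyears = 0, asthma = 0L
  )
  pc <- partial_correlations(co, vars = c("fev1fvc", "fef2575"),
                             surveys = 1, means = NULL)
  expect_lt(abs(pc["fev1fvc_s1", "fef2575_s1"]), 0.05)
})

test_that("partial-correlation matrix is PSD on complete data", {
  sim <- quick_sim(n = 800, seed = 16, attrition = NULL)
  pc <- partial_correlations(sim$cohort)
  ev <- eigen(pc, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("a singular residualization design names the collinear term", {
  co <- toy_cohort()
  co$sex <- 0   # constant sex: sex column and its interactions collinear
  expect_error(partial_correlations(co, vars = "fev1fvc", surveys = 1,
                                    means = NULL, min_pairs = 1),
               "collinear")
})

test_that("obesity strata summaries flag empty strata and split correctly", {
  co <- toy_cohort()                     # all BMI < 30
  expect_warning(out <- obesity_strata_summary(co), "empty")
  expect_true(all(out$n[out$stratum == "obese"] == 0))
  expect_true(all(is.nan(out$mean[out$stratum == "obese"])))
  # duplicated strata built by construction give identical summaries
  co2 <- co
  co2$bmi <- co2$bmi + 10                # everybody obese, same LF values
  both <- dplyr::bind_rows(co, co2)
  s <- suppressWarnings(obesity_strata_summary(both, vars = "fev1fvc"))
  ob <- s[s$stratum == "obese", c("n", "mean", "sd", "q25", "median", "q75")]
  no <- s[s$stratum == "non_obese", c("n", "mean", "sd", "q25", "median", "q75")]
  expect_equal(ob, no)
})

test_that("obese individuals have lower mid-expiratory flow at baseline", {
  sim <- quick_sim(n = 6000, seed = 17)
  s <- obesity_strata_summary(sim$cohort, vars = "fef2575")
  s1 <- s[s$survey == 1, ]
  expect_lt(s1$mean[s1$stratum == "obese"],
            s1$mean[s1$stratum == "non_obese"])
})
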