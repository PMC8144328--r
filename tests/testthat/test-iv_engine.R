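test_that("fit_ols reproduces exact linear relationships", {
  d <- tibble::tibble(x = 1:10, y = 2 + 3 * (1:10))
  ft <- fit_ols(d, "y", "x")
  expect_equal(unname(coef(ft)), c(2, 3), tolerance = 1e-10)
})

test_that("fit_ols matches the explicit normal-equations oracle", {
  d <- tibble::tibble(x = c(1, 2, 4, 5, 7), z = c(0, 1, 0, 1, 1),
                      y = c(2.2, 3.1, 5.4, 5.9, 8.3))
  ft <- fit_ols(d, "y", c("x", "z"))
  X <- cbind(1, d$x, d$z)
  expect_equal(unname(coef(ft)), unname(oracle_ols(X, d$y)),
               tolerance = 1e-10)
  # classical covariance sigma^2 (X'X)^{-1}
  r <- d$y - X %*% oracle_ols(X, d$y)
  s2 <- sum(r^2) / (5 - 3)
  expect_equal(unname(vcov(ft)), unname(s2 * solve(t(X) %*% X)),
               tolerance = 1e-10)
})

test_that("duplicating every row keeps estimates and shrinks SEs by sqrt(2)", {
  set.seed(2)
  d <- tibble::tibble(x = rnorm(30), z = rnorm(30),
                      y = 1 + 2 * rnorm(30))
  d2 <- dplyr::bind_rows(d, d)
  f1 <- fit_ols(d, "y", c("x", "z"))
  f2 <- fit_ols(d2, "y", c("x", "z"))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  # n doubles, rss doubles: sigma2 ratio (2n-k)/(2(n-k)), vcov halves up
  # to that df correction
  ratio <- sqrt(diag(vcov(f1)) / diag(vcov(f2)))
  df_corr <- sqrt((60 - 3) / (2 * (30 - 3)))
  expect_equal(unname(ratio), rep(sqrt(2) * df_corr, 3), tolerance = 1e-10)
})

test_that("rank-deficient designs name the aliased columns", {
  d <- tibble::tibble(x = 1:6, x2 = 2 * (1:6), y = rnorm(6))
  expect_error(fit_ols(d, "y", c("x", "x2")), "aliased.*x2")
})

test_that("2SLS with a perfect instrument degenerates to OLS", {
  set.seed(3)
  d <- tibble::tibble(x = rnorm(50), w = rnorm(50))
  d$y <- 1 - 0.5 * d$x + 0.2 * d$w + rnorm(50, 0, 0.3)
  d$z <- d$x
  iv <- fit_2sls(d, "y", causal = "x", instruments = "z", exogenous = "w")
  ols <- fit_ols(d, "y", c("w", "x"))
  expect_equal(coef(iv)[names(coef(ols))], coef(ols), tolerance = 1e-10)
})

test_that("just-identified 2SLS equals the ratio-of-covariances IV oracle", {
  # 8-row hand dataset, one endogenous term, one instrument, intercept only
  d <- tibble::tibble(
    z = c(0, 1, 2, 0, 1, 2, 1, 0),
    x = c(0.1, 0.9, 2.2, -0.3, 1.3, 1.8, 1.1, 0.2),
    y = c(0.5, 1.7, 4.1, 0.2, 2.9, 3.6, 2.4, 0.6))
  iv <- suppressWarnings(
    fit_2sls(d, "y", causal = "x", instruments = "z",
             exogenous = character(0)))
  expect_equal(coef(iv)[["x"]], oracle_iv_ratio(d$z, d$x, d$y),
               tolerance = 1e-8)
})

test_that("the projection solution equals the explicit two-regression construction", {
  sim <- quick_sim(n = 600, seed = 33, attrition = NULL)
  fr <- quick_frame(sim)
  fr <- add_interaction_instrument(fr, "score", "age_c")
  iv <- suppressWarnings(
    fit_2sls(fr, "fev1fvc",
             causal = c("log_bmi", "log_bmi:age_c"),
             instruments = c("score", "score:age_c"),
             exogenous = c("age_c", "sex", "height", "packyears")))
  # manual stage 1 with lm, manual stage 2 on fitted values
  fr$lbxa <- fr$log_bmi * fr$age_c
  s1a <- lm(log_bmi ~ score + `score:age_c` + age_c + sex + height +
              packyears, data = fr)
  s1b <- lm(lbxa ~ score + `score:age_c` + age_c + sex + height + packyears,
            data = fr)
  fr$f1 <- fitted(s1a)
  fr$f2 <- fitted(s1b)
  s2 <- lm(fev1fvc ~ age_c + sex + height + packyears + f1 + f2, data = fr)
  expect_equal(unname(coef(iv)[c("log_bmi", "log_bmi:age_c")]),
               unname(coef(s2)[c("f1", "f2")]), tolerance = 1e-8)
})

test_that("degenerate instruments fail loudly", {
  sim <- quick_sim(n = 200, seed = 34, attrition = NULL)
  fr <- quick_frame(sim)
  fr$age_c <- 0   # interaction instrument identically zero
  expect_error(
    fit_2sls(fr, "fev1fvc", causal = c("log_bmi", "log_bmi:age_c"),
             instruments = c("score", "score:age_c"),
             exogenous = c("sex", "height", "packyears")),
    "constant instrument")
  fr2 <- quick_frame(sim)
  fr2$score <- 1
  expect_error(
    fit_2sls(fr2, "fev1fvc", causal = "log_bmi", instruments = "score",
             exogenous = c("age_c", "sex", "height", "packyears")),
    "constant instrument")
  # fewer instruments than causal terms
  expect_error(
    fit_2sls(quick_frame(sim), "fev1fvc",
             causal = c("log_bmi", "log_bmi:age_c"),
             instruments = "score",
             exogenous = c("age_c", "sex")),
    "at least as many instruments")
})

test_that("interaction instruments are element-wise products", {
  fr <- tibble::tibble(score = c(1, 2, 3, 0.5, 1.5, 2.5),
                       age_c = c(0, 10, 20, 5, 15, 25))
  out <- add_interaction_instrument(fr, "score", "age_c")
  expect_equal(out[["score:age_c"]], fr$score * fr$age_c)
})

test_that("weak instruments warn but do not error", {
  sim <- quick_sim(n = 400, seed = 35, attrition = NULL,
                   snp_weights = rep(1e-4, 32))
  fr <- quick_frame(sim)
  expect_warning(
    fit_2sls(fr, "fev1fvc", causal = "log_bmi", instruments = "score",
             exogenous = c("age_c", "sex", "height", "packyears")),
    "weak instrument")
})

test_that("first_stage_f matches the explicit RSS oracle", {
  set.seed(4)
  d <- tibble::tibble(z = rnorm(40), w = rnorm(40))
  d$x <- 0.4 * d$z + 0.3 * d$w + rnorm(40)
  f <- first_stage_f(d, "x", "z", "w")
  X0 <- cbind(1, d$w)
  X1 <- cbind(1, d$w, d$z)
  rss0 <- sum((d$x - X0 %*% oracle_ols(X0, d$x))^2)
  rss1 <- sum((d$x - X1 %*% oracle_ols(X1, d$x))^2)
  expect_equal(as.numeric(f), oracle_partial_f(rss0, rss1, 1, 40 - 3),
               tolerance = 1e-8)
})

test_that("the null first-stage F averages to one", {
  set.seed(5)
  fs <- replicate(200, {
    d <- tibble::tibble(z = rnorm(1000), w = rnorm(1000))
    d$x <- 0.3 * d$w + rnorm(1000)   # instrument truly irrelevant
    as.numeric(first_stage_f(d, "x", "z", "w"))
  })
  expect_gt(mean(fs), 0.8)
  expect_lt(mean(fs), 1.2)
})

test_that("first-stage F sits in the calibrated band on default simulations", {
  sim <- quick_sim(n = 2700, seed = 36, attrition = NULL)
  fr <- quick_frame(sim)
  f <- first_stage_f(fr, "log_bmi", "score",
                     c("age_c", "sex", "height", "packyears"))
  expect_gt(as.numeric(f), 50)
  expect_lt(as.numeric(f), 400)
})

test_that("effect_at_age applies the delta method around the centering age", {
  sim <- quick_sim(n = 900, seed = 37, attrition = NULL)
  fr <- quick_frame(sim)
  fit <- run_model(fr, mode = "causal")
  e0 <- effect_at_age(fit, 0)
  expect_equal(e0$estimate, coef(fit)[["log_bmi"]])
  expect_equal(e0$se, sqrt(vcov(fit)["log_bmi", "log_bmi"]))
  e20 <- effect_at_age(fit, 20)
  V <- vcov(fit)[c("log_bmi", "log_bmi:age_c"), c("log_bmi", "log_bmi:age_c")]
  expect_equal(e20$se, sqrt(drop(t(c(1, 20)) %*% V %*% c(1, 20))))
})

test_that("published coefficients combine to the in-text effects", {
  co <- c(log_bmi = -0.752, `log_bmi:age_c` = 0.021)
  expect_equal(co[["log_bmi"]] + 10 * co[["log_bmi:age_c"]], -0.542)
  d10 <- predict_bmi_delta(co, 25, 30, age_c = 10)
  expect_equal(round(d10$delta, 2), -0.10)
  d40 <- predict_bmi_delta(co, 25, 30, age_c = 40)
  expect_equal(round(d40$delta, 3), 0.016)
  # no BMI change, no effect; non-positive BMI rejected
  expect_equal(predict_bmi_delta(co, 27, 27, age_c = 15)$delta, 0)
  expect_error(predict_bmi_delta(co, 0, 30, 10), "positive")
})

test_that("the sex interaction enters the BMI-change multiplier when present", {
  co <- c(log_bmi = -0.7, `log_bmi:age_c` = 0.02, `log_bmi:sex` = 0.1)
  male <- predict_bmi_delta(co, 25, 30, age_c = 10, sex = 0)$delta
  female <- predict_bmi_delta(co, 25, 30, age_c = 10, sex = 1)$delta
  expect_equal(male, (-0.7 + 0.2) * log(30 / 25))
  expect_equal(female - male, 0.1 * log(30 / 25))
})

test_that("aic_compare ranks models and refuses invalid comparisons", {
  set.seed(8)
  d <- tibble::tibble(x = rnorm(200), j = rnorm(200))
  d$y <- 1 + 0.5 * d$x + rnorm(200)
  f1 <- fit_ols(d, "y", "x")
  expect_equal(aic_compare(list(a = f1, b = f1))$delta_aic, c(0, 0))
  # a pure-noise extra term costs about two AIC points
  deltas <- replicate(150, {
    d$y <- 1 + 0.5 * d$x + rnorm(200)
    d$j <- rnorm(200)
    small <- fit_ols(d, "y", "x")
    big <- fit_ols(d, "y", c("x", "j"))
    big$aic - small$aic
  })
  expect_gte(median(deltas), 0)
  expect_lte(median(deltas), 4)
  # differing n or transform refuse
  f2 <- fit_ols(d[1:100, ], "y", "x")
  expect_error(aic_compare(list(f1, f2)), "differing sample sizes")
  d$ypos <- exp(d$y / 5)
  f3 <- fit_ols(d, "ypos", "x", transform = "log")
  f4 <- fit_ols(d, "ypos", "x")
  expect_error(aic_compare(list(f3, f4)), "Jacobian")
})

test_that("AIC selects the log-BMI exposure when the truth is logarithmic", {
  set.seed(9)
  wins <- replicate(200, {
    bmi <- exp(rnorm(800, log(25), 0.18))
    y <- 2 - 1.5 * log(bmi) + rnorm(800, 0, 0.12)
    d <- tibble::tibble(bmi = bmi, log_bmi = log(bmi), y = y)
    flog <- fit_ols(d, "y", "log_bmi")
    flin <- fit_ols(d, "y", "bmi")
    flog$aic < flin$aic
  })
  expect_gte(mean(wins), 0.95)
})

test_that("without confounding, OLS and 2SLS converge at large n", {
  sim <- quick_sim(n = 30000, seed = 38, attrition = NULL,
                   conf_to_lf = 0)
  fr <- quick_frame(sim)
  iv <- run_model(fr, mode = "causal")
  ols <- run_model(fr, mode = "observational")
  gap_big <- abs(coef(iv)[["log_bmi"]] - coef(ols)[["log_bmi"]])
  expect_lt(gap_big, 0.08)
  expect_lt(abs(coef(ols)[["log_bmi"]] - sim$truth$config$beta_c1), 0.05)
})

test_that("robust covariance is available and close to classical under homoskedasticity", {
  sim <- quick_sim(n = 2000, seed = 39, attrition = NULL)
  fr <- quick_frame(sim)
  f_c <- run_model(fr, mode = "causal")
  f_r <- run_model(fr, mode = "causal", vcov_type = "robust")
  expect_equal(coef(f_c), coef(f_r))
  ratio <- sqrt(diag(vcov(f_r))["log_bmi"] / diag(vcov(f_c))["log_bmi"])
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("fits serialize to JSON with coefficients and diagnostics", {
  sim <- quick_sim(n = 400, seed = 40, attrition = NULL)
  fr <- quick_frame(sim)
  fit <- suppressWarnings(run_model(fr, mode = "causal"))
  js <- jsonlite::fromJSON(write_fit_json(fit))
  expect_equal(js$class, "iv_fit")
  expect_equal(js$coefficients$log_bmi, coef(fit)[["log_bmi"]])
  expect_equal(length(js$first_stage$f_statistic), 3)
})
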