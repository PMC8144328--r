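# Shared fixtures: all data is generated in code, no files.

quick_sim <- function(n = 1000, seed = 1, ...) {
  simulate_cohort(default_config(n_individuals = n, seed = seed, ...))
}

# long-term frame with the generating score attached
quick_frame <- function(sim, which = "long_term") {
  fr <- suppressMessages(build_frame(sim$cohort, which))
  add_score(fr, compute_score(sim$genotypes, sim_weight_table(sim)))
}

# brute-force normal-equations OLS oracle: explicit (X'X)^{-1} X'y
oracle_ols <- function(X, y) {
  drop(solve(t(X) %*% X) %*% t(X) %*% y)
}

# textbook just-identified IV oracle for one endogenous regressor and one
# instrument (with intercept): beta = cov(z, y) / cov(z, x)
oracle_iv_ratio <- function(z, x, y) {
  stats::cov(z, y) / stats::cov(z, x)
}

# partial F from explicit residual sums of squares
oracle_partial_f <- function(rss0, rss1, q, df2) {
  ((rss0 - rss1) / q) / (rss1 / df2)
}

# hand-rolled two-stage residualization for partial correlations: each
# variable is residualized on its covariate expansion via explicit
# normal equations, then the residuals are correlated
oracle_partial_cor <- function(y1, y2, X1, X2) {
  # residuals are invariant to column scaling; scale for conditioning of
  # the explicit normal equations
  res <- function(y, X) {
    s <- apply(X, 2, function(c) max(abs(c)))
    Xs <- sweep(X, 2, s, "/")
    y - Xs %*% solve(t(Xs) %*% Xs) %*% t(Xs) %*% y
  }
  stats::cor(res(y1, X1), res(y2, X2))[1, 1]
}

# tiny deterministic cohort: two individuals, three surveys, no
# missingness, constructed by hand for arithmetic checks
toy_cohort <- function() {
  tibble::tibble(
    id = rep(c("a", "b"), each = 3),
    sex = rep(c(0, 1), each = 3),
    survey = rep(1:3, 2),
    participated = 1L,
    age = c(28, 38, 48, 40, 50, 60),
    height = c(175, 175, 175, 163, 163, 163),
    weight = NA_real_,
    bmi = c(24, 26, 28, 22, 23, 24),
    fev1 = c(3.5, 3.4, 3.3, 2.8, 2.7, 2.6),
    fvc = c(4.5, 4.4, 4.3, 3.6, 3.5, 3.4),
    fev1fvc = c(3.5 / 4.5, 3.4 / 4.4, 3.3 / 4.3, 2.8 / 3.6, 2.7 / 3.5, 2.6 / 3.4),
    fef2575 = c(3.1, 2.9, 2.7, 2.5, 2.3, 2.1),
    packyears = c(0, 0, 0, 5, 10, 12),
    asthma = 0L
  )
}
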