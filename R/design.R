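# Design-matrix utilities shared by the OLS and 2SLS fitters.
#
# Model terms are given as character vectors; "a:b" denotes the
# element-wise product of columns a and b. An intercept is always
# prepended. Degenerate designs fail loudly with the offending columns
# named -- nothing is dropped silently.

term_matrix <- function(data, terms) {
  if (!length(terms)) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  cols <- lapply(terms, function(tm) {
    if (tm %in% names(data)) return(as.numeric(data[[tm]]))
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    missing <- setdiff(parts, names(data))
    if (length(missing)) {
      stop("unknown variable(s) in term '", tm, "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    Reduce(`*`, lapply(parts, function(p) as.numeric(data[[p]])))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}

design_matrix <- function(data, terms) {
  X <- cbind(`(Intercept)` = rep(1, nrow(data)), term_matrix(data, terms))
  if (anyNA(X) || any(!is.finite(X))) {
    stop("non-finite values in design matrix; restrict to complete cases first",
         call. = FALSE)
  }
  X
}

check_full_rank <- function(X, what = "design") {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient ", what, " matrix; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  qrX
}

# weighted least squares on a prebuilt design; returns the pieces the
# fit classes share
lstsq <- function(X, y, w = NULL, what = "design") {
  if (!is.null(w)) {
    sw <- sqrt(w)
    qrX <- check_full_rank(X * sw, what)
    coef <- qr.coef(qrX, y * sw)
    fitted <- drop(X %*% coef)
    resid <- y - fitted
    rss <- sum(w * resid^2)
  } else {
    qrX <- check_full_rank(X, what)
    coef <- qr.coef(qrX, y)
    fitted <- drop(X %*% coef)
    resid <- y - fitted
    rss <- sum(resid^2)
  }
  names(coef) <- colnames(X)
  list(coef = coef, fitted = fitted, resid = resid, rss = rss, qr = qrX)
}

gaussian_loglik <- function(rss, n, w = NULL) {
  # matches stats::logLik.lm: ML variance estimate rss/n
  half <- if (is.null(w)) 0 else sum(log(w)) / 2
  half - n / 2 * (log(2 * pi) + 1 + log(rss / n))
}
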