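#' Standardize a numeric vector to z-scores
#'
#' Centred to mean 0 and scaled to sample standard deviation 1.
#'
#' @param x Numeric vector with at least two values and positive variance.
#' @return Numeric vector of the same length.
#' @export
zscore <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) abort("need at least 2 values", class = "phylograd_domain_error")
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("cannot z-score a constant vector", class = "phylograd_domain_error")
  }
  (x - mean(x)) / s
}

#' Gaussian maximum-likelihood OLS fit
#'
#' Ordinary least squares with the Gaussian maximized log-likelihood
#' \eqn{-\frac{n}{2}(\log 2\pi + \log(\mathrm{RSS}/n) + 1)} (ML residual
#' variance, i.e. RSS divided by \eqn{n}, not \eqn{n-p}). The parameter
#' count `k` includes the intercept, the slopes and the residual variance —
#' the convention under which AICc values are comparable across the
#' candidate set.
#'
#' @param data A data frame.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names (empty for
#'   the intercept-only null model).
#' @return An object of class `phylograd_fit`: a list with the underlying
#'   `lm` fit plus `response`, `predictors`, `n`, `k`, `loglik`, `rss` and
#'   `aicc`.
#' @export
fit_ols_ml <- function(data, response, predictors = character()) {
  stopifnot(is.character(response), length(response) == 1L)
  predictors <- as.character(predictors)
  fo <- reformulate(if (length(predictors)) predictors else "1", response = response)
  fit <- lm(fo, data = data)
  p <- length(coef(fit))
  if (fit$rank < p || anyNA(coef(fit))) {
    abort("rank-deficient design matrix", class = "phylograd_domain_error")
  }
  rss <- sum(resid(fit)^2)
  tss <- sum((data[[response]] - mean(data[[response]]))^2)
  if (rss <= max(1e-12, 1e-10 * tss)) {
    abort("perfect fit (RSS ~ 0): Gaussian likelihood unbounded",
      class = "phylograd_domain_error")
  }
  ll <- logLik(fit)
  out <- list(
    fit = fit,
    response = response,
    predictors = predictors,
    n = nobs(fit),
    k = attr(ll, "df"), # coefficients + residual variance
    loglik = as.numeric(ll),
    rss = rss
  )
  out$aicc <- aicc(out)
  class(out) <- "phylograd_fit"
  out
}

#' @export
print.phylograd_fit <- function(x, ...) {
  cat("Gaussian-ML OLS fit: ", x$response, " ~ ",
    if (length(x$predictors)) paste(x$predictors, collapse = " + ") else "1",
    "\n  n = ", x$n, ", k = ", x$k,
    ", logLik = ", formatC(x$loglik, digits = 4, format = "f"),
    ", AICc = ", formatC(x$aicc, digits = 2, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)}.
#'
#' @param fit A `phylograd_fit`, or a list with elements `loglik`, `n`, `k`.
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  n <- fit$n
  k <- fit$k
  if (n - k - 1 <= 0) {
    abort("AICc undefined: n - k - 1 <= 0", class = "phylograd_domain_error")
  }
  -2 * fit$loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc multimodel ranking over all predictor subsets
#'
#' Fits the full candidate set of additive OLS models — the intercept-only
#' null, every single predictor, every pair, up to the full set (8 models
#' for three predictors) — and ranks them by AICc. Akaike weights are
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}.
#'
#' @param data A data frame of responses and predictors.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @return A tibble of class `phylograd_ranking`, sorted by AICc, with
#'   columns `response`, `model`, `k`, `loglik`, `aicc`, `delta_aicc`,
#'   `weight`.
#' @export
rank_models <- function(data, response, predictors) {
  predictors <- as.character(predictors)
  subsets <- unlist(
    lapply(0:length(predictors), function(m) {
      combn(predictors, m, simplify = FALSE)
    }),
    recursive = FALSE
  )
  fits <- lapply(subsets, function(s) fit_ols_ml(data, response, s))
  tbl <- tibble::tibble(
    response = response,
    model = vapply(subsets, function(s) {
      if (length(s)) paste(s, collapse = " + ") else "Null"
    }, character(1)),
    predictors = subsets,
    k = vapply(fits, `[[`, 0, "k"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    aicc = vapply(fits, `[[`, 0, "aicc")
  )
  tbl$delta_aicc <- tbl$aicc - min(tbl$aicc)
  tbl$weight <- exp(-tbl$delta_aicc / 2) / sum(exp(-tbl$delta_aicc / 2))
  tbl <- dplyr::arrange(tbl, .data$aicc)
  class(tbl) <- c("phylograd_ranking", class(tbl))
  tbl
}

#' Second-order polynomial fit with quadratic-term test
#'
#' Fits `response ~ poly(predictor, 2)` on an orthogonalized basis (for
#' conditioning; the reported statistics are invariant to the basis) and
#' reports the t-test p-value of the quadratic term.
#'
#' @param data A data frame.
#' @param response,predictor Column names.
#' @return A list of class `phylograd_poly2`: `fit`, `response`,
#'   `predictor`, `loglik`, `aicc`, `quadratic_coef`, `quadratic_p`,
#'   `rss`, `perfect` (`TRUE` when the quadratic interpolates the data
#'   exactly, where the t-test is meaningless).
#' @export
fit_poly2 <- function(data, response, predictor) {
  if (nrow(data) < 4L) {
    abort("need at least 4 observations for a quadratic fit",
      class = "phylograd_domain_error")
  }
  fo <- stats::as.formula(paste0(response, " ~ poly(", predictor, ", 2)"))
  fit <- lm(fo, data = data)
  rss <- sum(resid(fit)^2)
  tss <- sum((data[[response]] - mean(data[[response]]))^2)
  perfect <- rss <= max(1e-12, 1e-10 * tss)
  co <- if (perfect) {
    suppressWarnings(summary(fit)$coefficients) # t stats meaningless at RSS ~ 0
  } else {
    summary(fit)$coefficients
  }
  ll <- logLik(fit)
  out <- list(
    fit = fit,
    response = response,
    predictor = predictor,
    n = nobs(fit),
    k = attr(ll, "df"),
    loglik = as.numeric(ll),
    rss = rss,
    quadratic_coef = co[3L, 1L],
    quadratic_p = if (perfect) NA_real_ else co[3L, 4L],
    perfect = perfect
  )
  out$aicc <- if (out$n - out$k - 1 > 0) aicc(out) else NA_real_
  class(out) <- "phylograd_poly2"
  out
}

#' Pearson correlation with two-sided t test
#'
#' @param data A data frame.
#' @param var1,var2 Column names.
#' @return A one-row tibble: `r`, `df`, `p_value`, `n`.
#' @export
pearson_test <- function(data, var1, var2) {
  x <- data[[var1]]
  y <- data[[var2]]
  if (length(x) < 3L) abort("need at least 3 observations", class = "phylograd_domain_error")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance input", class = "phylograd_domain_error")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(
    var1 = var1, var2 = var2,
    r = unname(ct$estimate),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    n = length(x)
  )
}

#' Mantel permutation test between two distance matrices
#'
#' Plain (Pearson) Mantel statistic: the correlation between the
#' lower-triangle entries of the two matrices. Significance is assessed
#' one-sided (greater) by jointly permuting rows and columns of the second
#' matrix: \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\})/(B + 1)}.
#'
#' @param d1,d2 Symmetric distance matrices over the same labels (matrices
#'   or `dist` objects; when both carry dimnames, `d2` is aligned to `d1`).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return A one-row tibble of class `phylograd_mantel`: `r`, `p_value`,
#'   `n_perm`, `n`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  d1 <- as.matrix(d1)
  d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) {
    abort("distance matrices must have the same dimension",
      class = "phylograd_validation_error")
  }
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2))) {
      abort("distance matrices have different labels",
        class = "phylograd_validation_error")
    }
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  if (!isSymmetric(unname(d1), tol = 1e-8) || !isSymmetric(unname(d2), tol = 1e-8)) {
    abort("distance matrices must be symmetric", class = "phylograd_validation_error")
  }
  n <- nrow(d1)
  lower <- lower.tri(d1)
  v1 <- d1[lower]
  r_obs <- cor(v1, d2[lower])
  run <- function() {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      r_p <- cor(v1, d2[p, p][lower])
      if (r_p >= r_obs) hits <- hits + 1L
    }
    hits
  }
  hits <- if (!is.null(seed)) withr::with_seed(seed, run()) else run()
  out <- tibble::tibble(
    r = r_obs,
    p_value = (1 + hits) / (n_perm + 1),
    n_perm = n_perm,
    n = n
  )
  class(out) <- c("phylograd_mantel", class(out))
  out
}
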