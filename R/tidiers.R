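#' Tidy a standardized-effect-size table
#'
#' Pivots the per-site SES table to one row per site x index, the shape
#' plotting and modelling verbs expect.
#'
#' @param x A `phylograd_ses` object.
#' @param ... Unused.
#' @return A tibble: `site`, (`elevation`,) `richness`, `index` (nri / nti /
#'   ses_pd), `value`, `significant`.
#' @export
tidy.phylograd_ses <- function(x, ...) {
  tbl <- tibble::as_tibble(x)
  keep <- intersect(c("site", "elevation", "richness"), names(tbl))
  long <- tidyr::pivot_longer(tbl[, c(keep, "nri", "nti", "ses_pd")],
    cols = c("nri", "nti", "ses_pd"),
    names_to = "index", values_to = "value")
  sig <- tidyr::pivot_longer(tbl[, c("site", "nri_sig", "nti_sig", "ses_pd_sig")],
    cols = -"site", names_to = "index", values_to = "significant")
  sig$index <- sub("_sig$", "", sig$index)
  dplyr::left_join(long, sig, by = c("site", "index"))
}

#' Summarise a standardized-effect-size table
#'
#' @param x A `phylograd_ses` object.
#' @param ... Unused.
#' @return A one-row tibble: site count, null iterations, and the number of
#'   sites flagged as significantly clustered (index >= threshold) per
#'   index.
#' @export
glance.phylograd_ses <- function(x, ...) {
  thr <- attr(x, "sig_threshold") %||% 1.96
  tibble::tibble(
    n_sites = nrow(x),
    n_null = max(x$n_null),
    sig_threshold = thr,
    n_clustered_nri = sum(x$nri >= thr, na.rm = TRUE),
    n_clustered_nti = sum(x$nti >= thr, na.rm = TRUE),
    n_low_pd = sum(x$ses_pd <= -thr, na.rm = TRUE)
  )
}

#' Tidy an AICc model ranking
#'
#' @param x A `phylograd_ranking` object.
#' @param ... Unused.
#' @return The ranking as a plain tibble (one row per candidate model).
#' @export
tidy.phylograd_ranking <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$predictors <- NULL
  out
}

#' Summarise an AICc model ranking
#'
#' @param x A `phylograd_ranking` object.
#' @param ... Unused.
#' @return A one-row tibble describing the best-supported model.
#' @export
glance.phylograd_ranking <- function(x, ...) {
  tibble::tibble(
    response = x$response[1L],
    n_models = nrow(x),
    best_model = x$model[1L],
    best_aicc = x$aicc[1L],
    best_weight = x$weight[1L],
    n_plausible = sum(x$delta_aicc < 2)
  )
}

#' Tidy a Gaussian-ML OLS fit
#'
#' @param x A `phylograd_fit` object.
#' @param ... Unused.
#' @return A tibble of coefficients: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`.
#' @export
tidy.phylograd_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = co[, 1L],
    std_error = co[, 2L],
    statistic = co[, 3L],
    p_value = co[, 4L]
  )
}

#' Summarise a Gaussian-ML OLS fit
#'
#' @param x A `phylograd_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `response`, `model`, `n`, `k`, `loglik`,
#'   `aicc`, `rss`.
#' @export
glance.phylograd_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    model = if (length(x$predictors)) paste(x$predictors, collapse = " + ") else "Null",
    n = x$n, k = x$k, loglik = x$loglik, aicc = x$aicc, rss = x$rss
  )
}
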