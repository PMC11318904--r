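#' Plot standardized effect sizes along the gradient
#'
#' One panel per index (NRI, NTI, SES.PD) against elevation, with dashed
#' horizontal lines at the +/- significance demarcation: points above the
#' upper line indicate phylogenetic clustering (or, for SES.PD, below the
#' lower line indicate depauperate phylogenetic diversity).
#'
#' @param object A `phylograd_ses` table with an `elevation` column.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phylograd_ses <- function(object, ...) {
  if (!"elevation" %in% names(object)) {
    abort("plotting needs an `elevation` column", class = "phylograd_validation_error")
  }
  thr <- attr(object, "sig_threshold") %||% 1.96
  long <- tidy(object)
  long$index <- factor(toupper(sub("ses_pd", "SES.PD", long$index)),
    levels = c("NRI", "NTI", "SES.PD"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$elevation, y = .data$value)) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed",
      colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue", `TRUE` = "firebrick"),
      na.value = "grey50", name = paste0("|index| ≥ ", thr)) +
    ggplot2::facet_wrap(~index, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Elevation (m a.s.l.)", y = "Standardized effect size") +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise dissimilarity matrix
#'
#' @param m A symmetric site x site matrix (e.g. one element of
#'   [beta_matrices()] or [comdist_matrix()]).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_beta_heatmap <- function(m, title = "Pairwise dissimilarity") {
  m <- as.matrix(m)
  df <- tibble::tibble(
    site1 = factor(rep(rownames(m), times = ncol(m)), levels = rownames(m)),
    site2 = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$site1, .data$site2, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "dissimilarity") +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Richness and phylogenetic diversity along the gradient
#'
#' Observed per-site species richness and Faith's PD against elevation with
#' a second-order polynomial fit — diversity on tropical mountains commonly
#' peaks at mid elevation, and the quadratic captures that hump.
#'
#' @param ses A `phylograd_ses` table with an `elevation` column.
#' @return A ggplot object.
#' @export
plot_diversity_elevation <- function(ses) {
  if (!"elevation" %in% names(ses)) {
    abort("plotting needs an `elevation` column", class = "phylograd_validation_error")
  }
  tbl <- tibble::as_tibble(ses)[, c("elevation", "richness", "pd")]
  long <- tidyr::pivot_longer(tbl, cols = c("richness", "pd"),
    names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure, levels = c("richness", "pd"),
    labels = c("Species richness", "Faith's PD"))
  ggplot2::ggplot(long, ggplot2::aes(.data$elevation, .data$value)) +
    ggplot2::geom_point(size = 2.5, colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ poly(x, 2),
      se = FALSE, colour = "firebrick") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Elevation (m a.s.l.)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
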