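#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot enrichment time courses
#'
#' Observed mean fractional enrichment against time, one panel per
#' metabolite, colored by leaf rank.
#'
#' @param tc Tibble from [enrichment_timecourses()].
#' @param metabolites Optional subset of metabolites to show.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(tc, metabolites = NULL) {
  if (!is.null(metabolites)) {
    tc <- dplyr::filter(tc, .data$metabolite %in% metabolites)
  }
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$time_min, y = .data$enrichment,
                                   colour = .data$leaf_rank,
                                   group = interaction(.data$leaf_rank,
                                                       .data$replicate))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metabolite)) +
    ggplot2::labs(x = "Time (min)", y = "Fractional 15N enrichment",
                  colour = "Leaf rank") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' @export
autoplot.pca_fingerprint <- function(object, ellipses = TRUE, level = 0.95,
                                     ...) {
  sc <- object$scores
  pct <- round(100 * object$var_explained[1:2], 1)
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                        colour = .data$leaf_rank)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste0("Dim1 (", pct[1], "%)"),
                  y = paste0("Dim2 (", pct[2], "%)"),
                  colour = "Leaf rank") +
    ggplot2::theme_bw()
  if (ellipses) {
    ell <- sc |>
      dplyr::group_by(.data$leaf_rank) |>
      dplyr::group_modify(function(d, key) {
        if (nrow(d) < 3L) return(tibble::tibble(x = numeric(),
                                                y = numeric()))
        score_ellipse(as.matrix(d[, c("PC1", "PC2")]), level = level)
      }) |>
      dplyr::ungroup()
    if (nrow(ell)) {
      p <- p + ggplot2::geom_path(
        data = ell,
        ggplot2::aes(x = .data$x, y = .data$y, colour = .data$leaf_rank),
        inherit.aes = FALSE)
    }
  }
  p
}

#' @export
autoplot.subsystem_fit <- function(object, n_grid = 101, ...) {
  d <- object$data
  tt <- seq(min(d$time_min), max(d$time_min), length.out = n_grid)
  sim <- tibble::tibble(
    time_min = tt,
    enrichment = simulate_enrichment(object$input, tt, object$v_hat,
                                     object$M_hat, x0 = object$x0)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min,
                                  y = .data$enrichment)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = sim, colour = "steelblue") +
    ggplot2::labs(
      title = paste0(object$precursor, " → ", object$product,
                     "  (v = ", signif(object$v_hat, 4),
                     " nmol g-1 DW min-1)"),
      x = "Time (min)", y = "Fractional 15N enrichment") +
    ggplot2::theme_bw()
}

#' Plot per-rank flux summaries
#'
#' Bar chart of mean estimated fluxes with SD error bars, one facet per
#' subsystem product.
#'
#' @param summary Tibble from [summarize_fluxes()].
#' @return A ggplot object.
#' @export
plot_flux_summary <- function(summary) {
  summary <- dplyr::mutate(
    summary, leaf_rank = factor(.data$leaf_rank,
                                levels = unique(.data$leaf_rank)))
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$leaf_rank,
                                        y = .data$mean_flux)) +
    ggplot2::geom_col(fill = "grey70", colour = "black") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_flux - .data$sd_flux,
                   ymax = .data$mean_flux + .data$sd_flux),
      width = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$product), scales = "free_y") +
    ggplot2::labs(x = "Leaf rank",
                  y = "Biosynthesis flux (nmol g-1 DW min-1)") +
    ggplot2::theme_bw()
}
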