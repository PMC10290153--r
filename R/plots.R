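#' Plot per-sample read-length spectra
#'
#' Column chart of RPM by read length, faceted by group, with one bar per
#' length averaged over samples and per-sample points overlaid.
#'
#' @param spectra A `trf_spectrum` tibble.
#' @param highlight Optional length(s) to colour (e.g. a called peak).
#' @return A ggplot object.
#' @export
plot_length_spectrum <- function(spectra, highlight = NULL) {
  means <- spectra %>%
    group_by(.data$group, .data$length) %>%
    summarise(mean_rpm = mean(.data$rpm), .groups = "drop") %>%
    mutate(highlighted = .data$length %in% (highlight %||% integer(0)))
  ggplot2::ggplot(means, ggplot2::aes(x = .data$length, y = .data$mean_rpm,
                                      fill = .data$highlighted)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_point(data = as_tibble(spectra), inherit.aes = FALSE,
                        mapping = ggplot2::aes(x = .data$length, y = .data$rpm),
                        size = 0.4, alpha = 0.4) +
    ggplot2::facet_wrap(~group, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "read length (nt)", y = "reads per million")
}

#' @export
autoplot.trf_spectrum <- function(object, ...) plot_length_spectrum(object, ...)

#' Plot the sequence composition of a peak
#'
#' Stacked bar of per-scope sequence fractions (the bar-chart equivalent of
#' the usual pie charts). Sequences beyond the top `max_sequences` are
#' lumped as "other".
#'
#' @param composition Tibble from [decompose_peak()].
#' @param max_sequences Number of distinct sequences to show.
#' @return A ggplot object.
#' @export
plot_peak_composition <- function(composition, max_sequences = 4) {
  comp <- composition %>%
    mutate(label = ifelse(.data$rank <= max_sequences,
                          paste0("seq", .data$rank), "other")) %>%
    group_by(.data$scope, .data$label) %>%
    summarise(fraction = sum(.data$fraction), .groups = "drop")
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$scope, y = .data$fraction,
                                     fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of peak reads", fill = NULL)
}

#' Plot PCA scores with QC samples marked
#'
#' @param pca A `trf_pca` object from [pca_scores()].
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(pca) {
  df <- tibble(sample = rownames(pca$scores),
               group = pca$groups %||% "sample",
               pc1 = pca$scores[, 1],
               pc2 = if (ncol(pca$scores) > 1) pca$scores[, 2] else 0)
  vf <- round(100 * pca$variance_fraction, 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   colour = .data$group,
                                   shape = .data$group == "QC")) +
    ggplot2::geom_point(size = 2, show.legend = c(colour = TRUE, shape = FALSE)) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", vf[1]),
                  y = if (length(vf) > 1) sprintf("PC2 (%.1f%%)", vf[2]) else "PC2")
}

#' @export
autoplot.trf_pca <- function(object, ...) plot_pca_scores(object)

#' Plot VIP scores with the screening cutoff
#'
#' @param fit A `plsda_vip` object.
#' @param vip_cutoff Cutoff line (default 1).
#' @param top Label/show only the `top` highest-VIP metabolites.
#' @return A ggplot object.
#' @export
plot_vip <- function(fit, vip_cutoff = 1, top = 25) {
  df <- fit$vip %>% arrange(desc(.data$vip)) %>% slice_head(n = top)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$metabolite, .data$vip),
                                   y = .data$vip)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = vip_cutoff, linetype = 2,
                        colour = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "VIP")
}

#' @export
autoplot.plsda_vip <- function(object, ...) plot_vip(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
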