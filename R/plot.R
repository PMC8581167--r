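# ggplot2 views of the pipeline's result tables: radial trend plots (one
# line per colony / replicate, faceted by marker) and PCA score plots.

#' Radial trend plot
#'
#' Mean normalized expression as a function of distance from the colony
#' centre, one line per profile unit (colony, well or line), faceted by
#' marker. Ribbons show +/- 1 SD where the table carries an `sd` column.
#'
#' @param profiles Long profile table (from [radial_profiles()] or
#'   [aggregate_profiles()]).
#' @param unit Column identifying one plotted line (default `"colony"`;
#'   use `"well"` or `"line"` for aggregated tables).
#' @param bin_width_um Ring spacing used to convert bins to um.
#' @return A ggplot object.
#' @export
plot_radial_profiles <- function(profiles, unit = "colony",
                                 bin_width_um = 25) {
  df <- mutate(profiles,
               dist = (bin - 0.5) * bin_width_um,
               .unit = interaction(!!!rlang::syms(
                 intersect(c("well", unit), names(profiles)))))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = dist, y = value,
                                        group = .unit, colour = .unit))
  if ("sd" %in% names(df))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(value - sd, 0), ymax = value + sd,
                   fill = .unit),
      alpha = 0.2, colour = NA)
  p + ggplot2::geom_line() +
    ggplot2::facet_wrap(~marker) +
    ggplot2::labs(x = "Distance from colony center (µm)",
                  y = "Normalized expression", colour = unit, fill = unit) +
    ggplot2::theme_minimal()
}

#' Percent-positive scatter by line
#'
#' One point per colony, faceted by marker, mirroring the standard
#' per-line expression summary of high-content differentiation screens.
#'
#' @param pct Percent-positive table from [percent_positive_table()] with
#'   a `line` column.
#' @return A ggplot object.
#' @export
plot_percent_positive <- function(pct) {
  ggplot2::ggplot(pct, ggplot2::aes(x = line, y = percent_positive)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "red3", linewidth = 0.3) +
    ggplot2::facet_wrap(~marker) +
    ggplot2::labs(x = NULL, y = "% positive cells per colony") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' PCA score plot of line-level marker features
#'
#' @param object An `mp_pca` from [pca_lines()].
#' @param ... Unused.
#' @return A ggplot object; points are labelled by line id and coloured by
#'   donor (the four-letter line prefix), so clonal lines of one donor
#'   share a colour.
#' @export
autoplot.mp_pca <- function(object, ...) {
  scores <- tidy(object)
  ve <- glance(object)$variance_explained
  scores$donor <- sub("_.*$", "", scores$line)
  ggplot2::ggplot(scores, ggplot2::aes(PC1, PC2, colour = donor)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = line), vjust = -0.8,
                       size = 3, show.legend = FALSE) +
    ggplot2::labs(x = sprintf("PC1 (%.0f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.0f%%)",
                              if (length(ve) > 1) 100 * ve[2] else 0)) +
    ggplot2::theme_minimal()
}
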