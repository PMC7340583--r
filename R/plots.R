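#' Dot plot of per-cell wall mCherry by strain
#'
#' The presentation used for within-field comparisons: one dot per cell
#' (its mean wall mCherry), jittered by group, with the group mean and
#' mean +/- s.d. overlaid in red. Unclassified cells are dropped.
#'
#' @param records A cell-record tibble with identities assigned.
#' @return A ggplot object.
#' @export
plot_wall_intensity <- function(records) {
  df <- dplyr::filter(records, .data$identity %in% c("reference", "tester"))
  if (nrow(df) == 0L) abort("No classified cells to plot.")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$identity,
                                   y = .data$mean_wall_mcherry)) +
    ggplot2::geom_jitter(width = 0.15, colour = "steelblue", alpha = 0.6,
                         size = 1.2) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          size = 2.5) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1), geom = "errorbar",
                          colour = "red", width = 0.2) +
    ggplot2::labs(x = NULL, y = "Mean wall mCherry (ADU)",
                  title = "Cell-wall mCherry per cell") +
    ggplot2::theme_classic()
}

#' Bar plot of replicate mating efficiencies
#'
#' Mean efficiency per group with s.d. error bars and individual replicate
#' points.
#'
#' @param counts Tibble with columns `group`, `diploids`, `total`.
#' @return A ggplot object.
#' @export
plot_mating <- function(counts) {
  if (!"group" %in% names(counts)) abort("`counts` needs a `group` column.")
  df <- dplyr::mutate(counts,
                      efficiency = mating_efficiency(.data$diploids, .data$total))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$efficiency)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey80",
                          colour = "black", width = 0.6) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1), geom = "errorbar",
                          width = 0.2) +
    ggplot2::geom_jitter(width = 0.1, size = 1.5) +
    ggplot2::labs(x = NULL, y = "Mating efficiency",
                  title = "Quantitative mating assay") +
    ggplot2::theme_classic()
}
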