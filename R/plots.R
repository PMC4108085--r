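# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col geom_abline
#'   geom_vline labs facet_wrap scale_colour_brewer ylim theme_minimal
NULL

#' Plot a metagene methylation profile
#'
#' Bin means as points, the moving average as a line, with the TSS and
#' TES marked.
#'
#' @param object An `mscc_metagene` profile.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.mscc_metagene <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$position, y = .data$mean_level)) +
    geom_point(alpha = 0.5, size = 1, na.rm = TRUE) +
    geom_line(aes(y = .data$smoothed), linewidth = 0.8, na.rm = TRUE) +
    geom_vline(xintercept = c(0, 1), linetype = "dashed", colour = "grey50") +
    ylim(0, 1) +
    labs(x = "position relative to gene (TSS = 0, TES = 1)",
         y = "mean methylation level") +
    theme_minimal()
}

#' Plot unit comparisons as a before/after scatter
#'
#' One point per analysis unit and treated sample: baseline unit mean on
#' the x axis, treated mean on the y axis, with the delta-cutoff boundary
#' lines, faceted by treated sample.
#'
#' @param object An `mscc_dmr` object from [compare_all_units()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.mscc_dmr <- function(object, ...) {
  ggplot(object$comparisons,
         aes(x = .data$mean_a, y = .data$mean_b, colour = .data$kind)) +
    geom_point(alpha = 0.4, size = 1) +
    geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    geom_abline(slope = 1, intercept = c(-1, 1) * object$delta_cutoff,
                colour = "black", linetype = "dashed") +
    facet_wrap(~sample_b) +
    scale_colour_brewer(palette = "Set1") +
    labs(x = paste0("mean level, ", object$baseline),
         y = "mean level, treated sample", colour = "unit") +
    theme_minimal()
}

#' Plot a depth-accuracy curve
#'
#' Pairwise correlation of methylation levels as a function of the depth
#' threshold.
#'
#' @param object An `mscc_depth_curve` from [depth_accuracy_curve()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.mscc_depth_curve <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$threshold, y = .data$r)) +
    geom_point() +
    geom_line() +
    labs(x = "minimum depth in both replicates",
         y = "Pearson correlation") +
    theme_minimal()
}

#' Plot per-chromosome mean methylation
#'
#' @param object An `mscc_chrom_summary` from [chromosome_summary()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.mscc_chrom_summary <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$chrom, y = .data$mean_level)) +
    geom_col(na.rm = TRUE) +
    labs(x = NULL, y = "mean methylation level") +
    theme_minimal()
}

#' Plot expression-tertile metagene profiles
#'
#' @param object An `mscc_tertiles` from [expression_tertile_profiles()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.mscc_tertiles <- function(object, ...) {
  df <- object$profiles |>
    mutate(tertile = factor(.data$tertile, 1:3,
                            c("low", "mid", "high")))
  ggplot(df, aes(x = .data$position, y = .data$smoothed,
                 colour = .data$tertile)) +
    geom_line(linewidth = 0.8, na.rm = TRUE) +
    geom_vline(xintercept = c(0, 1), linetype = "dashed", colour = "grey50") +
    scale_colour_brewer(palette = "Dark2") +
    labs(x = "position relative to gene (TSS = 0, TES = 1)",
         y = "smoothed mean methylation", colour = "expression") +
    theme_minimal()
}
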