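#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_errorbar
#'   geom_tile labs facet_grid scale_fill_brewer theme_minimal
#' @export
ggplot2::autoplot

#' Plot binned 4C interaction signal
#'
#' @param object a `fourc_tag_table`.
#' @param bin_size bp per bin (default 2000, as displayed in the source
#'   figures).
#' @param ... unused.
#' @return a ggplot of rpm per bin across the reference.
#' @export
autoplot.fourc_tag_table <- function(object, bin_size = 2000L, ...) {
  b <- bin_tags(object, bin_size)
  ggplot(b, aes(x = .data$bin_start / 1000, y = .data$rpm)) +
    geom_col(width = bin_size / 1000, fill = "grey30") +
    labs(x = "position (kb)", y = "4C tags (rpm)") +
    theme_minimal()
}

#' Plot a 5'-collapsed small-RNA profile
#'
#' Stacked bars of mean rpm per bin, colored by read length, with plus-strand
#' signal above and minus-strand signal below the axis.
#'
#' @param profile output of [collapse_5prime_profile()].
#' @return a ggplot.
#' @export
plot_srna_profile <- function(profile) {
  d <- profile |>
    mutate(rpm_signed = ifelse(.data$strand == "+", .data$rpm, -.data$rpm),
           length = factor(.data$length))
  ggplot(d, aes(x = .data$bin_start, y = .data$rpm_signed,
                fill = .data$length)) +
    geom_col() +
    labs(x = "position (bp)", y = "mean rpm (+ above / - below)",
         fill = "length (nt)") +
    theme_minimal()
}

#' Lollipop-style methylation plot
#'
#' Clone-by-cytosine grid colored by context, filled when methylated.
#'
#' @param object a `methylation_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.methylation_profile <- function(object, ...) {
  d <- object$calls |> filter(!is.na(.data$context))
  ggplot(d, aes(x = .data$position, y = .data$clone,
                color = .data$context,
                shape = .data$call)) +
    geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(methylated = 16,
                                           unmethylated = 1,
                                           ambiguous = 4)) +
    labs(x = "position (bp, interval-relative)", y = NULL) +
    theme_minimal()
}

#' Mean-fold bar plot for ddCt results
#'
#' @param object a `fold_change_result` or the tibble from
#'   [mnase_enrichment()].
#' @param ... unused.
#' @return a ggplot of mean fold with s.e.m. error bars per group.
#' @export
autoplot.fold_change_result <- function(object, ...) {
  ggplot(object$groups, aes(x = .data$group, y = .data$mean_fold)) +
    geom_col(fill = "grey40", width = 0.6) +
    geom_errorbar(aes(ymin = .data$mean_fold - .data$sem,
                      ymax = .data$mean_fold + .data$sem), width = 0.2) +
    labs(x = NULL, y = "mean fold (2^-ddCt)") +
    theme_minimal()
}
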