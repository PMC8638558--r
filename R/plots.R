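#' Plot a reactivity profile
#'
#' Per-nucleotide SHAPE reactivity for one transcript, with the
#' conventional low/medium/high bands at 0.3 and 0.6.
#'
#' @param reactivity Reactivity tibble (`transcript_id`, `position`,
#'   `reactivity`).
#' @param transcript_id Which transcript to show.
#' @return A ggplot object.
#' @export
plot_reactivity <- function(reactivity, transcript_id) {
  df <- reactivity[reactivity$transcript_id == transcript_id, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$reactivity)) +
    ggplot2::geom_hline(yintercept = c(0.3, 0.6), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_col(width = 1, fill = "#b2182b", na.rm = TRUE) +
    ggplot2::labs(x = "position (nt)", y = "SHAPE reactivity",
                  title = transcript_id) +
    ggplot2::theme_minimal()
}

#' Plot metagene reactivity profiles by TE decile
#'
#' @param profile Output of [metagene_profile()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(profile) {
  breaks <- cumsum(rle(profile$region[profile$group ==
                                        profile$group[1]])$lengths)
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin,
                                        y = .data$reactivity,
                                        colour = .data$group)) +
    ggplot2::geom_vline(xintercept = head(breaks, -1) + 0.5,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "scaled position (5'UTR | CDS | 3'UTR)",
                  y = "mean SHAPE reactivity", colour = "TE decile") +
    ggplot2::theme_minimal()
}

#' Scatter plot of structural vs translational asymmetry
#'
#' @param deltas Tibble with `dbpp` and `dte` columns (see
#'   [pair_deltas()]).
#' @return A ggplot object.
#' @export
plot_delta_correlation <- function(deltas) {
  df <- dplyr::mutate(deltas, adbpp = abs(.data$dbpp),
                      adte = abs(.data$dte))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$adbpp, y = .data$adte)) +
    ggplot2::geom_point(alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#2166ac", na.rm = TRUE) +
    ggplot2::labs(x = "|Δ mean BPP|", y = "|Δ log2 TE|") +
    ggplot2::theme_minimal()
}

#' Base-pairing probability profile of a fold
#'
#' @param object A `ribo_fold` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ribo_fold <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bpp)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (nt)", y = "base-pairing probability",
                  title = object$transcript_id) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
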