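#' Replicate-concordance plot of competition indices
#'
#' Scatter of replicate-1 vs replicate-2 CI on log10 axes, one panel per
#' treatment, colored by classification, with the classification cutoffs
#' drawn as reference lines. Genes excluded by the filters are omitted.
#'
#' @param object A `tn_ci` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tn_ci
#' @export
autoplot.tn_ci <- function(object, ...) {
  dat <- dplyr::filter(object$records, !is.na(.data$ci_rep1),
                       !is.na(.data$ci_rep2))
  cuts <- c(object$params$ci_low, object$params$ci_high)
  ggplot2::ggplot(dat, ggplot2::aes(.data$ci_rep1, .data$ci_rep2,
                                    colour = .data$classification)) +
    ggplot2::geom_hline(yintercept = cuts, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_vline(xintercept = cuts, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$treatment)) +
    ggplot2::scale_colour_manual(values = c(
      REDUCED_COMPETITIVENESS = "#D55E00",
      INCREASED_COMPETITIVENESS = "#0072B2",
      NO_CHANGE = "grey40"
    )) +
    ggplot2::labs(x = "CI, replicate 1", y = "CI, replicate 2",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Insertion-density track along a replicon
#'
#' Read counts per insertion site (strands summed per position), as a
#' ggplot, for quick visual QC of library coverage.
#'
#' @param profile A `tn_profile`.
#' @param replicon_id Replicon to plot (default: first present).
#' @param binwidth Sum counts in windows of this many bp (default 1000).
#' @return A ggplot.
#' @export
plot_insertion_density <- function(profile, replicon_id = NULL,
                                   binwidth = 1000) {
  sites <- profile$sites
  rid <- replicon_id %||% sites$replicon_id[1]
  dat <- sites %>%
    filter(.data$replicon_id == rid) %>%
    mutate(bin = binwidth * (.data$position %/% binwidth)) %>%
    group_by(.data$bin) %>%
    summarise(reads = sum(.data$count), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(.data$bin / 1000, .data$reads)) +
    ggplot2::geom_col(width = binwidth / 1000, fill = "#0072B2") +
    ggplot2::labs(x = paste0(rid, " position (kb)"),
                  y = paste0("reads per ", binwidth, " bp"),
                  title = profile$sample_id) +
    ggplot2::theme_bw()
}
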