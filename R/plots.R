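#' Plot window coverage for one or more samples
#'
#' Draws per-window read counts along the genome, faceted by chromosome,
#' one colour per sample: the visual used to spot multi-exon deletions and
#' chrX copy number at a glance.
#'
#' @param coverage A coverage tibble, or a list of them (rows are bound).
#' @param chrom Optional chromosome to restrict to.
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage, chrom = NULL) {
  if (is.list(coverage) && !is.data.frame(coverage)) {
    coverage <- list_rbind(map(coverage, as_tibble))
  }
  if (!is.null(chrom)) coverage <- coverage[coverage$chrom == chrom, ]
  ggplot2::ggplot(coverage,
                  ggplot2::aes(x = .data$start, y = .data$count,
                               colour = .data$sample)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "window start (bp)", y = "reads per window",
                  colour = "sample") +
    ggplot2::theme_minimal()
}

#' @rdname plot_coverage
#' @param object A `deletion_calls` object.
#' @param ... Passed on.
#' @exportS3Method ggplot2::autoplot
autoplot.deletion_calls <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$bp_upstream_start,
                                    xmax = .data$bp_downstream_end,
                                    ymin = 0, ymax = 1),
                       fill = "grey85") +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$core_start,
                                    xmax = .data$core_end,
                                    ymin = 0, ymax = 1),
                       fill = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "Deletion calls (core red, breakpoint grey)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_ranking
#' @param object A `ranked_candidates` object.
#' @param ... Passed on to `plot_ranking()`.
#' @exportS3Method ggplot2::autoplot
autoplot.ranked_candidates <- function(object, ...) {
  plot_ranking(object, ...)
}

#' Plot a patient's candidate ranking
#'
#' Scores of the top candidates in the primary list, coloured by
#' inheritance compatibility.
#'
#' @param ranked A [rank_patient()] result.
#' @param top_n Candidates shown (default 15).
#' @return A ggplot object.
#' @export
plot_ranking <- function(ranked, top_n = 15) {
  d <- ranked |>
    filter(.data$list == "primary") |>
    arrange(.data$level, .data$rank) |>
    group_by(.data$level) |>
    slice_head(n = top_n) |>
    ungroup() |>
    mutate(label = paste0(.data$gene, " (", .data$effect_category, ")"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score,
                                  y = stats::reorder(.data$label,
                                                     .data$score),
                                  fill = .data$inheritance_compatible)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$level), scales = "free_y") +
    ggplot2::labs(x = "score", y = NULL, fill = "inheritance\ncompatible") +
    ggplot2::theme_minimal()
}
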