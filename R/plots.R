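# ggplot2 views of design results.

#' Plot per-gene guide coverage of a targetability report
#'
#' Histogram of retained guides per gene; genes without any guide under the
#' report's rule appear in the zero bin.
#'
#' @param object A `targetability_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot targetability_report
#' @export
autoplot.targetability_report <- function(object, ...) {
  counts <- tibble::tibble(n_guides = c(object$per_gene$n_guides,
                                        rep(0L, object$n_genes - object$n_targetable)))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$n_guides)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = -0.5,
                            fill = "steelblue", colour = "grey30") +
    ggplot2::labs(x = "retained guides per gene", y = "genes",
                  title = sprintf("Targetable genes: %d of %d (rule: %s)",
                                  object$n_targetable, object$n_genes,
                                  object$params$rule)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map guides along a contig
#'
#' Gene bodies as grey bars, guides as points at their protospacer midpoint,
#' coloured by strand class.
#'
#' @param guides Annotated guide tibble.
#' @param features Gene feature tibble.
#' @param seqid Contig to draw (default: first in `guides`).
#' @return A ggplot.
#' @export
plot_guide_map <- function(guides, features, seqid = NULL) {
  seqid <- seqid %||% guides$seqid[1]
  g <- dplyr::filter(guides, .data$seqid == !!seqid)
  f <- dplyr::filter(features, .data$seqid == !!seqid)
  mid <- (g$spacer_start + g$spacer_end) / 2
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = f,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = -0.2, ymax = 0.2),
                       fill = "grey80", colour = "grey50") +
    ggplot2::geom_point(data = dplyr::mutate(g, mid = mid),
                        ggplot2::aes(x = .data$mid,
                                     y = ifelse(.data$strand == "+", 0.5, -0.5),
                                     colour = .data$strand_class),
                        shape = 17, size = 2) +
    ggplot2::labs(x = sprintf("position on %s (bp)", seqid), y = NULL,
                  colour = "strand class") +
    ggplot2::scale_y_continuous(breaks = c(-0.5, 0, 0.5),
                                labels = c("- guides", "genes", "+ guides"),
                                limits = c(-1, 1)) +
    ggplot2::theme_minimal()
}
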