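# ggplot2 views of the result objects. These are convenience plots for
# interactive use; publication graphics are out of scope.

#' Plot Venn region sizes
#'
#' Bar chart of the exclusive Venn regions of a [venn_regions()] result,
#' central overlap highlighted.
#'
#' @param object A `regensig_overlap` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot regensig_overlap
#' @export
autoplot.regensig_overlap <- function(object, ...) {
  d <- object$regions |>
    dplyr::mutate(
      region = factor(.data$region, levels = rev(.data$region)),
      central = .data$region == "central"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$region, fill = .data$central)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "#b2182b")) +
    ggplot2::labs(
      x = "genes in region", y = NULL,
      title = sprintf("Signature overlap (k = %d lists)", object$k),
      subtitle = if (!is.null(object$null)) {
        sprintf("central = %d, expected = %.3g, permutation p = %.3g",
                length(object$central), object$null$expected, object$null$p_value)
      }
    ) +
    ggplot2::theme_minimal()
}

#' Plot term enrichment
#'
#' Dot plot of the most enriched terms: -log10 raw p against term, point size
#' the overlap count `a`.
#'
#' @param object A `regensig_enrichment` object.
#' @param n_terms Number of top terms to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot regensig_enrichment
#' @export
autoplot.regensig_enrichment <- function(object, n_terms = 15, ...) {
  d <- utils::head(tidy(object), n_terms) |>
    dplyr::mutate(term_name = factor(.data$term_name, levels = rev(.data$term_name)))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_value), y = .data$term_name,
                                  size = .data$a)) +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL, size = "genes in list",
                  title = "Fisher term enrichment") +
    ggplot2::theme_minimal()
}

#' Plot an aggregate ranking profile
#'
#' Mean rank against aggregate position; a vertical cut marks `n_top` when
#' given. A planted or otherwise highlighted gene set can be overlaid.
#'
#' @param object A `regensig_aggregate` object.
#' @param n_top Optional signature cut to mark.
#' @param highlight Optional character vector of gene symbols to colour.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot regensig_aggregate
#' @export
autoplot.regensig_aggregate <- function(object, n_top = NULL, highlight = NULL, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(position = dplyr::row_number(),
                  highlighted = .data$gene_symbol %in% (highlight %||% character()))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$mean_rank)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlighted),
                        size = 0.8, show.legend = !is.null(highlight)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "#b2182b"),
                                 name = "highlighted") +
    ggplot2::labs(x = "aggregate position", y = "mean rank across experiments",
                  title = "Cross-experiment rank aggregation") +
    ggplot2::theme_minimal()
  if (!is.null(n_top)) {
    p <- p + ggplot2::geom_vline(xintercept = n_top + 0.5, linetype = "dashed")
  }
  p
}
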