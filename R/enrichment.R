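#' Fisher's exact term enrichment of a signature list
#'
#' For each term, membership is first restricted to the universe, then the
#' 2x2 table is formed: `a` = list genes in the term, `b` = list genes not in
#' the term, `c` = term genes outside the list, `d` = the rest of the
#' universe (a + b + c + d = U). The one-sided over-representation p-value is
#' the upper hypergeometric tail P(X >= a); Benjamini-Hochberg and Bonferroni
#' adjustments are computed across all tested terms. Terms with no member in
#' the universe are skipped and logged in the `skipped` attribute.
#'
#' The reported `odds_ratio` is the sample cross-product estimate
#' `(a * d) / (b * c)` (`Inf` when `b * c = 0`), not the conditional maximum
#' likelihood estimate.
#'
#' @param signature Signature list (tibble or character vector) — a subset of
#'   the universe.
#' @param terms Term database: long tibble `term_id`, `term_name`,
#'   `gene_symbol` (as returned by [read_term_gmt()]).
#' @param universe The background gene set ([build_common_universe()] object
#'   or character vector). The default background is the common universe; to
#'   use a different background pass it here explicitly.
#' @param adjustment `"both"` (default), `"BH"`, or `"bonferroni"` — which
#'   adjusted columns to keep.
#' @param alternative `"greater"` (one-sided over-representation, default) or
#'   `"two.sided"` (via [stats::fisher.test()]).
#' @return Tibble of class `regensig_enrichment`, one row per tested term,
#'   sorted by raw p: `term_id`, `term_name`, `n_term`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_value`, and the requested `p_bh` / `p_bonferroni`.
#' @export
#' @examples
#' fisher_enrichment(
#'   c("g1", "g2"),
#'   tibble::tibble(term_id = "t1", term_name = "pair",
#'                  gene_symbol = c("g1", "g2")),
#'   universe = c("g1", "g2", "g3", "g4")
#' )
fisher_enrichment <- function(signature, terms, universe,
                              adjustment = c("both", "BH", "bonferroni"),
                              alternative = c("greater", "two.sided")) {
  adjustment <- match.arg(adjustment)
  alternative <- match.arg(alternative)
  genes <- unique(sig_genes(signature))
  ug <- universe_genes(universe)
  U <- length(ug)
  outside <- setdiff(genes, ug)
  if (length(outside)) {
    abort_input(sprintf("signature gene(s) outside the universe: %s",
                        paste(head(sort(outside), 5), collapse = ", ")))
  }
  if (!is.data.frame(terms) || !all(c("term_id", "gene_symbol") %in% names(terms))) {
    abort_input("`terms` must be a long data frame with term_id and gene_symbol")
  }
  if (!"term_name" %in% names(terms)) terms$term_name <- terms$term_id
  restricted <- terms |>
    dplyr::distinct(.data$term_id, .data$term_name, .data$gene_symbol) |>
    dplyr::filter(.data$gene_symbol %in% ug)
  skipped <- setdiff(unique(terms$term_id), unique(restricted$term_id))
  if (length(skipped)) {
    rlang::inform(sprintf(
      "%d term(s) skipped: no members in the universe (%s)",
      length(skipped), paste(head(skipped, 5), collapse = ", ")
    ))
  }
  if (nrow(restricted) == 0L) {
    abort_input("no term has any member in the universe")
  }
  n_list <- length(genes)
  res <- restricted |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(
      n_term = dplyr::n(),
      a = sum(.data$gene_symbol %in% genes),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      b = n_list - .data$a,
      c = .data$n_term - .data$a,
      d = U - n_list - .data$c,
      odds_ratio = (.data$a * .data$d) / (.data$b * .data$c),
      p_value = if (alternative == "greater") {
        phyper(.data$a - 1, .data$n_term, U - .data$n_term, n_list,
               lower.tail = FALSE)
      } else {
        purrr::pmap_dbl(list(.data$a, .data$b, .data$c, .data$d), function(a, b, c, d) {
          stats::fisher.test(matrix(c(a, b, c, d), 2), alternative = "two.sided")$p.value
        })
      }
    )
  res$p_bh <- p.adjust(res$p_value, method = "BH")
  res$p_bonferroni <- p.adjust(res$p_value, method = "bonferroni")
  if (adjustment == "BH") res$p_bonferroni <- NULL
  if (adjustment == "bonferroni") res$p_bh <- NULL
  res <- dplyr::arrange(res, .data$p_value, .data$term_id)
  attr(res, "skipped") <- skipped
  attr(res, "universe_size") <- U
  attr(res, "list_size") <- n_list
  class(res) <- c("regensig_enrichment", class(res))
  res
}
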