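# broom-style accessors for the package's result objects.

#' Tidy a Venn overlap result
#'
#' @param x A `regensig_overlap` object.
#' @param ... Unused.
#' @return One row per Venn region: `region`, `pattern` (membership bits in
#'   list order), `n`, `genes` (list-column).
#' @method tidy regensig_overlap
#' @export
tidy.regensig_overlap <- function(x, ...) {
  x$regions
}

#' One-row summary of a Venn overlap result
#'
#' @param x A `regensig_overlap` object.
#' @param ... Unused.
#' @return Tibble with `k`, the list sizes, `central_n`, and — when the
#'   permutation null has been run — `expected` and `p_value`.
#' @method glance regensig_overlap
#' @export
glance.regensig_overlap <- function(x, ...) {
  out <- tibble::tibble(
    k = x$k,
    list_sizes = paste(x$list_sizes, collapse = ","),
    central_n = length(x$central),
    universe_size = x$universe_size
  )
  if (!is.null(x$null)) {
    out$expected <- x$null$expected
    out$p_value <- x$null$p_value
    out$n_perm <- x$null$n_perm
  }
  out
}

#' Tidy an enrichment result
#'
#' @param x A `regensig_enrichment` object.
#' @param ... Unused.
#' @return The underlying per-term tibble, sorted by raw p.
#' @method tidy regensig_enrichment
#' @export
tidy.regensig_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "regensig_enrichment")
  out
}

#' One-row summary of an enrichment result
#'
#' @param x A `regensig_enrichment` object.
#' @param alpha Significance threshold applied to the adjusted p-values.
#' @param ... Unused.
#' @return Tibble with the number of tested and skipped terms, the list and
#'   universe sizes, and the count of terms significant at `alpha` after each
#'   available adjustment.
#' @method glance regensig_enrichment
#' @export
glance.regensig_enrichment <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_terms = nrow(x),
    n_skipped = length(attr(x, "skipped")),
    list_size = attr(x, "list_size"),
    universe_size = attr(x, "universe_size"),
    n_sig_bh = if ("p_bh" %in% names(x)) sum(x$p_bh <= alpha) else NA_integer_,
    n_sig_bonferroni = if ("p_bonferroni" %in% names(x)) {
      sum(x$p_bonferroni <= alpha)
    } else {
      NA_integer_
    }
  )
}

#' One-row summary of a pipeline run
#'
#' @param x A `regensig_result` object.
#' @param ... Unused.
#' @return Tibble with the universe size, experiment count, `n_top`, mode,
#'   central overlap size, its expectation and permutation p-value, the top
#'   enriched term (when enrichment ran) and planted-signature recall /
#'   precision (synthetic runs).
#' @method glance regensig_result
#' @export
glance.regensig_result <- function(x, ...) {
  tibble::tibble(
    universe_size = x$universe$U,
    n_experiments = length(x$signatures),
    n_top = x$config$n_top,
    mode = x$config$mode,
    central_n = length(x$central),
    expected_overlap = if (!is.null(x$overlap$null)) x$overlap$null$expected else NA_real_,
    overlap_p = if (!is.null(x$overlap$null)) x$overlap$null$p_value else NA_real_,
    top_term = if (!is.null(x$enrichment) && nrow(x$enrichment)) {
      x$enrichment$term_id[1]
    } else {
      NA_character_
    },
    recall = if (!is.null(x$recovery)) x$recovery$recall else NA_real_,
    precision = if (!is.null(x$recovery)) x$recovery$precision else NA_real_,
    config_hash = x$config_hash
  )
}

#' Tidy a pipeline run into its long per-gene rank table
#'
#' @param x A `regensig_result` object.
#' @param ... Unused.
#' @return The long tibble of per-experiment ranks joined with the aggregate
#'   mean rank: `experiment_id`, `gene_symbol`, `log2fc`, `n_probes`, `rank`,
#'   `mean_rank`.
#' @method tidy regensig_result
#' @export
tidy.regensig_result <- function(x, ...) {
  dplyr::left_join(x$ranks, tibble::as_tibble(x$aggregate)[, c("gene_symbol", "mean_rank")],
                   by = "gene_symbol")
}
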