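#' Floored log2 fold change
#'
#' The per-probe statistic: log2 of the high-regeneration group mean over the
#' low-regeneration group mean, with both means floored at a small positive
#' intensity so the ratio is always finite.
#'
#' @param mean_high,mean_low Non-negative group mean intensities (vectorized).
#' @param floor Positive intensity floor applied to both means.
#' @return `log2(max(mean_high, floor) / max(mean_low, floor))`.
#' @export
#' @examples
#' log2_fold_change(8, 2, floor = 0.5) # 2
#' log2_fold_change(0, 4, floor = 1) # -2
log2_fold_change <- function(mean_high, mean_low, floor) {
  if (!is_number(floor) || floor <= 0) abort_input("`floor` must be a positive number")
  if (any(!is.finite(mean_high)) || any(!is.finite(mean_low))) {
    abort_input("group means must be finite")
  }
  if (any(mean_high < 0) || any(mean_low < 0)) {
    abort_input("intensities must be non-negative")
  }
  log2(pmax(mean_high, floor) / pmax(mean_low, floor))
}

#' Collapse probe-level fold changes to one value per gene
#'
#' Microarray platforms carry several probe sets per gene; ranking requires
#' exactly one value per gene. The default collapse is the median of the
#' probe log2 fold changes (robust to a single discordant probe); `mean` and
#' `max_abs` (the probe with the largest absolute fold change, sign kept) are
#' available for sensitivity analysis.
#'
#' @param probe_fc Tibble with columns `gene_symbol` and `log2fc` (one row per
#'   probe), optionally `experiment_id`.
#' @param method One of `"median"`, `"mean"`, `"max_abs"`.
#' @return Tibble with one row per gene: `gene_symbol`, `log2fc`, `n_probes`
#'   (plus `experiment_id` if present in the input).
#' @export
#' @examples
#' collapse_probes(tibble::tibble(
#'   gene_symbol = c("A", "A", "A"), log2fc = c(1, 2, 10)
#' )) # median 2
collapse_probes <- function(probe_fc, method = c("median", "mean", "max_abs")) {
  method <- match.arg(method)
  if (!is.data.frame(probe_fc) || nrow(probe_fc) == 0L) {
    abort_input("`probe_fc` must be a non-empty data frame")
  }
  if (!all(c("gene_symbol", "log2fc") %in% names(probe_fc))) {
    abort_input("`probe_fc` needs columns gene_symbol and log2fc")
  }
  keys0 <- intersect(c("experiment_id", "gene_symbol"), names(probe_fc))
  if (!anyDuplicated(probe_fc[keys0])) {
    out <- tibble::as_tibble(probe_fc[, c(keys0, "log2fc")])
    out$n_probes <- 1L
    return(out)
  }
  fun <- switch(method,
    median = stats::median,
    mean = mean,
    max_abs = function(x) x[which.max(abs(x))]
  )
  keys <- intersect(c("experiment_id", "gene_symbol"), names(probe_fc))
  probe_fc |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      log2fc = fun(.data$log2fc),
      n_probes = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-gene fold-change table for one experiment
#'
#' Computes the probe-level log2 fold change of high- over low-regeneration
#' group means (or uses the precomputed `log2fc` column when the experiment
#' carries one), then collapses probes to genes.
#'
#' @param experiment A [expression_experiment()], already mapped to the human
#'   gene space for mouse data.
#' @param floor Intensity floor for [log2_fold_change()]; default `NULL` uses
#'   the smallest positive intensity observed in the experiment, so no
#'   constant has to be chosen per platform.
#' @param collapse Probe-collapse method, see [collapse_probes()].
#' @return Tibble `experiment_id`, `gene_symbol`, `log2fc`, `n_probes`.
#' @export
fold_change_table <- function(experiment, floor = NULL,
                              collapse = c("median", "mean", "max_abs")) {
  stopifnot(inherits(experiment, "regensig_experiment"))
  collapse <- match.arg(collapse)
  if (experiment$has_fc) {
    probe_fc <- tibble::tibble(
      experiment_id = experiment$experiment_id,
      gene_symbol = experiment$data$gene_symbol,
      log2fc = experiment$data$log2fc
    )
  } else {
    hi <- experiment$design$sample[experiment$design$group == "high_regeneration"]
    lo <- experiment$design$sample[experiment$design$group == "low_regeneration"]
    m <- as.matrix(experiment$data[, c(hi, lo), drop = FALSE])
    if (is.null(floor)) {
      pos <- m[m > 0]
      if (length(pos) == 0L) abort_input("all intensities are zero; supply `floor`")
      floor <- min(pos)
    }
    probe_fc <- tibble::tibble(
      experiment_id = experiment$experiment_id,
      gene_symbol = experiment$data$gene_symbol,
      log2fc = log2_fold_change(
        rowMeans(m[, hi, drop = FALSE]),
        rowMeans(m[, lo, drop = FALSE]),
        floor = floor
      )
    )
  }
  collapse_probes(probe_fc, method = collapse)
}

#' Rank genes by descending fold change within one experiment
#'
#' Rank 1 is the gene with the largest log2 fold change; ties receive the
#' average of the tied positions, so every rank table sums to U(U+1)/2
#' exactly. Restrict the table to the common universe before ranking.
#'
#' @param fc Tibble with one row per universe gene: `gene_symbol`, `log2fc`
#'   (and optionally `experiment_id`, `n_probes`).
#' @return The input with a `rank` column, sorted by ascending rank.
#' @export
#' @examples
#' rank_by_fc(tibble::tibble(gene_symbol = c("A", "B", "C"), log2fc = c(3, 2, 1)))
rank_by_fc <- function(fc) {
  if (!is.data.frame(fc) || !all(c("gene_symbol", "log2fc") %in% names(fc))) {
    abort_input("`fc` needs columns gene_symbol and log2fc")
  }
  if (anyDuplicated(fc$gene_symbol)) {
    abort_input("`fc` must have exactly one row per gene; collapse probes first")
  }
  if (any(!is.finite(fc$log2fc))) abort_input("non-finite log2fc")
  fc |>
    dplyr::mutate(rank = rank(-.data$log2fc, ties.method = "average")) |>
    dplyr::arrange(.data$rank, .data$gene_symbol)
}

#' Average per-experiment ranks across experiments
#'
#' The cross-experiment statistic: each universe gene's mean rank over the k
#' experiments, sorted ascending (mean rank 1 = top of every list). All rank
#' tables must cover the identical universe; the result is invariant under
#' permutation of the experiment list.
#'
#' @param rank_tables A list of [rank_by_fc()] outputs, or one long tibble
#'   with columns `experiment_id`, `gene_symbol`, `rank`.
#' @return A tibble of class `regensig_aggregate`: `gene_symbol`, `mean_rank`,
#'   `k`, sorted by ascending `mean_rank` then symbol.
#' @export
aggregate_ranks <- function(rank_tables) {
  long <- if (is.data.frame(rank_tables)) {
    tibble::as_tibble(rank_tables)
  } else {
    if (length(rank_tables) == 0L) abort_input("no rank tables supplied")
    dplyr::bind_rows(purrr::imap(rank_tables, function(t, i) {
      if (!"experiment_id" %in% names(t)) {
        t$experiment_id <- if (is.character(i)) i else paste0("experiment_", i)
      }
      t
    }))
  }
  if (!all(c("experiment_id", "gene_symbol", "rank") %in% names(long))) {
    abort_input("rank tables need columns experiment_id, gene_symbol, rank")
  }
  sets <- split(long$gene_symbol, long$experiment_id)
  ref <- sort(sets[[1]])
  for (id in names(sets)) {
    diff <- c(setdiff(sets[[id]], ref), setdiff(ref, sets[[id]]))
    if (length(diff)) {
      abort_input(sprintf(
        "rank tables disagree on the universe; experiment \"%s\" differs on: %s",
        id, paste(sort(unique(diff)), collapse = ", ")
      ))
    }
  }
  out <- long |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(mean_rank = mean(.data$rank), k = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$mean_rank, .data$gene_symbol)
  class(out) <- c("regensig_aggregate", class(out))
  out
}

#' Extract the top-N signature from a ranking
#'
#' Takes the first `min(n_top, U)` genes by ascending rank. Exact ties are
#' broken by lexicographic gene symbol, deterministically; when a tie crosses
#' the N boundary the event is recorded in the returned attributes so the cut
#' is auditable.
#'
#' @param ranking A [aggregate_ranks()] result, or any tibble with
#'   `gene_symbol` and a `mean_rank` or `rank` column (so a single
#'   experiment's rank table works directly in per-dataset mode).
#' @param n_top Number of genes to keep (>= 0).
#' @return Tibble of class `regensig_signature` with columns `position`,
#'   `gene_symbol`, and the rank column used; attributes `n_top`,
#'   `tie_break` (note, or `NA` when no boundary tie occurred).
#' @export
top_n_signature <- function(ranking, n_top) {
  if (!is_count(n_top)) abort_input("`n_top` must be a non-negative integer")
  if (!is.data.frame(ranking) || !"gene_symbol" %in% names(ranking)) {
    abort_input("`ranking` must be a data frame with gene_symbol")
  }
  rank_col <- intersect(c("mean_rank", "rank"), names(ranking))[1]
  if (is.na(rank_col)) abort_input("`ranking` needs a mean_rank or rank column")
  ord <- ranking |>
    dplyr::arrange(.data[[rank_col]], .data$gene_symbol)
  n <- min(n_top, nrow(ord))
  tie_break <- NA_character_
  if (n > 0L && sum(ord[[rank_col]] == ord[[rank_col]][n]) > 1L) {
    crosses <- n < nrow(ord) && ord[[rank_col]][n] == ord[[rank_col]][n + 1L]
    tie_break <- sprintf(
      "tie at %s = %.6g %s the n_top = %d boundary; broken lexicographically",
      rank_col, ord[[rank_col]][n],
      if (crosses) "crosses" else "touches", n_top
    )
  }
  out <- ord[seq_len(n), c("gene_symbol", rank_col), drop = FALSE]
  out <- dplyr::mutate(out, position = dplyr::row_number(), .before = 1)
  attr(out, "n_top") <- as.integer(n_top)
  attr(out, "tie_break") <- tie_break
  class(out) <- c("regensig_signature", class(out))
  out
}
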