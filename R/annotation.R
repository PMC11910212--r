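#' Build or read a gene-alias table
#'
#' Alias tables update outdated gene symbols to current nomenclature
#' (HUGO for human, MGI for mouse). Canonical symbols are fixed points:
#' a symbol that is itself canonical must never appear in `alias_symbol`
#' mapped to something else.
#'
#' @param x Data frame with columns `alias_symbol`, `canonical_symbol`,
#'   `species`, or a file path to a tab/comma-delimited table with those
#'   columns.
#' @return A tibble with the three columns, duplicates collapsed.
#' @export
#' @examples
#' alias_table(tibble::tibble(
#'   alias_symbol = "Il1f6", canonical_symbol = "Il36a", species = "mouse"
#' ))
alias_table <- function(x) {
  tbl <- if (is.character(x) && length(x) == 1L) read_delim_auto(x) else tibble::as_tibble(x)
  need <- c("alias_symbol", "canonical_symbol", "species")
  if (!all(need %in% names(tbl))) {
    abort_parse(sprintf("alias table must have columns: %s", paste(need, collapse = ", ")))
  }
  tbl <- dplyr::distinct(tbl[, need])
  if (any(tbl$alias_symbol == "" | tbl$canonical_symbol == "" |
          is.na(tbl$alias_symbol) | is.na(tbl$canonical_symbol))) {
    abort_parse("alias table contains empty symbols")
  }
  # fixed-point check: no canonical symbol may be re-aliased within a species
  clash <- dplyr::inner_join(
    tbl, tbl,
    by = c("alias_symbol" = "canonical_symbol", "species" = "species"),
    suffix = c("", ".y")
  )
  clash <- clash[clash$alias_symbol != clash$canonical_symbol, , drop = FALSE]
  if (nrow(clash)) {
    abort_parse(sprintf(
      "alias table is not canonical: %s is both an alias and a canonical symbol",
      clash$alias_symbol[1]
    ))
  }
  tbl
}

#' Build or read a mouse-to-human ortholog map
#'
#' @param x Data frame with columns `mouse_symbol`, `human_symbol` and
#'   optionally `source_db` (one of `HomoloGene`, `HCOP`, `fixture`), or a
#'   path to a delimited file. Duplicate pairs are collapsed on load.
#' @return A tibble `mouse_symbol`, `human_symbol`, `source_db`.
#' @export
ortholog_map <- function(x) {
  tbl <- if (is.character(x) && length(x) == 1L) read_delim_auto(x) else tibble::as_tibble(x)
  if (!all(c("mouse_symbol", "human_symbol") %in% names(tbl))) {
    abort_parse("ortholog map must have columns mouse_symbol, human_symbol")
  }
  if (!"source_db" %in% names(tbl)) tbl$source_db <- "fixture"
  tbl <- tbl[, c("mouse_symbol", "human_symbol", "source_db")]
  if (any(tbl$mouse_symbol == "" | tbl$human_symbol == "" |
          is.na(tbl$mouse_symbol) | is.na(tbl$human_symbol))) {
    abort_parse("ortholog map contains empty symbols")
  }
  dplyr::distinct(tbl, .data$mouse_symbol, .data$human_symbol, .keep_all = TRUE)
}

#' Canonicalize the gene symbols of an experiment
#'
#' Replaces every probe's gene symbol by its canonical form where the alias
#' table (restricted to the experiment's species) has a record; unknown
#' symbols pass through unchanged and are counted in the experiment log.
#' The operation is idempotent because canonical symbols are fixed points of
#' the alias table.
#'
#' @param experiment A [expression_experiment()].
#' @param aliases An [alias_table()].
#' @return The experiment with updated symbols and log fields
#'   `canonicalized` / `unmapped_alias`.
#' @export
canonicalize_symbols <- function(experiment, aliases) {
  stopifnot(inherits(experiment, "regensig_experiment"))
  aliases <- alias_table(aliases)
  species_aliases <- aliases[aliases$species == experiment$species, , drop = FALSE]
  lookup <- setNames(species_aliases$canonical_symbol, species_aliases$alias_symbol)
  hit <- experiment$data$gene_symbol %in% names(lookup)
  experiment$data$gene_symbol[hit] <-
    unname(lookup[experiment$data$gene_symbol[hit]])
  experiment$log$canonicalized <- sum(hit)
  experiment$log$unmapped_alias <- sum(!hit)
  experiment
}

#' Map a mouse experiment into human gene space
#'
#' Relabels each mouse probe with its human ortholog symbol. A mouse gene with
#' no ortholog record is dropped (and logged); when two mouse paralogs map to
#' one human symbol both probe sets are retained under that symbol, so the
#' later probe-to-gene collapse yields a single value per human gene. A mouse
#' gene with several human orthologs contributes its probes to each. Human
#' experiments pass through unchanged.
#'
#' @param experiment A [expression_experiment()].
#' @param orthologs An [ortholog_map()].
#' @return The experiment with `gene_space = "human"` and dropped mouse genes
#'   recorded in `log$dropped_no_ortholog`.
#' @export
map_to_human <- function(experiment, orthologs) {
  stopifnot(inherits(experiment, "regensig_experiment"))
  if (experiment$species == "human" || identical(experiment$gene_space, "human")) {
    experiment$gene_space <- "human"
    return(experiment)
  }
  orthologs <- ortholog_map(orthologs)
  mapped <- dplyr::inner_join(
    experiment$data, orthologs[, c("mouse_symbol", "human_symbol")],
    by = c(gene_symbol = "mouse_symbol"), relationship = "many-to-many"
  )
  dropped <- setdiff(experiment$data$gene_symbol, orthologs$mouse_symbol)
  if (nrow(mapped) == 0L) {
    abort_input(sprintf(
      "experiment \"%s\": no probe survived ortholog mapping", experiment$experiment_id
    ))
  }
  mapped$gene_symbol <- mapped$human_symbol
  mapped$human_symbol <- NULL
  experiment$data <- mapped
  experiment$gene_space <- "human"
  experiment$log$dropped_no_ortholog <- sort(dropped)
  experiment
}

#' Build the common gene universe shared by all experiments
#'
#' The universe is the intersection of the per-experiment gene sets after
#' ortholog mapping: the identical background on which every experiment is
#' ranked, intersected and enrichment-tested. Symbols are returned sorted so
#' the universe is invariant under reordering of the experiment list.
#'
#' @param gene_sets A named list; each element is a character vector of
#'   human-space gene symbols, or a data frame with a `gene_symbol` column
#'   (e.g. a fold-change table).
#' @return An object of class `regensig_universe`: list with `genes` (sorted
#'   character vector), `U`, and `dropped` — a tibble of per-experiment genes
#'   excluded by the intersection.
#' @export
#' @examples
#' u <- build_common_universe(list(e1 = c("A", "B", "C"), e2 = c("B", "C", "D")))
#' u$genes # "B" "C"
build_common_universe <- function(gene_sets) {
  if (!is.list(gene_sets) || length(gene_sets) == 0L) {
    abort_input("`gene_sets` must be a non-empty list")
  }
  sets <- purrr::map(gene_sets, function(x) {
    g <- if (is.data.frame(x)) {
      if (!"gene_symbol" %in% names(x)) abort_input("gene set data frames need `gene_symbol`")
      x$gene_symbol
    } else {
      as.character(x)
    }
    g <- unique(g[!is.na(g) & g != ""])
    if (length(g) == 0L) abort_input("an experiment contributed an empty gene set")
    g
  })
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("experiment_", seq_along(sets))
  }
  genes <- sort(Reduce(intersect, sets))
  if (length(genes) == 0L) {
    abort_input("common universe is empty: the experiments share no genes")
  }
  dropped <- purrr::imap(sets, function(g, id) {
    tibble::tibble(experiment_id = id, gene_symbol = sort(setdiff(g, genes)))
  })
  structure(
    list(genes = genes, U = length(genes), dropped = dplyr::bind_rows(dropped)),
    class = "regensig_universe"
  )
}

#' @export
print.regensig_universe <- function(x, ...) {
  cat(sprintf("<regensig_universe> %d genes; %d gene(s) dropped across experiments\n",
              x$U, nrow(x$dropped)))
  invisible(x)
}

universe_genes <- function(universe) {
  if (inherits(universe, "regensig_universe")) universe$genes
  else if (is.character(universe)) unique(universe)
  else if (is.data.frame(universe) && "gene_symbol" %in% names(universe)) {
    unique(universe$gene_symbol)
  } else {
    abort_input("`universe` must be a regensig_universe, character vector, or data frame with gene_symbol")
  }
}

#' Read a GMT term database
#'
#' GMT is the tab-delimited gene-set format: one term per line —
#' `term_id TAB description TAB gene TAB gene ...`.
#'
#' @param path Path to a `.gmt` file.
#' @return A long tibble `term_id`, `term_name`, `gene_symbol`.
#' @export
read_term_gmt <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- purrr::map(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) abort_parse(sprintf("GMT line with fewer than 3 fields: %s", l))
    tibble::tibble(term_id = f[1], term_name = f[2],
                   gene_symbol = unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  })
  out <- dplyr::bind_rows(rows)
  if (any(!nzchar(out$term_id))) abort_parse("GMT contains an empty term id")
  out
}

#' Write a term database to GMT
#'
#' @param terms Long tibble `term_id`, `term_name`, `gene_symbol`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_term_gmt <- function(terms, path) {
  lines <- terms |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(line = paste(.data$gene_symbol, collapse = "\t"), .groups = "drop") |>
    dplyr::arrange(.data$term_id)
  readr::write_lines(paste(lines$term_id, lines$term_name, lines$line, sep = "\t"), path)
  invisible(path)
}
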