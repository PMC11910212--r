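#' Construct a two-group expression experiment
#'
#' The unit of analysis: one platform/species dataset with a two-group
#' (high- vs low-regeneration) design at probe level. Either raw intensities
#' (one column per sample, non-negative) or a precomputed per-probe `log2fc`
#' column can be supplied; with raw intensities a design table mapping every
#' sample column to `high_regeneration` / `low_regeneration` is required.
#'
#' @param data Tibble with columns `probe_id`, `gene_symbol`, and either one
#'   numeric column per sample or a single `log2fc` column.
#' @param design Tibble with columns `sample`, `group`, one row per sample
#'   column of `data`; groups must be exactly `high_regeneration` and
#'   `low_regeneration`. Ignored (may be `NULL`) when `data` carries `log2fc`.
#' @param species `"mouse"` or `"human"`.
#' @param platform Free-text platform label.
#' @param experiment_id Experiment label, unique within a study.
#'
#' @return An object of class `regensig_experiment`: a list with fields
#'   `experiment_id`, `species`, `platform`, `data`, `design`, `has_fc`,
#'   `gene_space` (initially the native species) and a `log` of row drops.
#'   Rows with an empty `gene_symbol` are dropped and counted in `log`.
#' @export
#' @examples
#' ex <- expression_experiment(
#'   tibble::tibble(
#'     probe_id = c("p1", "p2"), gene_symbol = c("OAS1", "WNT7B"),
#'     s1 = c(4, 2), s2 = c(5, 2), s3 = c(1, 2), s4 = c(2, 2)
#'   ),
#'   design = tibble::tibble(
#'     sample = c("s1", "s2", "s3", "s4"),
#'     group = rep(c("high_regeneration", "low_regeneration"), each = 2)
#'   ),
#'   species = "human", platform = "demo", experiment_id = "e1"
#' )
expression_experiment <- function(data, design = NULL, species, platform = "unknown",
                                  experiment_id) {
  if (!is.data.frame(data)) abort_input("`data` must be a data frame")
  data <- tibble::as_tibble(data)
  if (!all(c("probe_id", "gene_symbol") %in% names(data))) {
    abort_parse("`data` must have `probe_id` and `gene_symbol` columns")
  }
  if (!species %in% c("mouse", "human")) {
    abort_input(sprintf("`species` must be \"mouse\" or \"human\", not \"%s\"", species))
  }

  data$probe_id <- as.character(data$probe_id)
  data$gene_symbol <- as.character(data$gene_symbol)
  empty <- is.na(data$gene_symbol) | data$gene_symbol == ""
  n_dropped <- sum(empty)
  data <- data[!empty, , drop = FALSE]
  if (nrow(data) == 0L) abort_input("experiment has no probes with a gene symbol")
  if (anyDuplicated(data$probe_id)) {
    abort_input(sprintf(
      "duplicate probe_id in experiment \"%s\": %s",
      experiment_id, paste(unique(data$probe_id[duplicated(data$probe_id)]), collapse = ", ")
    ))
  }

  has_fc <- "log2fc" %in% names(data)
  if (has_fc) {
    if (!is.numeric(data$log2fc) || !all(is.finite(data$log2fc))) {
      abort_parse("`log2fc` column must be finite numeric")
    }
    design <- NULL
  } else {
    if (is.null(design)) abort_input("`design` is required when `data` has no log2fc column")
    design <- tibble::as_tibble(design)
    if (!all(c("sample", "group") %in% names(design))) {
      abort_parse("design must have `sample` and `group` columns")
    }
    design$sample <- as.character(design$sample)
    design$group <- as.character(design$group)
    missing_samples <- setdiff(design$sample, names(data))
    if (length(missing_samples)) {
      abort_parse(sprintf(
        "design lists sample(s) absent from the expression table: %s",
        paste(missing_samples, collapse = ", ")
      ))
    }
    groups <- sort(unique(design$group))
    if (!identical(groups, c("high_regeneration", "low_regeneration"))) {
      abort_parse(sprintf(
        "design groups must be exactly {high_regeneration, low_regeneration}, got {%s}",
        paste(groups, collapse = ", ")
      ))
    }
    for (s in design$sample) {
      col <- data[[s]]
      if (!is.numeric(col)) abort_parse(sprintf("sample column \"%s\" is not numeric", s))
      if (!all(is.finite(col)) || any(col < 0)) {
        bad <- which(!is.finite(col) | col < 0)[1]
        abort_parse(sprintf(
          "sample column \"%s\" has a non-finite or negative intensity at row %d", s, bad
        ))
      }
    }
    data <- data[, c("probe_id", "gene_symbol", design$sample), drop = FALSE]
  }

  structure(
    list(
      experiment_id = as.character(experiment_id),
      species = species,
      platform = as.character(platform),
      data = data,
      design = design,
      has_fc = has_fc,
      gene_space = species,
      log = list(dropped_empty_symbol = n_dropped,
                 unmapped_alias = NA_integer_,
                 canonicalized = NA_integer_,
                 dropped_no_ortholog = character())
    ),
    class = "regensig_experiment"
  )
}

#' @export
print.regensig_experiment <- function(x, ...) {
  cat(sprintf(
    "<regensig_experiment> %s: %s (%s), %d probes, %d genes, %s\n",
    x$experiment_id, x$species, x$platform, nrow(x$data),
    dplyr::n_distinct(x$data$gene_symbol),
    if (x$has_fc) "precomputed log2fc" else
      sprintf("%d samples (%d high / %d low)", nrow(x$design),
              sum(x$design$group == "high_regeneration"),
              sum(x$design$group == "low_regeneration"))
  ))
  invisible(x)
}

#' Read an expression table and its design from disk
#'
#' Reads a TSV or CSV expression table (`probe_id`, `gene_symbol`, then one
#' numeric column per sample — or a `log2fc` column for precomputed fold
#' changes) together with a two-column design table (`sample`, `group`).
#' Rows with an empty gene symbol are dropped and counted in the experiment
#' log. Group labels other than the canonical pair are accepted when
#' `high_group` names which one is the high-regeneration condition.
#'
#' @inheritParams expression_experiment
#' @param path Path to the expression table (`.tsv`/`.txt` tab-delimited,
#'   `.csv` comma-delimited).
#' @param design_path Path to the design table (same delimiter rules), or
#'   `NULL` for precomputed fold-change tables.
#' @param high_group Group label in the design file to treat as
#'   high-regeneration; the other label becomes low-regeneration.
#' @return A [expression_experiment()] object.
#' @export
read_expression_table <- function(path, design_path = NULL, species,
                                  platform = "unknown",
                                  experiment_id = basename(path),
                                  high_group = "high_regeneration") {
  data <- read_delim_auto(path)
  design <- NULL
  if (!is.null(design_path)) {
    design <- read_delim_auto(design_path)
    if (!all(c("sample", "group") %in% names(design))) {
      abort_parse(sprintf("design file %s must have columns sample, group", design_path))
    }
    groups <- unique(design$group)
    if (length(groups) != 2L) {
      abort_parse(sprintf("design file %s must define exactly 2 groups, found %d",
                          design_path, length(groups)))
    }
    if (!high_group %in% groups) {
      abort_parse(sprintf("high_group \"%s\" not among design groups {%s}",
                          high_group, paste(groups, collapse = ", ")))
    }
    design$group <- ifelse(design$group == high_group,
                           "high_regeneration", "low_regeneration")
  }
  expression_experiment(data, design, species = species, platform = platform,
                        experiment_id = experiment_id)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}
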