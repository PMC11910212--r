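#' Validate a pipeline configuration
#'
#' Accepts a YAML or JSON file path, or an R list, describing either a
#' synthetic study (`synthetic:` block, see [synthetic_config()]) or a set of
#' on-disk experiments (`experiments:` list with `id`, `path`, `species`, and
#' for raw-intensity tables a `design` path and optional `high_group`).
#' Validation is not fail-fast: all problems are collected and reported in a
#' single error, each naming the offending field.
#'
#' @param config File path or list.
#' @return A list of class `regensig_config` with defaults filled in:
#'   `n_top` (200), `mode` (`"per_dataset"`), `collapse` (`"median"`),
#'   `floor` (`NULL` = data-driven), `n_perm` (10000), `adjustment`
#'   (`"both"`), `seed` (1), `out_dir` (`NULL`), plus the experiment or
#'   synthetic declarations and optional `alias_table` / `ortholog_map` /
#'   `terms` paths.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort_config(sprintf("config file not found: %s", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (inherits(config, "regensig_config")) return(config)
  if (!is.list(config)) abort_config("config must be a file path or a list")

  defaults <- list(
    n_top = 200L, mode = "per_dataset", collapse = "median", floor = NULL,
    n_perm = 10000L, adjustment = "both", seed = 1L, out_dir = NULL,
    alias_table = NULL, ortholog_map = NULL, terms = NULL,
    synthetic = NULL, experiments = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  cfg <- utils::modifyList(defaults, config[intersect(names(config), names(defaults))])

  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(length(unknown) == 0L,
      sprintf("unknown field(s): %s", paste(unknown, collapse = ", ")))
  chk(is_count(cfg$n_top), "n_top: must be a non-negative integer")
  chk(cfg$mode %in% c("per_dataset", "aggregate"),
      "mode: must be \"per_dataset\" or \"aggregate\"")
  chk(cfg$collapse %in% c("median", "mean", "max_abs"),
      "collapse: must be one of median, mean, max_abs")
  chk(is.null(cfg$floor) || (is_number(cfg$floor) && cfg$floor > 0),
      "floor: must be a positive number or null")
  chk(is_count(cfg$n_perm, 1L), "n_perm: must be a positive integer")
  chk(cfg$adjustment %in% c("both", "BH", "bonferroni"),
      "adjustment: must be one of both, BH, bonferroni")
  chk(is_count(cfg$seed), "seed: must be a non-negative integer")

  if (is.null(cfg$synthetic) && is.null(cfg$experiments)) {
    chk(FALSE, "one of `synthetic` or `experiments` is required")
  }
  if (!is.null(cfg$synthetic)) {
    synth_args <- cfg$synthetic
    if (!"seed" %in% names(synth_args)) synth_args$seed <- cfg$seed
    tryCatch(
      cfg$synthetic <- do.call(synthetic_config, synth_args),
      error = function(e) chk(FALSE, sprintf("synthetic: %s",
                                             paste(conditionMessage(e), collapse = "; ")))
    )
  }
  if (!is.null(cfg$experiments)) {
    chk(is.list(cfg$experiments) && length(cfg$experiments) >= 1L,
        "experiments: must be a non-empty list")
    if (is.list(cfg$experiments)) {
      ids <- character()
      for (i in seq_along(cfg$experiments)) {
        ex <- cfg$experiments[[i]]
        where <- sprintf("experiments[%d]", i)
        if (!is.list(ex)) { chk(FALSE, sprintf("%s: must be a mapping", where)); next }
        for (f in c("id", "path", "species")) {
          chk(!is.null(ex[[f]]), sprintf("%s.%s: required", where, f))
        }
        if (!is.null(ex$species)) {
          chk(ex$species %in% c("mouse", "human"),
              sprintf("%s.species: must be mouse or human", where))
        }
        if (!isTRUE(ex$precomputed_fc)) {
          chk(!is.null(ex$design),
              sprintf("%s.design: required unless precomputed_fc is true", where))
        }
        if (!is.null(ex$id)) {
          chk(!ex$id %in% ids, sprintf("%s.id: duplicate experiment id \"%s\"", where, ex$id))
          ids <- c(ids, ex$id)
        }
      }
    }
  }
  if (length(errs)) {
    abort_config(c("invalid pipeline configuration:",
                   setNames(errs, rep("x", length(errs)))))
  }
  structure(cfg, class = "regensig_config")
}

with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      rlang::abort(
        sprintf("pipeline stage \"%s\" failed: %s", stage,
                paste(conditionMessage(e), collapse = "\n")),
        class = "regensig_stage_error", parent = e
      )
    }
  )
}

#' Run the full regeneration-signature pipeline
#'
#' One call from inputs to results: acquire the experiments (generated from a
#' `synthetic` block or read from disk), canonicalize symbols, map mouse
#' genes to human orthologs, compute per-gene log2 fold changes, build the
#' common universe, rank within each experiment, extract top-N signatures
#' (per-dataset lists intersected in a Venn, or aggregate-then-top-N),
#' test the central overlap against a seeded permutation null, and run Fisher
#' term enrichment on the central overlap. For synthetic studies the planted
#' signature's recovery is scored.
#'
#' @param config A [validate_config()] input (path, list, or validated
#'   config).
#' @return Object of class `regensig_result`: fields `config`, `config_hash`,
#'   `universe`, `fold_changes`, `ranks` (long tibbles), `aggregate`
#'   ([aggregate_ranks()] output), `signatures` (named list), `overlap`
#'   (with its permutation `null` filled in), `enrichment`, `recovery`,
#'   `truth` (synthetic runs only) and `log` (per-stage counts, drop lists
#'   and tie-break events).
#' @export
#' @examples
#' res <- run_pipeline(list(
#'   synthetic = list(U = 200, k = 2, S = 5, delta = 3, sigma = 1, seed = 7),
#'   n_top = 20, n_perm = 200
#' ))
#' glance(res)
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  config_hash <- rlang::hash(unclass(cfg))
  log <- list(config_hash = config_hash, seed = cfg$seed)
  if (cfg$n_top == 0L) {
    rlang::warn("n_top = 0: signatures, overlap and enrichment will be empty")
  }

  truth <- NULL
  if (!is.null(cfg$synthetic)) {
    study <- with_stage("synthetic_data", generate_study(cfg$synthetic))
    experiments <- study$experiments
    aliases <- study$aliases
    orthologs <- study$orthologs
    terms <- study$terms
    truth <- study$truth
  } else {
    experiments <- with_stage("ingest", {
      exs <- purrr::map(cfg$experiments, function(ex) {
        read_expression_table(
          ex$path,
          design_path = if (isTRUE(ex$precomputed_fc)) NULL else ex$design,
          species = ex$species,
          platform = ex$platform %||% "unknown",
          experiment_id = ex$id,
          high_group = ex$high_group %||% "high_regeneration"
        )
      })
      setNames(exs, purrr::map_chr(cfg$experiments, "id"))
    })
    aliases <- if (!is.null(cfg$alias_table)) {
      with_stage("ingest", alias_table(cfg$alias_table))
    }
    orthologs <- if (!is.null(cfg$ortholog_map)) {
      with_stage("ingest", ortholog_map(cfg$ortholog_map))
    }
    terms <- if (!is.null(cfg$terms)) with_stage("ingest", read_term_gmt(cfg$terms))
  }

  if (!is.null(aliases)) {
    experiments <- with_stage(
      "canonicalize",
      purrr::map(experiments, canonicalize_symbols, aliases = aliases)
    )
  }
  if (any(purrr::map_chr(experiments, "species") == "mouse")) {
    if (is.null(orthologs)) {
      abort_input("mouse experiment(s) present but no ortholog_map configured")
    }
    experiments <- with_stage(
      "ortholog_mapping",
      purrr::map(experiments, map_to_human, orthologs = orthologs)
    )
  }

  fold_changes <- with_stage("fold_change", {
    dplyr::bind_rows(purrr::map(
      experiments, fold_change_table,
      floor = cfg$floor, collapse = cfg$collapse
    ))
  })
  universe <- with_stage(
    "universe",
    build_common_universe(split(fold_changes$gene_symbol, fold_changes$experiment_id))
  )
  fold_changes <- fold_changes[fold_changes$gene_symbol %in% universe$genes, ]
  ranks <- with_stage("ranking", {
    fold_changes |>
      dplyr::group_by(.data$experiment_id) |>
      dplyr::group_modify(~ rank_by_fc(.x)) |>
      dplyr::ungroup()
  })
  aggregate <- with_stage("aggregation", aggregate_ranks(ranks))

  signatures <- with_stage("signature", {
    if (cfg$mode == "per_dataset") {
      ids <- sort(unique(ranks$experiment_id))
      sigs <- purrr::map(
        setNames(ids, ids),
        function(id) top_n_signature(ranks[ranks$experiment_id == id, ], cfg$n_top)
      )
    } else {
      list(aggregate = top_n_signature(aggregate, cfg$n_top))
    }
  })
  log$tie_breaks <- purrr::compact(purrr::map(signatures, attr, "tie_break"))
  log$tie_breaks <- log$tie_breaks[!is.na(log$tie_breaks)]

  overlap <- NULL
  if (length(signatures) <= 3L && cfg$n_top > 0L) {
    overlap <- with_stage("overlap", {
      ov <- venn_regions(signatures, universe = universe)
      overlap_null_pvalue(ov, universe_size = universe$U,
                          n_perm = cfg$n_perm, seed = cfg$seed)
    })
    central <- overlap$central
  } else {
    central <- Reduce(intersect, purrr::map(signatures, sig_genes))
  }

  enrichment <- NULL
  if (!is.null(terms) && nrow(terms) > 0L) {
    if (length(central) > 0L) {
      enrichment <- with_stage(
        "enrichment",
        fisher_enrichment(central, terms, universe, adjustment = cfg$adjustment)
      )
    } else {
      rlang::warn("central overlap is empty; enrichment skipped")
    }
  }

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- with_stage("recovery", evaluate_recovery(central, truth))
  }

  log$experiments <- purrr::map(experiments, function(ex) {
    c(list(probes = nrow(ex$data), genes = dplyr::n_distinct(ex$data$gene_symbol)),
      ex$log)
  })
  log$universe_size <- universe$U
  log$dropped_by_universe <- nrow(universe$dropped)

  result <- structure(
    list(
      config = cfg, config_hash = config_hash, universe = universe,
      fold_changes = fold_changes, ranks = ranks, aggregate = aggregate,
      signatures = signatures, overlap = overlap, central = central,
      enrichment = enrichment, recovery = recovery, truth = truth, log = log
    ),
    class = "regensig_result"
  )
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(result, cfg$out_dir)
  result
}

#' @export
print.regensig_result <- function(x, ...) {
  cat(sprintf("<regensig_result> %d experiments, universe U = %d, n_top = %d (%s mode)\n",
              length(x$signatures), x$universe$U, x$config$n_top, x$config$mode))
  cat(sprintf("  central overlap: %d gene(s)", length(x$central)))
  if (!is.null(x$overlap$null)) {
    cat(sprintf(" (expected %.3g, permutation p = %.3g)",
                x$overlap$null$expected, x$overlap$null$p_value))
  }
  cat("\n")
  if (!is.null(x$enrichment) && nrow(x$enrichment)) {
    cat(sprintf("  top enriched term: %s (p = %.3g)\n",
                x$enrichment$term_id[1], x$enrichment$p_value[1]))
  }
  if (!is.null(x$recovery)) {
    cat(sprintf("  planted-signature recovery: recall %.3f, precision %.3f\n",
                x$recovery$recall, x$recovery$precision))
  }
  invisible(x)
}

#' Write pipeline outputs and provenance sidecars
#'
#' Primary outputs are TSVs (signatures, fold changes, ranks, aggregate
#' ranking, overlap regions, enrichment); each carries a
#' `<name>.provenance.json` sidecar with the config hash and seed, and a
#' plain-text Venn region report plus a JSON run report are written
#' alongside. Re-running an identical config over identical inputs yields
#' byte-identical TSVs.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "regensig_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  provenance <- list(
    config_hash = result$config_hash,
    seed = result$config$seed,
    n_top = result$config$n_top,
    mode = result$config$mode,
    universe_size = result$universe$U,
    tie_breaks = result$log$tie_breaks
  )
  emit_tsv <- function(tbl, name, stage) {
    path <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, path, progress = FALSE)
    jsonlite::write_json(c(provenance, list(stage = stage, file = basename(path))),
                         file.path(dir, paste0(name, ".provenance.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  emit_tsv(result$fold_changes, "fold_changes", "fold_change")
  emit_tsv(result$ranks, "ranks", "ranking")
  emit_tsv(tibble::as_tibble(result$aggregate), "aggregate_ranking", "aggregation")
  for (id in names(result$signatures)) {
    emit_tsv(tibble::as_tibble(result$signatures[[id]]),
             paste0("signature_", id), "signature")
  }
  if (!is.null(result$overlap)) {
    regions <- result$overlap$regions |>
      dplyr::mutate(genes = purrr::map_chr(.data$genes, paste, collapse = ";"))
    emit_tsv(regions, "overlap_regions", "overlap")
    report <- c(
      sprintf("Venn regions over %d lists (universe U = %d)",
              result$overlap$k, result$universe$U),
      sprintf("%-28s %6d  %s", regions$region, regions$n,
              ifelse(nchar(regions$genes) > 60,
                     paste0(substr(regions$genes, 1, 57), "..."), regions$genes))
    )
    if (!is.null(result$overlap$null)) {
      report <- c(report, sprintf(
        "central overlap = %d; expected under independence = %.4g; permutation p = %.4g (M = %d, seed = %d)",
        result$overlap$null$observed, result$overlap$null$expected,
        result$overlap$null$p_value, result$overlap$null$n_perm,
        result$overlap$null$seed
      ))
    }
    readr::write_lines(report, file.path(dir, "venn_report.txt"))
  }
  if (!is.null(result$enrichment)) {
    emit_tsv(tibble::as_tibble(result$enrichment), "enrichment", "enrichment")
  }
  run_report <- c(provenance, list(
    central_overlap = result$central,
    experiments = result$log$experiments,
    dropped_by_universe = result$log$dropped_by_universe
  ))
  if (!is.null(result$recovery)) {
    run_report$recovery <- as.list(result$recovery[, c("recall", "precision",
                                                       "n_recovered", "n_signature",
                                                       "n_planted")])
  }
  jsonlite::write_json(run_report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
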