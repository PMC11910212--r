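test_that("expression tables and designs parse with validation", {
  paths <- write_tiny_experiment()
  ex <- read_expression_table(paths$expr, paths$design, species = "human",
                              platform = "demo", experiment_id = "tiny")
  expect_s3_class(ex, "regensig_experiment")
  expect_equal(nrow(ex$data), 3)
  expect_equal(sum(ex$design$group == "high_regeneration"), 2)
  expect_equal(sum(ex$design$group == "low_regeneration"), 2)
})

test_that("a design sample missing from the table is an error naming it", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_experiment(dir)
  design <- readr::read_tsv(paths$design, show_col_types = FALSE)
  design$sample[1] <- "s_ghost"
  readr::write_tsv(design, paths$design, progress = FALSE)
  expect_error(
    read_expression_table(paths$expr, paths$design, species = "human"),
    "s_ghost"
  )
})

test_that("rows with an empty gene symbol are dropped and counted", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_experiment(dir)
  expr <- readr::read_tsv(paths$expr, show_col_types = FALSE)
  expr$gene_symbol[2] <- ""
  readr::write_tsv(expr, paths$expr, progress = FALSE)
  ex <- read_expression_table(paths$expr, paths$design, species = "human")
  expect_equal(nrow(ex$data), 2)
  expect_equal(ex$log$dropped_empty_symbol, 1)
})

test_that("malformed tables fail with parse errors in context", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_experiment(dir)
  expr <- readr::read_tsv(paths$expr, show_col_types = FALSE)

  readr::write_tsv(dplyr::rename(expr, probe = probe_id), paths$expr, progress = FALSE)
  expect_error(read_expression_table(paths$expr, paths$design, species = "human"),
               "probe_id")

  expr$s1 <- c("high", "low", "high")
  readr::write_tsv(expr, paths$expr, progress = FALSE)
  expect_error(read_expression_table(paths$expr, paths$design, species = "human"),
               "s1")

  expect_error(
    expression_experiment(
      tibble::tibble(probe_id = c("p1", "p1"), gene_symbol = c("A", "B"), log2fc = c(1, 2)),
      species = "human", experiment_id = "dup"
    ),
    "duplicate probe_id"
  )
})

test_that("custom design group labels map onto the canonical pair", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_experiment(dir)
  design <- readr::read_tsv(paths$design, show_col_types = FALSE)
  design$group <- rep(c("polyIC", "vehicle"), each = 2)
  readr::write_tsv(design, paths$design, progress = FALSE)
  ex <- read_expression_table(paths$expr, paths$design, species = "human",
                              high_group = "polyIC")
  expect_setequal(unique(ex$design$group),
                  c("high_regeneration", "low_regeneration"))
  expect_equal(ex$design$sample[ex$design$group == "high_regeneration"], c("s1", "s2"))
})

test_that("symbol canonicalization updates aliases, passes unknowns, and is idempotent", {
  aliases <- alias_table(tibble::tibble(
    alias_symbol = c("Il1f6", "Oas1l"),
    canonical_symbol = c("Il36a", "Oas1a"),
    species = "mouse"
  ))
  ex <- expression_experiment(
    tibble::tibble(probe_id = paste0("p", 1:3),
                   gene_symbol = c("Il1f6", "Il36a", "Zzz99"),
                   log2fc = c(1, 2, 3)),
    species = "mouse", experiment_id = "m1"
  )
  out <- canonicalize_symbols(ex, aliases)
  expect_equal(out$data$gene_symbol, c("Il36a", "Il36a", "Zzz99"))
  expect_equal(out$log$canonicalized, 1)
  expect_equal(out$log$unmapped_alias, 2)
  twice <- canonicalize_symbols(out, aliases)
  expect_identical(twice$data$gene_symbol, out$data$gene_symbol)
})

test_that("an alias table that re-aliases a canonical symbol is rejected", {
  expect_error(
    alias_table(tibble::tibble(
      alias_symbol = c("A", "B"), canonical_symbol = c("B", "C"),
      species = "mouse"
    )),
    "canonical"
  )
})

test_that("ortholog mapping relabels, expands paralogs, and drops unmapped genes", {
  orthologs <- ortholog_map(tibble::tibble(
    mouse_symbol = c("Oas1a", "Oas1g"),
    human_symbol = c("OAS1", "OAS1"),
    source_db = "HomoloGene"
  ))
  ex <- expression_experiment(
    tibble::tibble(probe_id = paste0("p", 1:3),
                   gene_symbol = c("Oas1a", "Oas1g", "Orphan1"),
                   log2fc = c(1, 3, 9)),
    species = "mouse", experiment_id = "m1"
  )
  mapped <- map_to_human(ex, orthologs)
  # both paralog probe sets are carried under OAS1 ...
  expect_equal(mapped$data$gene_symbol, c("OAS1", "OAS1"))
  expect_equal(mapped$log$dropped_no_ortholog, "Orphan1")
  # ... and the gene-level collapse yields a single OAS1 fold change (median 2)
  fc <- fold_change_table(mapped)
  expect_equal(nrow(fc), 1)
  expect_equal(fc$log2fc, 2)
  expect_equal(fc$n_probes, 2L)
})

test_that("human experiments pass through ortholog mapping unchanged", {
  ex <- expression_experiment(
    tibble::tibble(probe_id = "p1", gene_symbol = "OAS1", log2fc = 1),
    species = "human", experiment_id = "h1"
  )
  mapped <- map_to_human(ex, ortholog_map(tibble::tibble(
    mouse_symbol = "Oas1a", human_symbol = "OAS1"
  )))
  expect_identical(mapped$data, ex$data)
  expect_identical(mapped$gene_space, "human")
})

test_that("mapping that empties an experiment is an input error", {
  ex <- expression_experiment(
    tibble::tibble(probe_id = "p1", gene_symbol = "NoSuchGene", log2fc = 1),
    species = "mouse", experiment_id = "m1"
  )
  expect_error(
    map_to_human(ex, ortholog_map(tibble::tibble(
      mouse_symbol = "Oas1a", human_symbol = "OAS1"
    ))),
    "no probe survived"
  )
})

test_that("the common universe is the sorted intersection, order-invariant", {
  expect_equal(build_common_universe(list(c("A", "B", "C"), c("B", "C", "D")))$genes,
               c("B", "C"))
  sets <- list(e1 = c("A", "B", "C"), e2 = c("B", "C", "D"), e3 = c("C", "D", "E"))
  expect_equal(build_common_universe(sets)$genes, "C")
  expect_identical(build_common_universe(sets)$genes,
                   build_common_universe(rev(sets))$genes)
  same <- build_common_universe(list(a = c("X", "Y"), b = c("Y", "X")))
  expect_setequal(same$genes, c("X", "Y"))
  expect_error(build_common_universe(list(c("A"), c("B"))), "empty")
  # never invents symbols, and logs what each experiment lost
  u <- build_common_universe(sets)
  expect_true(all(u$genes %in% unlist(sets)))
  expect_setequal(u$dropped$gene_symbol[u$dropped$experiment_id == "e1"], c("A", "B"))
})

test_that("GMT term databases round-trip through disk", {
  terms <- tibble::tibble(
    term_id = c("t1", "t1", "t2"),
    term_name = c("oas family", "oas family", "wnt"),
    gene_symbol = c("OAS1", "OAS2", "WNT7B")
  )
  path <- withr::local_tempfile(fileext = ".gmt")
  write_term_gmt(terms, path)
  back <- read_term_gmt(path)
  expect_equal(dplyr::arrange(back, term_id, gene_symbol),
               dplyr::arrange(terms, term_id, gene_symbol))
})
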