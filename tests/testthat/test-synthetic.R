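test_that("identical config and seed reproduce the study byte for byte", {
  cfg <- synthetic_config(U = 80, k = 3, S = 5, delta = 2, sigma = 1, seed = 11)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1, s2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study_fixtures(s1, d1)
  write_study_fixtures(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed must change the data
  s3 <- generate_study(synthetic_config(U = 80, k = 3, S = 5, delta = 2,
                                        sigma = 1, seed = 12))
  expect_false(identical(s1$truth$planted_genes, s3$truth$planted_genes) &&
                 identical(s1$experiments[[1]]$data, s3$experiments[[1]]$data))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(synthetic_config(U = 5, S = 10), "S")
  expect_error(synthetic_config(sigma = -1), "sigma")
  expect_error(synthetic_config(k = 0), "k")
  expect_error(synthetic_config(frac_unmapped = 1.5), "frac_unmapped")
  expect_error(synthetic_config(probes_per_gene_range = c(3, 1)),
               "probes_per_gene_range")
  # all problems reported at once
  err <- tryCatch(synthetic_config(sigma = -1, k = 0), error = conditionMessage)
  expect_match(err, "sigma")
  expect_match(err, "k >= 1")
})

test_that("without noise the planted genes top every experiment exactly", {
  study <- generate_study(synthetic_config(
    U = 50, k = 3, S = 5, delta = 2, sigma = 0, seed = 3
  ))
  planted <- study$truth$planted_genes
  for (ex in study$experiments) {
    ex <- canonicalize_symbols(ex, study$aliases)
    ex <- map_to_human(ex, study$orthologs)
    fc <- fold_change_table(ex)
    top5 <- fc$gene_symbol[order(-fc$log2fc)][1:5]
    expect_setequal(top5, planted)
    expect_equal(fc$log2fc[fc$gene_symbol %in% planted], rep(2, 5))
    expect_true(all(abs(fc$log2fc[!fc$gene_symbol %in% planted]) < 1e-12))
  }
})

test_that("mouse experiments live in mouse symbol space until mapped", {
  study <- generate_study(synthetic_config(U = 60, k = 2, S = 3, seed = 5))
  mouse <- study$experiments[[1]]
  human <- study$experiments[[2]]
  expect_identical(mouse$species, "mouse")
  expect_identical(human$species, "human")
  expect_false(any(grepl("^GENE", mouse$data$gene_symbol)))
  mapped <- map_to_human(canonicalize_symbols(mouse, study$aliases), study$orthologs)
  expect_true(all(grepl("^GENE", mapped$data$gene_symbol)))
  expect_true(all(mapped$data$gene_symbol %in% study$truth$universe))
})

test_that("the term database contains the planted set plus decoys", {
  study <- generate_study(synthetic_config(U = 400, S = 12, seed = 9))
  planted_term <- study$terms[study$terms$term_id == "TERM000", ]
  expect_setequal(planted_term$gene_symbol, study$truth$planted_genes)
  decoys <- study$terms[study$terms$term_id != "TERM000", ]
  expect_length(unique(decoys$term_id), 20)
  sizes <- table(decoys$term_id)
  expect_true(all(sizes >= 10 & sizes <= 50))
  expect_false(any(decoys$gene_symbol %in% study$truth$planted_genes))
})

test_that("recovery metrics follow the set arithmetic, with degenerate cases", {
  study <- generate_study(synthetic_config(U = 500, S = 20, seed = 21))
  truth <- study$truth
  planted <- truth$planted_genes

  exact <- evaluate_recovery(planted, truth)
  expect_equal(exact$recall, 1)
  expect_equal(exact$precision, 1)

  non_planted <- setdiff(truth$universe, planted)
  sig <- c(planted[1:10], non_planted[1:190])
  partial <- evaluate_recovery(sig, truth)
  expect_equal(partial$recall, 0.5)
  expect_equal(partial$precision, 0.05)
  expect_setequal(partial$recovered[[1]], planted[1:10])

  empty <- evaluate_recovery(character(), truth)
  expect_equal(empty$recall, 0)
  expect_true(is.na(empty$precision))

  expect_error(evaluate_recovery(c("NOT_A_GENE"), truth), "universe")
})

test_that("planted-signature recall is non-decreasing in the effect size", {
  deltas <- c(0, 0.5, 1, 2, 4)
  mean_recall <- vapply(deltas, function(d) {
    recalls <- vapply(1:3, function(s) {
      res <- run_pipeline(list(
        synthetic = list(U = 300, k = 3, S = 10, delta = d, sigma = 1, seed = 100 + s),
        n_top = 50, n_perm = 100
      ))
      res$recovery$recall
    }, numeric(1))
    mean(recalls)
  }, numeric(1))
  expect_true(all(diff(mean_recall) >= -0.05))
  expect_gt(mean_recall[length(deltas)], 0.95)
})
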