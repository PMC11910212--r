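test_that("log2 fold change follows the floored ratio rule", {
  expect_equal(log2_fold_change(8, 2, floor = 0.5), 2)
  expect_equal(log2_fold_change(5, 5, floor = 1), 0)
  expect_equal(log2_fold_change(0, 4, floor = 1), -2)
  expect_equal(log2_fold_change(c(8, 0), c(2, 4), floor = 1), c(2, -2))
  expect_error(log2_fold_change(-1, 2, floor = 1), "non-negative")
  expect_error(log2_fold_change(1, 2, floor = 0), "floor")
  expect_true(is.finite(log2_fold_change(0, 0, floor = 1e-6)))
})

test_that("probe collapse supports median, mean and max_abs", {
  two <- tibble::tibble(gene_symbol = "G", log2fc = c(1, 3))
  expect_equal(collapse_probes(two)$log2fc, 2)
  one <- tibble::tibble(gene_symbol = "G", log2fc = 2.5)
  expect_equal(collapse_probes(one)$log2fc, 2.5)
  three <- tibble::tibble(gene_symbol = "G", log2fc = c(1, 2, 10))
  expect_equal(collapse_probes(three, "median")$log2fc, 2)
  expect_equal(collapse_probes(three, "mean")$log2fc, 13 / 3)
  signed <- tibble::tibble(gene_symbol = "G", log2fc = c(1, -5, 2))
  expect_equal(collapse_probes(signed, "max_abs")$log2fc, -5)
  expect_equal(collapse_probes(three)$n_probes, 3L)
  expect_error(collapse_probes(three[0, ]), "non-empty")
})

test_that("ranking is descending in fold change with average ties", {
  r <- rank_by_fc(tibble::tibble(gene_symbol = c("A", "B", "C"), log2fc = c(3, 2, 1)))
  expect_equal(r$rank[match(c("A", "B", "C"), r$gene_symbol)], c(1, 2, 3))
  tied <- rank_by_fc(tibble::tibble(gene_symbol = c("C", "A", "B"), log2fc = c(2, 1, 1)))
  expect_equal(tied$rank[match(c("C", "A", "B"), tied$gene_symbol)], c(1, 2.5, 2.5))
  expect_equal(sum(tied$rank), 6)
  expect_error(rank_by_fc(tibble::tibble(gene_symbol = c("A", "A"), log2fc = c(1, 2))),
               "one row per gene")
  expect_error(rank_by_fc(tibble::tibble(gene_symbol = "A", log2fc = NaN)), "finite")
})

test_that("rank sums equal U(U+1)/2 on randomized instances", {
  withr::with_seed(42, {
    for (i in 1:20) {
      U <- sample(3:40, 1)
      fc <- tibble::tibble(
        gene_symbol = paste0("g", seq_len(U)),
        # coarse rounding forces frequent ties
        log2fc = round(stats::rnorm(U), sample(0:1, 1))
      )
      expect_equal(sum(rank_by_fc(fc)$rank), U * (U + 1) / 2)
    }
  })
})

test_that("ranks are invariant under strictly increasing transforms", {
  withr::with_seed(7, {
    fc <- tibble::tibble(gene_symbol = paste0("g", 1:30),
                         log2fc = round(stats::rnorm(30), 1))
    base <- rank_by_fc(fc)
    for (f in list(function(x) 2 * x + 1, exp, function(x) x^3)) {
      transformed <- rank_by_fc(dplyr::mutate(fc, log2fc = f(log2fc)))
      expect_equal(
        transformed$rank[match(base$gene_symbol, transformed$gene_symbol)],
        base$rank
      )
    }
  })
})

test_that("the six-gene worked study aggregates to the hand-computed mean ranks", {
  ranks <- purrr::map(worked_example_fc(), rank_by_fc)
  agg <- aggregate_ranks(ranks)
  expect_equal(
    setNames(agg$mean_rank[match(names(worked_example_mean_ranks), agg$gene_symbol)],
             names(worked_example_mean_ranks)),
    worked_example_mean_ranks,
    tolerance = 1e-12
  )
  expect_equal(agg$gene_symbol[1:2], c("A", "B"))
})

test_that("aggregation is invariant under experiment order and k=1 is the identity", {
  ranks <- purrr::map(worked_example_fc(), rank_by_fc)
  agg <- aggregate_ranks(ranks)
  shuffled <- aggregate_ranks(ranks[c(3, 1, 2)])
  expect_equal(tibble::as_tibble(agg), tibble::as_tibble(shuffled))

  solo <- aggregate_ranks(ranks[1])
  expect_equal(solo$gene_symbol, ranks[[1]]$gene_symbol[order(ranks[[1]]$rank)])
  expect_equal(sort(solo$mean_rank), sort(ranks[[1]]$rank))
})

test_that("aggregation rejects mismatched universes naming the difference", {
  ranks <- purrr::map(worked_example_fc(), rank_by_fc)
  ranks[[2]] <- ranks[[2]][ranks[[2]]$gene_symbol != "F", ]
  expect_error(aggregate_ranks(ranks), "F")
})

test_that("top-N extraction is deterministic with a lexicographic boundary tie-break", {
  agg <- aggregate_ranks(purrr::map(worked_example_fc(), rank_by_fc))
  top2 <- top_n_signature(agg, 2)
  expect_equal(top2$gene_symbol, c("A", "B"))
  expect_match(attr(top2, "tie_break"), "lexicographically")

  full <- top_n_signature(agg, 100)
  expect_equal(nrow(full), 6)
  expect_equal(full$gene_symbol, agg$gene_symbol)
  expect_true(is.na(attr(full, "tie_break")))

  expect_equal(nrow(top_n_signature(agg, 0)), 0)
  # works directly on a single experiment's rank table (per-dataset mode)
  r1 <- rank_by_fc(worked_example_fc()$E1)
  expect_equal(top_n_signature(r1, 3)$gene_symbol, c("A", "B", "C"))
})

test_that("aggregation bounds hold: 1 <= mean rank <= U, unanimity gives 1", {
  unanimous <- purrr::map(1:3, function(i) {
    tibble::tibble(experiment_id = paste0("e", i),
                   gene_symbol = c("TOP", "X", "Y"),
                   rank = c(1, 2, 3))
  })
  agg <- aggregate_ranks(unanimous)
  expect_equal(agg$mean_rank[agg$gene_symbol == "TOP"], 1)
  expect_true(all(agg$mean_rank >= 1 & agg$mean_rank <= 3))
})
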