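# Shared fixtures and independent oracles. Oracles are deliberately naive
# (choose() sums, full enumeration) and never call the code paths they check.

# Six-gene, three-experiment worked study; hand-computed mean ranks:
# E1 ranks: A1 B2 C3 D4 E5 F6
# E2 ranks: B1 A2 D3 C4 F5 E6
# E3 ranks: C1 A2.5 B2.5 E4 D5 F6 (A/B tied at fc = 1)
# mean:     A 11/6, B 11/6, C 8/3, D 4, E 5, F 17/3
worked_example_fc <- function() {
  list(
    E1 = tibble::tibble(gene_symbol = LETTERS[1:6], log2fc = c(3, 2, 1, 0, -1, -2)),
    E2 = tibble::tibble(gene_symbol = LETTERS[1:6], log2fc = c(2, 3, 0, 1, -2, -1)),
    E3 = tibble::tibble(gene_symbol = LETTERS[1:6], log2fc = c(1, 1, 2, -1, 0, -3))
  )
}

worked_example_mean_ranks <- c(A = 11 / 6, B = 11 / 6, C = 8 / 3, D = 4, E = 5, F = 17 / 3)

# Upper hypergeometric tail by explicit combinatorial sum: the probability of
# drawing >= a term genes when `n_list` genes are drawn from a universe of U
# containing `n_term` term genes.
enum_hyper_tail <- function(a, n_term, n_list, U) {
  xs <- seq(max(0L, n_term + n_list - U), min(n_term, n_list))
  xs <- xs[xs >= a]
  if (length(xs) == 0L) return(0)
  sum(choose(n_term, xs) * choose(U - n_term, n_list - xs)) / choose(U, n_list)
}

# Exact null distribution of the k-way central overlap of independent uniform
# draws without replacement, by full enumeration of every tuple of subsets.
# Only feasible for tiny U; returns P(overlap >= observed).
enum_overlap_tail <- function(observed, list_sizes, U) {
  subsets <- lapply(list_sizes, function(n) utils::combn(U, n, simplify = FALSE))
  grids <- expand.grid(lapply(subsets, seq_along))
  sizes <- apply(grids, 1, function(idx) {
    length(Reduce(intersect, Map(function(s, i) s[[i]], subsets, idx)))
  })
  mean(sizes >= observed)
}

# Step-up BH adjustment written out longhand, independent of p.adjust.
enum_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# A tiny on-disk expression fixture: 3 probes, 2 + 2 samples.
write_tiny_experiment <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  expr <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    gene_symbol = c("OAS1", "WNT7B", "IL36A"),
    s1 = c(8, 2, 4), s2 = c(8, 2, 4), s3 = c(2, 2, 1), s4 = c(2, 2, 1)
  )
  design <- tibble::tibble(
    sample = c("s1", "s2", "s3", "s4"),
    group = rep(c("high_regeneration", "low_regeneration"), each = 2)
  )
  paths <- list(expr = file.path(dir, "expr.tsv"), design = file.path(dir, "design.tsv"))
  readr::write_tsv(expr, paths$expr, progress = FALSE)
  readr::write_tsv(design, paths$design, progress = FALSE)
  paths
}
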