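#' Venn regions of up to three signature lists
#'
#' Computes exact region memberships for the 2^k - 1 Venn regions of k
#' signature lists (k <= 3) drawn from one universe. The central region is
#' the intersection of all lists — the cross-experiment signature.
#'
#' @param lists Named list of 1-3 signatures (character vectors or
#'   [top_n_signature()] tibbles).
#' @param universe Optional universe ([build_common_universe()] object or
#'   character vector); when supplied, a list gene outside it is an error.
#' @return Object of class `regensig_overlap`: fields `regions` (tibble with
#'   `region`, `pattern`, `n`, `genes` list-column; exclusive regions),
#'   `central` (character vector), `k`, `list_sizes`, `universe_size`
#'   (`NA` when no universe given), and `null` (`NULL` until
#'   [overlap_null_pvalue()] is run).
#' @export
#' @examples
#' ov <- venn_regions(list(
#'   e1 = c("A", "B", "C"), e2 = c("B", "C", "D"), e3 = c("C", "D", "E")
#' ))
#' ov$central # "C"
venn_regions <- function(lists, universe = NULL) {
  if (!is.list(lists) || length(lists) < 1L || length(lists) > 3L) {
    abort_input("`lists` must hold 1 to 3 signature lists")
  }
  sets <- purrr::map(lists, function(s) unique(sig_genes(s)))
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("list_", seq_along(sets))
  }
  u_size <- NA_integer_
  if (!is.null(universe)) {
    ug <- universe_genes(universe)
    u_size <- length(ug)
    outside <- setdiff(unlist(sets), ug)
    if (length(outside)) {
      abort_input(sprintf(
        "signature gene(s) outside the universe: %s",
        paste(head(sort(outside), 5), collapse = ", ")
      ))
    }
  }
  k <- length(sets)
  all_genes <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  membership <- matrix(membership, nrow = length(all_genes),
                       dimnames = list(all_genes, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), , drop = FALSE]
  names(patterns) <- names(sets)
  regions <- purrr::pmap(patterns, function(...) {
    inc <- c(...)
    hit <- rep(TRUE, length(all_genes))
    for (j in seq_len(k)) hit <- hit & (membership[, j] == inc[j])
    all_genes[hit]
  })
  region_label <- apply(patterns, 1, function(inc) {
    paste0(
      paste(names(sets)[as.logical(inc)], collapse = "&"),
      if (any(!inc)) paste0(" only") else ""
    )
  })
  region_label[rowSums(patterns) == k] <- "central"
  regions_tbl <- tibble::tibble(
    region = region_label,
    pattern = apply(patterns, 1, function(inc) paste(as.integer(inc), collapse = "")),
    n = lengths(regions),
    genes = regions
  ) |>
    dplyr::arrange(dplyr::desc(nchar(gsub("0", "", .data$pattern))), .data$pattern)
  central <- regions[[which(rowSums(patterns) == k)]]
  structure(
    list(
      regions = regions_tbl,
      central = central,
      k = k,
      list_sizes = lengths(sets),
      universe_size = u_size,
      null = NULL
    ),
    class = "regensig_overlap"
  )
}

#' @export
print.regensig_overlap <- function(x, ...) {
  cat(sprintf("<regensig_overlap> k = %d lists (sizes %s); central overlap = %d gene(s)\n",
              x$k, paste(x$list_sizes, collapse = ", "), length(x$central)))
  if (!is.null(x$null)) {
    cat(sprintf("  expected under independence = %.4g; permutation p = %.4g (M = %d)\n",
                x$null$expected, x$null$p_value, x$null$n_perm))
  }
  invisible(x)
}

#' Permutation null for the central overlap
#'
#' Under the null that the k signature lists are independent uniform draws
#' (without replacement) from the universe, the expected central overlap is
#' U * prod(n_i / U). The permutation p-value uses the standard
#' add-one Monte-Carlo convention `p = (1 + #{null >= observed}) / (M + 1)`,
#' which guarantees p in (0, 1].
#'
#' @param observed Observed central overlap size, or a `regensig_overlap`
#'   object (whose `null` field is then filled in).
#' @param list_sizes Integer vector of the k list sizes (taken from the
#'   overlap object when one is given).
#' @param universe_size Universe size U.
#' @param n_perm Number of permutations M.
#' @param seed Integer seed for the permutation draws.
#' @return A tibble `observed`, `expected`, `p_value`, `n_perm`, `seed` —
#'   or, when `observed` is an overlap object, that object with `null` set.
#' @export
#' @examples
#' overlap_null_pvalue(2, c(2, 2), universe_size = 4, n_perm = 2000, seed = 1)
overlap_null_pvalue <- function(observed, list_sizes = NULL, universe_size,
                                n_perm = 10000, seed = 1) {
  if (inherits(observed, "regensig_overlap")) {
    ov <- observed
    if (missing(universe_size)) universe_size <- ov$universe_size
    res <- overlap_null_pvalue(length(ov$central), ov$list_sizes,
                               universe_size = universe_size,
                               n_perm = n_perm, seed = seed)
    ov$null <- res
    return(ov)
  }
  if (!is_count(observed)) abort_input("`observed` must be a non-negative integer")
  if (!is_count(universe_size, min = 1L)) abort_input("`universe_size` must be >= 1")
  if (is.null(list_sizes) || !all(vapply(list_sizes, is_count, logical(1)))) {
    abort_input("`list_sizes` must be non-negative integers")
  }
  if (any(list_sizes > universe_size)) {
    abort_input("every list size must be <= universe_size")
  }
  if (observed > min(list_sizes)) {
    abort_input("`observed` overlap cannot exceed the smallest list size")
  }
  if (!is_count(n_perm, min = 1L)) abort_input("`n_perm` must be >= 1")
  k <- length(list_sizes)
  expected <- universe_size * prod(list_sizes / universe_size)
  null_sizes <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      hits <- integer(universe_size)
      for (n_i in list_sizes) {
        idx <- sample.int(universe_size, n_i)
        hits[idx] <- hits[idx] + 1L
      }
      sum(hits == k)
    }, integer(1))
  })
  p <- (1 + sum(null_sizes >= observed)) / (n_perm + 1)
  tibble::tibble(
    observed = as.integer(observed),
    expected = expected,
    p_value = p,
    n_perm = as.integer(n_perm),
    seed = as.integer(seed)
  )
}
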