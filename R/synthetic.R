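#' Configuration for a synthetic multi-platform study
#'
#' Describes a simulated study of `k` two-group experiments over a shared
#' universe of `U` orthologous genes, with `S` planted signature genes that
#' carry a common positive log2 effect `delta` in the high-regeneration group
#' of every experiment. Per-sample log2-intensity noise is Gaussian with
#' standard deviation `sigma`; each platform draws its probe multiplicity per
#' gene uniformly from `probes_per_gene_range`. A fraction `frac_unmapped` of
#' non-planted genes has no ortholog record (so they drop out of the common
#' universe via the mouse experiments), and `frac_many_to_one` of mapped
#' genes receive a second mouse paralog mapping to the same human symbol.
#'
#' @param U Number of orthologous genes in the simulated universe.
#' @param k Number of experiments (>= 1); experiments listed in
#'   `mouse_experiments` are mouse-labelled, the rest human.
#' @param S Number of planted signature genes (0 <= S <= U).
#' @param delta Planted log2 effect added to the high-regeneration group.
#' @param sigma Per-sample log2-intensity noise standard deviation (>= 0).
#' @param probes_per_gene_range Inclusive integer range for per-gene probe
#'   multiplicity on each platform.
#' @param samples_per_group Replicates per condition (>= 1).
#' @param frac_unmapped Fraction of (non-planted) mouse genes without an
#'   ortholog entry, in [0, 1].
#' @param frac_many_to_one Fraction of mapped human genes receiving two mouse
#'   paralogs, in [0, 1].
#' @param frac_alias Fraction of (non-planted) genes recorded under an
#'   outdated alias symbol in the expression tables, with the alias table
#'   providing the update to current nomenclature.
#' @param mouse_experiments Integer indices (in 1..k) of the mouse-labelled
#'   experiments; default the first.
#' @param seed Integer random seed; identical config + seed gives
#'   byte-identical output.
#' @return A validated list of class `regensig_synth_config`.
#' @export
synthetic_config <- function(U = 2000, k = 3, S = 20, delta = 3, sigma = 1,
                             probes_per_gene_range = c(1L, 3L),
                             samples_per_group = 3L,
                             frac_unmapped = 0.05, frac_many_to_one = 0.05,
                             frac_alias = 0.1,
                             mouse_experiments = 1L, seed = 1L) {
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(is_count(U, 1L), "U: must be a positive integer")
  chk(is_count(k, 1L), "k: must be a positive integer (k >= 1)")
  chk(is_count(S) && (!is_count(U, 1L) || S <= U), "S: must be an integer with 0 <= S <= U")
  chk(is_number(delta), "delta: must be a finite number")
  chk(is_number(sigma) && sigma >= 0, "sigma: must be >= 0")
  chk(length(probes_per_gene_range) == 2L &&
        all(vapply(probes_per_gene_range, is_count, logical(1), min = 1L)) &&
        probes_per_gene_range[1] <= probes_per_gene_range[2],
      "probes_per_gene_range: must be an increasing pair of positive integers")
  chk(is_count(samples_per_group, 1L), "samples_per_group: must be >= 1")
  chk(is_fraction(frac_unmapped), "frac_unmapped: must be in [0, 1]")
  chk(is_fraction(frac_many_to_one), "frac_many_to_one: must be in [0, 1]")
  chk(is_fraction(frac_alias), "frac_alias: must be in [0, 1]")
  chk(is.numeric(mouse_experiments) &&
        all(mouse_experiments == as.integer(mouse_experiments)) &&
        (!is_count(k, 1L) || all(mouse_experiments >= 1 & mouse_experiments <= k)),
      "mouse_experiments: indices must lie in 1..k")
  chk(is_count(seed), "seed: must be a non-negative integer")
  if (length(errs)) {
    abort_config(c("invalid synthetic configuration:", setNames(errs, rep("x", length(errs)))))
  }
  structure(
    list(
      U = as.integer(U), k = as.integer(k), S = as.integer(S),
      delta = delta, sigma = sigma,
      probes_per_gene_range = as.integer(probes_per_gene_range),
      samples_per_group = as.integer(samples_per_group),
      frac_unmapped = frac_unmapped, frac_many_to_one = frac_many_to_one,
      frac_alias = frac_alias,
      mouse_experiments = as.integer(mouse_experiments),
      seed = as.integer(seed)
    ),
    class = "regensig_synth_config"
  )
}

# human symbol GENE00042 <-> mouse symbol Gene00042 (paralog b: Gene00042b)
human_symbols <- function(U) sprintf("GENE%05d", seq_len(U))
mouse_of <- function(human) sub("^GENE", "Gene", human)

#' Generate a synthetic multi-platform, two-species study
#'
#' Simulates `k` probe-level two-group experiments over a shared orthologous
#' universe, together with the matching alias table, mouse-to-human ortholog
#' map, term database (one term equal to the planted set plus 20 decoy terms
#' of size 10-50 drawn from non-planted genes) and the ground truth needed to
#' score signature recovery. Intensities are log2-normal: per-gene baseline
#' `N(8, 1)` on the log2 scale, plus `delta` for planted genes in the
#' high-regeneration group, plus `N(0, sigma)` per sample; all probes of a
#' gene share the gene's effect.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `regensig_study`: list with `experiments` (named
#'   list of [expression_experiment()]), `aliases`, `orthologs`, `terms`,
#'   `truth` (class `regensig_truth`: `planted_genes`, `universe`, `config`,
#'   `per_experiment_effect`), and `config`.
#' @export
#' @examples
#' study <- generate_study(synthetic_config(U = 100, S = 5, seed = 42))
#' names(study$experiments)
generate_study <- function(config) {
  if (!inherits(config, "regensig_synth_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  human <- human_symbols(cfg$U)
  planted <- sort(sample(human, cfg$S))
  free <- setdiff(human, planted) # genes eligible for mapping/alias perturbations

  # ortholog map: every gene except an unmapped fraction of non-planted genes;
  # a fraction of mapped genes gains a second mouse paralog
  unmapped <- sample(free, round(cfg$frac_unmapped * length(free)))
  mapped <- setdiff(human, unmapped)
  ortho <- tibble::tibble(
    mouse_symbol = mouse_of(mapped), human_symbol = mapped, source_db = "fixture"
  )
  paralog_of <- sample(mapped, round(cfg$frac_many_to_one * length(mapped)))
  # paste0() recycles zero-length input against "b", so guard the empty case
  paralog_mouse <- if (length(paralog_of)) paste0(mouse_of(paralog_of), "b") else character()
  if (length(paralog_of)) {
    ortho <- dplyr::bind_rows(ortho, tibble::tibble(
      mouse_symbol = paralog_mouse,
      human_symbol = paralog_of, source_db = "fixture"
    ))
  }
  ortho <- dplyr::arrange(ortho, .data$mouse_symbol)

  # alias table: a fraction of non-planted genes appear under an outdated
  # "<symbol>-ALT" alias in the expression tables, both species
  aliased <- sample(free, round(cfg$frac_alias * length(free)))
  alias_of <- function(x, suffix) if (length(x)) paste0(x, suffix) else character()
  aliases <- dplyr::bind_rows(
    tibble::tibble(alias_symbol = alias_of(aliased, "-ALT"),
                   canonical_symbol = aliased, species = rep("human", length(aliased))),
    tibble::tibble(alias_symbol = alias_of(mouse_of(aliased), "-alt"),
                   canonical_symbol = mouse_of(aliased),
                   species = rep("mouse", length(aliased)))
  ) |> dplyr::arrange(.data$species, .data$alias_symbol)

  effect <- setNames(numeric(cfg$U), human)
  effect[planted] <- cfg$delta

  experiments <- list()
  for (e in seq_len(cfg$k)) {
    is_mouse <- e %in% cfg$mouse_experiments
    id <- sprintf("%s_%02d", if (is_mouse) "mouse" else "human", e)
    if (is_mouse) {
      genes <- c(mouse_of(mapped), paralog_mouse)
      gene_effect <- c(effect[mapped], effect[paralog_of])
      alias_lookup <- setNames(alias_of(mouse_of(aliased), "-alt"), mouse_of(aliased))
    } else {
      genes <- human
      gene_effect <- effect[human]
      alias_lookup <- setNames(alias_of(aliased, "-ALT"), aliased)
    }
    n_genes <- length(genes)
    multiplicities <- seq(cfg$probes_per_gene_range[1], cfg$probes_per_gene_range[2])
    n_probes <- if (length(multiplicities) == 1L) {
      rep.int(multiplicities, n_genes)
    } else {
      sample(multiplicities, n_genes, replace = TRUE)
    }
    baseline <- rnorm(n_genes, mean = 8, sd = 1)
    gene_idx <- rep.int(seq_len(n_genes), n_probes)
    total_probes <- length(gene_idx)
    n_samp <- 2L * cfg$samples_per_group
    samples <- sprintf("s%02d", seq_len(n_samp))
    groups <- rep(c("high_regeneration", "low_regeneration"),
                  each = cfg$samples_per_group)
    log2_mu <- outer(baseline[gene_idx], rep(1, n_samp)) +
      outer(gene_effect[gene_idx], as.numeric(groups == "high_regeneration"))
    noise <- matrix(rnorm(total_probes * n_samp, sd = cfg$sigma),
                    nrow = total_probes)
    intensities <- 2^(log2_mu + noise)
    symbols <- genes[gene_idx]
    hit <- symbols %in% names(alias_lookup)
    symbols[hit] <- unname(alias_lookup[symbols[hit]])
    data <- tibble::as_tibble(as.data.frame(intensities))
    names(data) <- samples
    data <- dplyr::bind_cols(
      tibble::tibble(probe_id = sprintf("%s_p%06d", id, seq_len(total_probes)),
                     gene_symbol = symbols),
      data
    )
    experiments[[id]] <- expression_experiment(
      data,
      design = tibble::tibble(sample = samples, group = groups),
      species = if (is_mouse) "mouse" else "human",
      platform = sprintf("synthetic_platform_%02d", e),
      experiment_id = id
    )
  }

  # term database: the planted set plus 20 decoy terms from non-planted genes
  terms <- tibble::tibble(term_id = "TERM000", term_name = "planted_signature",
                          gene_symbol = planted)
  if (cfg$S == 0L) terms <- terms[0, ]
  decoy_pool <- free
  for (t in seq_len(20L)) {
    size <- min(sample(10:50, 1L), length(decoy_pool))
    if (size < 1L) break
    terms <- dplyr::bind_rows(terms, tibble::tibble(
      term_id = sprintf("TERM%03d", t),
      term_name = sprintf("decoy_process_%02d", t),
      gene_symbol = sort(sample(decoy_pool, size))
    ))
  }

  truth <- structure(
    list(planted_genes = planted, universe = human,
         config = cfg, per_experiment_effect = rep(cfg$delta, cfg$k)),
    class = "regensig_truth"
  )
  structure(
    list(experiments = experiments, aliases = aliases, orthologs = ortho,
         terms = terms, truth = truth, config = cfg),
    class = "regensig_study"
  )
}

#' @export
print.regensig_study <- function(x, ...) {
  cat(sprintf(
    "<regensig_study> %d experiments over %d genes; %d planted signature genes (delta = %g, sigma = %g, seed = %d)\n",
    x$config$k, x$config$U, x$config$S, x$config$delta, x$config$sigma, x$config$seed
  ))
  invisible(x)
}

#' Score recovery of the planted signature
#'
#' @param signature A signature (tibble or character vector) drawn from the
#'   truth's universe — e.g. a top-N list or the central overlap.
#' @param truth The `truth` element of a [generate_study()] result.
#' @return One-row tibble: `recall` (= recovered / planted; `NA` when no
#'   genes were planted), `precision` (= recovered / signature size; `NA` for
#'   an empty signature), `n_recovered`, `n_signature`, `n_planted`, and a
#'   `recovered` list-column with the recovered gene symbols.
#' @export
evaluate_recovery <- function(signature, truth) {
  if (!inherits(truth, "regensig_truth")) abort_input("`truth` must be a regensig_truth")
  genes <- unique(sig_genes(signature))
  outside <- setdiff(genes, truth$universe)
  if (length(outside)) {
    abort_input(sprintf(
      "signature gene(s) outside the truth universe: %s",
      paste(head(sort(outside), 5), collapse = ", ")
    ))
  }
  recovered <- sort(intersect(genes, truth$planted_genes))
  S <- length(truth$planted_genes)
  tibble::tibble(
    recall = if (S == 0L) NA_real_ else length(recovered) / S,
    precision = if (length(genes) == 0L) NA_real_ else length(recovered) / length(genes),
    n_recovered = length(recovered),
    n_signature = length(genes),
    n_planted = S,
    recovered = list(recovered)
  )
}

#' Write a synthetic study to disk as plain-text fixtures
#'
#' One expression TSV and one design TSV per experiment, alias and ortholog
#' TSVs, the term database in GMT format, and the truth (planted genes plus
#' the generating configuration) as JSON.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if missing).
#' @return A named list of the written paths, invisibly.
#' @export
write_study_fixtures <- function(study, dir) {
  stopifnot(inherits(study, "regensig_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (id in names(study$experiments)) {
    ex <- study$experiments[[id]]
    p_expr <- file.path(dir, paste0(id, "_expression.tsv"))
    p_des <- file.path(dir, paste0(id, "_design.tsv"))
    readr::write_tsv(ex$data, p_expr, progress = FALSE)
    readr::write_tsv(ex$design, p_des, progress = FALSE)
    paths[[paste0(id, "_expression")]] <- p_expr
    paths[[paste0(id, "_design")]] <- p_des
  }
  paths$aliases <- file.path(dir, "aliases.tsv")
  readr::write_tsv(study$aliases, paths$aliases, progress = FALSE)
  paths$orthologs <- file.path(dir, "orthologs.tsv")
  readr::write_tsv(study$orthologs, paths$orthologs, progress = FALSE)
  paths$terms <- file.path(dir, "terms.gmt")
  write_term_gmt(study$terms, paths$terms)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(planted_genes = study$truth$planted_genes,
         per_experiment_effect = study$truth$per_experiment_effect,
         config = unclass(study$config)),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
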