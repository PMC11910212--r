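# Shared internal helpers: input-error signalling and seed scoping.

abort_input <- function(msg, class = "regensig_input_error") {
  rlang::abort(msg, class = class)
}

abort_config <- function(msg) {
  rlang::abort(msg, class = "regensig_config_error")
}

abort_parse <- function(msg) {
  rlang::abort(msg, class = "regensig_parse_error")
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_fraction <- function(x) {
  is_number(x) && x >= 0 && x <= 1
}

# Extract the ordered gene-symbol vector from a signature in any accepted form:
# a `regensig_signature` tibble, any data frame with a gene_symbol column, or a
# plain character vector.
sig_genes <- function(signature) {
  if (is.data.frame(signature)) {
    if (!"gene_symbol" %in% names(signature)) {
      abort_input("signature data frame must have a `gene_symbol` column")
    }
    as.character(signature$gene_symbol)
  } else if (is.character(signature)) {
    signature
  } else {
    abort_input("signature must be a data frame with `gene_symbol` or a character vector")
  }
}
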