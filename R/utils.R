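# Internal helpers shared across modules.

# Package-level memo cache for fingerprints keyed by
# (dictionary name, mode, canonical SMILES). Fingerprints are pure
# functions of the canonical structure, so memoization is transparent.
.erq_cache <- new.env(parent = emptyenv())

erq_cache_key <- function(dict_name, mode, smiles) {
  paste(dict_name, mode, smiles, sep = "\r")
}

erq_cache_clear <- function() {
  rm(list = ls(.erq_cache, all.names = TRUE), envir = .erq_cache)
  invisible(NULL)
}

abort_erq <- function(msg, class) {
  rlang::abort(msg, class = c(class, "erq_error"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Quietly run an expression that may emit Open Babel chatter on stderr.
quiet_ob <- function(expr) {
  suppressWarnings(suppressMessages(expr))
}

# Parse a Hill-order molecular formula ("C8H10N2O") into a named count vector.
parse_formula <- function(formula) {
  m <- stringr::str_match_all(formula, "([A-Z][a-z]?)([0-9]*)")[[1]]
  m <- m[m[, 2] != "", , drop = FALSE]
  counts <- as.integer(ifelse(m[, 3] == "", "1", m[, 3]))
  stats::setNames(counts, m[, 2])
}
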