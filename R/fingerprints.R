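#' Fingerprint dictionaries and dictionary-based fingerprints
#'
#' A fingerprint dictionary is an ordered list of bit definitions. Each bit
#' is one of three rule kinds: `smarts_presence` (bit set iff at least one
#' embedding of the SMARTS pattern exists; in count mode the value is the
#' number of symmetry-deduplicated embeddings), `smarts_count_at_least`
#' (bit set iff the embedding count reaches `threshold`), or
#' `feature_count_at_least` (named feature — `element:<symbol>`,
#' `element:H`, `ring:any<size>`, `ring:aromatic<size>` — whose count must
#' reach `threshold`). Bit order is part of the contract: index `i` of the
#' dictionary is column `i + 1` of every matrix computed from it.
#'
#' @name fp_dictionary
NULL

new_fp_dictionary <- function(entries, name, prefix) {
  stopifnot(all(c("index", "rule_kind", "pattern", "threshold", "description")
  %in% names(entries)))
  structure(
    entries,
    class = c("erq_fp_dictionary", class(tibble::tibble())),
    dict_name = name,
    bit_prefix = prefix
  )
}

#' @export
print.erq_fp_dictionary <- function(x, ...) {
  cat(sprintf(
    "<fingerprint dictionary '%s': %d bits (%s)>\n",
    attr(x, "dict_name"), nrow(x),
    paste(names(table(x$rule_kind)), table(x$rule_kind),
      sep = "=", collapse = ", "
    )
  ))
  NextMethod()
}

#' Dictionary name and bit names
#' @param dict A fingerprint dictionary.
#' @return `dictionary_name()`: the family name; `bit_names()`: character
#'   vector of per-bit column names (`<prefix><index>`).
#' @export
dictionary_name <- function(dict) attr(dict, "dict_name")

#' @rdname dictionary_name
#' @export
bit_names <- function(dict) {
  paste0(attr(dict, "bit_prefix") %||% "FP", dict$index)
}

#' Load a fingerprint dictionary from a TSV file
#'
#' Format: tab-separated with header `index`, `rule_kind`, `pattern`,
#' `threshold`, `description`; indices must be the contiguous range
#' `0..n-1` (order in the file is the bit order). SMARTS patterns are
#' syntax-checked at load; `validate = "compile"` additionally compiles
#' every pattern through the matcher (slower, catches semantic defects).
#'
#' @param path TSV path.
#' @param name Dictionary name (defaults to the file stem).
#' @param validate `"syntax"` (default) or `"compile"`.
#' @return An `erq_fp_dictionary`.
#' @export
load_fp_dictionary <- function(path, name = NULL,
                               validate = c("syntax", "compile")) {
  validate <- match.arg(validate)
  if (!file.exists(path)) {
    abort_erq(sprintf("dictionary file not found: %s", path), "erq_io_error")
  }
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      index = readr::col_integer(),
      rule_kind = readr::col_character(),
      pattern = readr::col_character(),
      threshold = readr::col_integer(),
      description = readr::col_character()
    ), progress = FALSE
  )
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  validate_dictionary(df, name, validate)
  new_fp_dictionary(df, name = name, prefix = paste0(name, "_"))
}

validate_dictionary <- function(df, name, validate = "syntax") {
  required <- c("index", "rule_kind", "pattern", "threshold", "description")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_erq(
      sprintf("dictionary lacks column(s): %s", paste(missing, collapse = ", ")),
      "erq_dictionary_error"
    )
  }
  if (anyDuplicated(df$index)) {
    dup <- df$index[duplicated(df$index)][1]
    abort_erq(
      sprintf("duplicate bit index %d in dictionary '%s'", dup, name),
      "erq_dictionary_error"
    )
  }
  if (!identical(sort(df$index), seq_len(nrow(df)) - 1L)) {
    abort_erq(
      sprintf("bit indices of '%s' are not contiguous 0..%d", name, nrow(df) - 1L),
      "erq_dictionary_error"
    )
  }
  kinds <- c("smarts_presence", "smarts_count_at_least", "feature_count_at_least")
  bad_kind <- !df$rule_kind %in% kinds
  if (any(bad_kind)) {
    abort_erq(
      sprintf(
        "unknown rule_kind '%s' at index %d",
        df$rule_kind[bad_kind][1], df$index[bad_kind][1]
      ),
      "erq_dictionary_error"
    )
  }
  needs_thr <- df$rule_kind != "smarts_presence"
  if (any(needs_thr & (is.na(df$threshold) | df$threshold < 1))) {
    i <- df$index[needs_thr & (is.na(df$threshold) | df$threshold < 1)][1]
    abort_erq(
      sprintf("threshold must be >= 1 at index %d", i),
      "erq_dictionary_error"
    )
  }
  is_smarts <- df$rule_kind %in% c("smarts_presence", "smarts_count_at_least")
  for (i in which(is_smarts)) {
    lex <- smarts_syntax_ok(df$pattern[i])
    if (!lex$ok) {
      abort_erq(
        sprintf(
          "SMARTS at index %d ('%s') fails to compile: %s",
          df$index[i], df$pattern[i], lex$msg
        ),
        "erq_dictionary_error"
      )
    }
  }
  feat <- df$pattern[df$rule_kind == "feature_count_at_least"]
  bad_feat <- !grepl("^(element:[A-Z][a-z]?|element:H|ring:any[3-9]|ring:aromatic[3-9])$", feat)
  if (any(bad_feat)) {
    abort_erq(
      sprintf("unknown feature name '%s'", feat[bad_feat][1]),
      "erq_dictionary_error"
    )
  }
  if (validate == "compile") {
    probe <- ob_mols("CCO")
    for (i in which(is_smarts)) {
      res <- tryCatch(
        ob_smarts_count(probe, df$pattern[i]),
        error = function(e) NULL
      )
      if (is.null(res)) {
        abort_erq(
          sprintf(
            "SMARTS at index %d ('%s') fails to compile",
            df$index[i], df$pattern[i]
          ),
          "erq_dictionary_error"
        )
      }
    }
  }
  invisible(TRUE)
}

# cheap structural check on a SMARTS string: balanced (), [] and
# paired ring-closure digits
smarts_syntax_ok <- function(p) {
  if (!nzchar(p)) {
    return(list(ok = FALSE, msg = "empty pattern"))
  }
  chars <- strsplit(p, "")[[1]]
  paren <- 0L
  bracket <- FALSE
  rings <- character(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (bracket) {
      if (ch == "]") bracket <- FALSE
      if (ch == "[") return(list(ok = FALSE, msg = "nested '['"))
      next
    }
    if (ch == "[") bracket <- TRUE
    else if (ch == "(") paren <- paren + 1L
    else if (ch == ")") {
      paren <- paren - 1L
      if (paren < 0) return(list(ok = FALSE, msg = "unmatched ')'"))
    } else if (grepl("[0-9]", ch)) {
      if (ch %in% rings) rings <- setdiff(rings, ch) else rings <- c(rings, ch)
    }
  }
  if (bracket) return(list(ok = FALSE, msg = "unclosed '['"))
  if (paren != 0) return(list(ok = FALSE, msg = "unclosed '('"))
  if (length(rings) > 0) {
    return(list(ok = FALSE, msg = sprintf("unclosed ring bond %s", rings[1])))
  }
  list(ok = TRUE, msg = "")
}

#' Write a fingerprint dictionary to its TSV interchange format
#' @param dict An `erq_fp_dictionary`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fp_dictionary <- function(dict, path) {
  readr::write_tsv(tibble::as_tibble(dict), path, progress = FALSE)
  invisible(path)
}

#' Compute dictionary fingerprints for a set of structures
#'
#' Computes the fingerprint vector of every structure against an ordered
#' dictionary, in presence (0/1) or count mode. Matching is performed on
#' the canonical standardized form, so fingerprints are invariant to the
#' SMILES spelling of a structure. Embedding counts are deduplicated over
#' automorphic matches (unique atom sets), so a count is a substructure
#' occurrence count, not a raw match enumeration. Aromaticity follows the
#' Open Babel perception model for molecules and patterns alike.
#' `feature_count_at_least` bits are threshold indicators (0/1) in both
#' modes.
#'
#' @param data A tibble with a SMILES column, or a character vector of
#'   SMILES.
#' @param dictionary An `erq_fp_dictionary` (see [builtin_dictionary()],
#'   [load_fp_dictionary()]).
#' @param mode `"presence"` (default) or `"count"`.
#' @param smiles_col,id_col Column names when `data` is a tibble.
#' @param standardized Set `TRUE` when the SMILES are already the package's
#'   canonical form (skips re-standardization).
#' @return A feature-matrix tibble: `compound_id` plus one integer column
#'   per bit (named `<prefix><index>`), rows in input order. Dictionary
#'   name and mode are attached as attributes `"dictionary"` and `"mode"`.
#' @export
compute_fingerprints <- function(data, dictionary,
                                 mode = c("presence", "count"),
                                 smiles_col = "smiles_canonical",
                                 id_col = "compound_id",
                                 standardized = FALSE) {
  mode <- match.arg(mode)
  if (!inherits(dictionary, "erq_fp_dictionary")) {
    abort_erq("dictionary must be an erq_fp_dictionary", "erq_state_error")
  }
  if (is.character(data)) {
    data <- tibble::tibble(
      compound_id = paste0("mol", seq_along(data)),
      smiles = data
    )
    smiles_col <- "smiles"
    id_col <- "compound_id"
  }
  if (nrow(data) == 0) {
    abort_erq("no structures to fingerprint", "erq_empty_error")
  }
  if (!smiles_col %in% names(data)) {
    # fall back to raw smiles column
    if ("smiles" %in% names(data)) smiles_col <- "smiles" else {
      abort_erq(
        sprintf("no '%s' column in input", smiles_col), "erq_schema_error"
      )
    }
  }
  smiles <- data[[smiles_col]]
  ids <- data[[id_col]] %||% paste0("mol", seq_len(nrow(data)))

  if (standardized || smiles_col == "smiles_canonical") {
    canonical <- smiles
  } else {
    std <- standardize_molecules(smiles, id = ids, on_error = "abort")
    canonical <- std$smiles_canonical
  }

  vecs <- fingerprint_vectors(canonical, dictionary, mode)
  mat <- do.call(rbind, vecs)
  colnames(mat) <- bit_names(dictionary)
  out <- dplyr::bind_cols(
    tibble::tibble(compound_id = ids),
    tibble::as_tibble(mat)
  )
  attr(out, "dictionary") <- dictionary_name(dictionary)
  attr(out, "mode") <- mode
  out
}

# per-structure fingerprint vectors with package-level memoization
fingerprint_vectors <- function(canonical, dictionary, mode) {
  dname <- dictionary_name(dictionary)
  keys <- erq_cache_key(dname, mode, canonical)
  cached <- purrr::map(keys, ~ .erq_cache[[.x]])
  todo <- which(purrr::map_lgl(cached, is.null))
  if (length(todo) > 0) {
    uniq <- unique(canonical[todo])
    computed <- fingerprint_block(uniq, dictionary, mode)
    for (i in seq_along(uniq)) {
      assign(erq_cache_key(dname, mode, uniq[i]), computed[i, ],
        envir = .erq_cache
      )
    }
    cached[todo] <- purrr::map(
      canonical[todo],
      ~ computed[match(.x, uniq), ]
    )
  }
  cached
}

# uncached block computation: one SMARTS pass per pattern over the set
fingerprint_block <- function(smiles, dictionary, mode) {
  mols <- ob_mols(smiles)
  n <- length(smiles)
  out <- matrix(0L, nrow = n, ncol = nrow(dictionary))

  is_smarts <- dictionary$rule_kind %in%
    c("smarts_presence", "smarts_count_at_least")
  patterns <- unique(dictionary$pattern[is_smarts])
  counts <- matrix(0L, nrow = n, ncol = length(patterns),
    dimnames = list(NULL, patterns)
  )
  for (p in patterns) {
    counts[, p] <- ob_smarts_count(mols, p)
  }

  needs_features <- any(dictionary$rule_kind == "feature_count_at_least")
  if (needs_features) {
    feats <- feature_counts(mols, dictionary)
  }

  for (j in seq_len(nrow(dictionary))) {
    kind <- dictionary$rule_kind[j]
    if (kind == "smarts_presence") {
      cnt <- counts[, dictionary$pattern[j]]
      out[, j] <- if (mode == "presence") as.integer(cnt > 0) else cnt
    } else if (kind == "smarts_count_at_least") {
      out[, j] <- as.integer(
        counts[, dictionary$pattern[j]] >= dictionary$threshold[j]
      )
    } else {
      out[, j] <- as.integer(
        feats[[dictionary$pattern[j]]] >= dictionary$threshold[j]
      )
    }
  }
  out
}

# named feature counts (elements, H, ring sizes) for every molecule
feature_counts <- function(mols, dictionary) {
  feat_names <- unique(
    dictionary$pattern[dictionary$rule_kind == "feature_count_at_least"]
  )
  props <- ob_props(mols)
  formulas <- purrr::map(props$formula, parse_formula)
  res <- list()
  for (f in feat_names) {
    if (startsWith(f, "element:")) {
      sym <- sub("^element:", "", f)
      res[[f]] <- purrr::map_int(formulas, function(fm) {
        v <- fm[sym]
        if (is.na(v)) 0L else as.integer(v)
      })
    } else {
      sz <- as.integer(stringr::str_extract(f, "[0-9]+$"))
      aromatic <- startsWith(f, "ring:aromatic")
      atom <- if (aromatic) "a" else "*"
      ring_smarts <- paste0(
        atom, "1", paste(rep(atom, sz - 1L), collapse = ""), "1"
      )
      res[[f]] <- ob_smarts_count(mols, ring_smarts)
    }
  }
  res
}

# ---- Open Babel molecule helpers ------------------------------------------

# parse SMILES into a list of OBMol handles; errors if any molecule is lost
ob_mols <- function(smiles) {
  mols <- quiet_ob(ChemmineOB::forEachMol(
    "SMILES", paste(smiles, collapse = "\n"), identity
  ))
  if (length(mols) != length(smiles)) {
    abort_erq(
      sprintf(
        "structure parsing dropped %d of %d molecules",
        length(smiles) - length(mols), length(smiles)
      ),
      "erq_parse_error"
    )
  }
  mols
}

# symmetry-deduplicated SMARTS occurrence counts over an OBMol list
ob_smarts_count <- function(mols, pattern) {
  as.integer(quiet_ob(
    ChemmineOB::smartsSearch_OB(mols, pattern, uniqueMatches = TRUE)
  ))
}

ob_props <- function(mols) {
  quiet_ob(do.call(rbind, lapply(mols, ChemmineOB::prop_OB)))
}
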