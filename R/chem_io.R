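#' Parse and standardize SMILES structures
#'
#' Validates SMILES syntax, strips salts/counter-ions by keeping the largest
#' organic fragment, applies the package's canonical normalization (Open
#' Babel canonical SMILES, rule set `"openbabel-canonical/1"`), and returns
#' one row per input structure.
#'
#' Standardization is idempotent: feeding the returned canonical SMILES back
#' in reproduces it exactly. Multi-fragment inputs (dot-disconnected salts)
#' are reduced to a single fragment: the one with the most heavy atoms,
#' preferring fragments that contain carbon; ties are broken by molecular
#' weight, then by lexicographic canonical SMILES. Stereochemistry markers
#' are preserved in the canonical form but play no role in substructure
#' fingerprint matching, which is constitution-only.
#'
#' @param smiles Character vector of SMILES strings.
#' @param id Optional character vector of compound identifiers (recycled
#'   names `mol1..moln` when omitted).
#' @param on_error `"abort"` (default) stops at the first bad structure;
#'   `"keep"` returns the row with `NA` canonical SMILES and the message in
#'   the `error` column; `"drop"` silently removes failing rows.
#' @return A tibble with columns `id`, `smiles_input`, `smiles_canonical`,
#'   `atom_count` (heavy atoms of the standardized structure),
#'   `fragment_count_input`, and `error` (`NA` for clean rows).
#' @examples
#' \donttest{
#' standardize_molecules(c("CCO", "OCC", "[Na+].CC(=O)[O-]"))
#' }
#' @export
standardize_molecules <- function(smiles, id = NULL,
                                  on_error = c("abort", "keep", "drop")) {
  on_error <- match.arg(on_error)
  if (length(smiles) == 0) {
    abort_erq("no SMILES supplied", "erq_parse_error")
  }
  id <- id %||% paste0("mol", seq_along(smiles))
  stopifnot(length(id) == length(smiles))

  rows <- purrr::map2(smiles, id, function(s, i) {
    res <- tryCatch(parse_and_standardize(s),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      tibble::tibble(
        id = i, smiles_input = s, smiles_canonical = NA_character_,
        atom_count = NA_integer_, fragment_count_input = NA_integer_,
        error = res
      )
    } else {
      tibble::tibble(
        id = i, smiles_input = s, smiles_canonical = res$smiles_canonical,
        atom_count = res$atom_count,
        fragment_count_input = res$fragment_count_input,
        error = NA_character_
      )
    }
  })
  out <- dplyr::bind_rows(rows)

  bad <- !is.na(out$error)
  if (any(bad) && on_error == "abort") {
    first <- which(bad)[1]
    abort_erq(
      sprintf(
        "structure %s ('%s') failed standardization: %s",
        out$id[first], out$smiles_input[first], out$error[first]
      ),
      "erq_parse_error"
    )
  }
  if (on_error == "drop") out <- out[!bad, , drop = FALSE]
  out
}

#' Standardize a single SMILES string
#'
#' Low-level single-structure worker behind [standardize_molecules()];
#' errors on invalid notation, naming the offending token position where the
#' defect is lexical (unclosed rings, unbalanced brackets or branches,
#' foreign characters).
#'
#' @param smiles A single SMILES string.
#' @return A list with `smiles_canonical`, `atom_count`,
#'   `fragment_count_input`.
#' @export
parse_and_standardize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
    !nzchar(trimws(smiles))) {
    abort_erq("empty SMILES", "erq_parse_error")
  }
  smiles <- trimws(smiles)
  memo_key <- paste0("std\r", smiles)
  hit <- .erq_cache[[memo_key]]
  if (!is.null(hit)) {
    return(hit)
  }
  lex <- smiles_lex(smiles)
  if (!lex$ok) {
    abort_erq(
      sprintf("invalid SMILES '%s': %s at position %d", smiles, lex$msg, lex$pos),
      "erq_parse_error"
    )
  }

  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0) {
    abort_erq("empty after salt stripping", "erq_standardize_error")
  }

  info <- purrr::map(frags, function(f) {
    fl <- smiles_lex(f)
    list(
      frag = f, heavy = fl$heavy_atoms, organic = fl$has_carbon,
      can = ob_canonical(f)
    )
  })
  parsed_ok <- purrr::map_lgl(info, ~ !is.na(.x$can))
  if (!all(parsed_ok)) {
    bad <- info[[which(!parsed_ok)[1]]]$frag
    abort_erq(
      sprintf("invalid SMILES: fragment '%s' not parseable", bad),
      "erq_parse_error"
    )
  }

  keep <- info[[pick_largest_fragment(info)]]
  # re-canonicalize the kept fragment so output is a fixed point
  can <- ob_canonical(keep$frag)
  if (is.na(can) || !nzchar(can)) {
    abort_erq("empty after salt stripping", "erq_standardize_error")
  }
  out <- list(
    smiles_canonical = can,
    atom_count = smiles_lex(can)$heavy_atoms,
    fragment_count_input = length(frags)
  )
  assign(memo_key, out, envir = .erq_cache)
  out
}

# Index of the preferred (largest organic) fragment: most heavy atoms,
# carbon-containing preferred, ties by MW then lexicographic canonical SMILES.
pick_largest_fragment <- function(info) {
  heavy <- purrr::map_int(info, "heavy")
  organic <- purrr::map_lgl(info, "organic")
  cans <- purrr::map_chr(info, "can")
  cand <- which(organic == max(organic))
  cand <- cand[heavy[cand] == max(heavy[cand])]
  if (length(cand) > 1) {
    mw <- purrr::map_dbl(cand, function(i) ob_molwt(info[[i]]$frag))
    cand <- cand[mw == max(mw)]
  }
  if (length(cand) > 1) cand <- cand[order(cans[cand])][1]
  cand[1]
}

# Canonical SMILES via Open Babel; NA when unparseable.
ob_canonical <- function(smiles) {
  out <- tryCatch(
    quiet_ob(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) ""
  )
  out <- sub("\t.*$", "", sub("\n.*$", "", out))
  out <- trimws(out)
  if (!nzchar(out)) NA_character_ else out
}

ob_molwt <- function(smiles) {
  p <- tryCatch(ob_props(ob_mols(smiles)), error = function(e) NULL)
  if (is.null(p)) NA_real_ else p$MW[1]
}

# Minimal SMILES lexer: validates bracket/branch/ring-closure balance and the
# character vocabulary, and counts heavy atoms and carbon presence in the
# same pass. Open Babel silently repairs some malformed strings, so this
# runs first to reject them with a position.
smiles_lex <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  heavy <- 0L
  has_c <- FALSE
  depth_stack <- integer(0)
  ring_open <- list() # ring number -> position opened
  fail <- function(msg, pos) {
    list(ok = FALSE, msg = msg, pos = pos, heavy_atoms = heavy, has_carbon = has_c)
  }
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) return(fail("unclosed atom bracket '['", i))
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!nzchar(body)) return(fail("empty atom bracket", i))
      sym <- stringr::str_match(body, "^[0-9]*([A-Za-z][a-z]?|\\*)")[, 2]
      if (is.na(sym)) return(fail("no element symbol in bracket", i))
      if (!identical(sym, "H")) heavy <- heavy + 1L
      if (sym %in% c("C", "c")) has_c <- TRUE
      i <- j + 1L
    } else if (ch %in% c("C", "c") && i < n && chars[i + 1L] == "l" && ch == "C") {
      heavy <- heavy + 1L # Cl
      i <- i + 2L
    } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
      heavy <- heavy + 1L # Br
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                         "b", "c", "n", "o", "s", "p", "*")) {
      heavy <- heavy + 1L
      if (ch %in% c("C", "c")) has_c <- TRUE
      i <- i + 1L
    } else if (ch == "(") {
      depth_stack <- c(depth_stack, i)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(depth_stack) == 0) return(fail("unmatched ')'", i))
      depth_stack <- depth_stack[-length(depth_stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n || !grepl("^[0-9]{2}$", paste(chars[i + 1L:2L], collapse = ""))) {
          return(fail("malformed %-ring closure", i))
        }
        num <- paste(chars[i + 1L:2L], collapse = "")
        i <- i + 3L
      } else {
        num <- ch
        i <- i + 1L
      }
      if (heavy == 0L) return(fail("ring closure before any atom", i - 1L))
      if (!is.null(ring_open[[num]])) {
        ring_open[[num]] <- NULL
      } else {
        ring_open[[num]] <- i - 1L
      }
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "~", ".", "@", "+")) {
      i <- i + 1L
    } else {
      return(fail(sprintf("unexpected character '%s'", ch), i))
    }
  }
  if (length(depth_stack) > 0) {
    return(fail("unclosed branch '('", depth_stack[length(depth_stack)]))
  }
  if (length(ring_open) > 0) {
    pos <- min(unlist(ring_open))
    return(fail(
      sprintf("unclosed ring bond %s", names(ring_open)[1]), pos
    ))
  }
  if (heavy == 0L) return(fail("no atoms", 1L))
  list(ok = TRUE, msg = "", pos = NA_integer_, heavy_atoms = heavy, has_carbon = has_c)
}

#' Read a ChEMBL-style activity table
#'
#' Reads a delimited text export with the five required columns
#' `compound_id`, `smiles`, `standard_type`, `standard_value`,
#' `standard_units` (comma- or tab-delimited, sniffed from the header).
#' Rows missing any of SMILES, value, or units are dropped and counted in
#' the attached drop report.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @return A tibble of activity records with columns `compound_id`,
#'   `smiles`, `standard_type`, `standard_value`, `standard_units`; the
#'   drop report is attached as attribute `"drop_report"` (retrieve with
#'   [drop_report()]).
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) {
    abort_erq(sprintf("activity table not found: %s", path), "erq_io_error")
  }
  header <- readLines(path, n = 1L)
  delim <- if (stringr::str_count(header, "\t") >
    stringr::str_count(header, ",")) "\t" else ","
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  names(raw) <- tolower(names(raw))
  required <- c(
    "compound_id", "smiles", "standard_type", "standard_value",
    "standard_units"
  )
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_erq(
      sprintf(
        "activity table lacks required column(s): %s",
        paste(missing, collapse = ", ")
      ),
      "erq_schema_error"
    )
  }
  raw <- raw[required]
  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  drop_smiles <- blank(raw$smiles)
  drop_value <- blank(raw$standard_value) |
    is.na(suppressWarnings(as.numeric(raw$standard_value)))
  drop_units <- blank(raw$standard_units)
  dropped <- drop_smiles | drop_value | drop_units
  out <- raw[!dropped, , drop = FALSE]
  out$standard_value <- as.numeric(out$standard_value)
  out <- tibble::as_tibble(out)
  attr(out, "drop_report") <- tibble::tibble(
    n_read = nrow(raw),
    n_kept = nrow(out),
    n_dropped = sum(dropped),
    n_missing_smiles = sum(drop_smiles),
    n_missing_value = sum(drop_value),
    n_missing_units = sum(drop_units)
  )
  out
}

#' Retrieve the row-drop report attached to a read activity table
#' @param x A tibble returned by [read_activity_table()].
#' @return One-row tibble of read/kept/dropped counts.
#' @export
drop_report <- function(x) {
  attr(x, "drop_report") %||%
    abort_erq("no drop report attached to this object", "erq_state_error")
}

#' Write an activity table
#' @param data Activity tibble (five standard columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read a .smi structure list
#'
#' One structure per line: SMILES, optionally followed by whitespace and an
#' identifier. Blank identifiers become `mol<row>`.
#'
#' @param path Path to a `.smi` file.
#' @return Tibble with columns `compound_id`, `smiles`.
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) {
    abort_erq(sprintf("SMILES file not found: %s", path), "erq_io_error")
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    abort_erq("SMILES file is empty", "erq_io_error")
  }
  parts <- stringr::str_split_fixed(lines, "\\s+", 2)
  ids <- ifelse(nzchar(parts[, 2]), parts[, 2], paste0("mol", seq_along(lines)))
  tibble::tibble(compound_id = ids, smiles = parts[, 1])
}

#' Write a .smi structure list
#' @param data Tibble with `smiles` and optionally `compound_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(data, path) {
  ids <- data$compound_id %||% paste0("mol", seq_len(nrow(data)))
  writeLines(paste(data$smiles, ids), path)
  invisible(path)
}
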