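#' Convert IC50 measurements to pIC50
#'
#' pIC50 = -log10(concentration in molar). The activity thresholds used
#' throughout the package (actives below 1 uM, inactives above 10 uM)
#' correspond to pIC50 6 and 5 on this scale.
#'
#' @param value Positive numeric vector of IC50 values.
#' @param units Character vector of units, one of `"nM"`, `"uM"` (or
#'   `"µM"`), `"M"`; recycled against `value`.
#' @return Numeric vector of pIC50 values.
#' @examples
#' to_pic50(1, "uM") # 6
#' to_pic50(10, "uM") # 5
#' @export
to_pic50 <- function(value, units) {
  if (any(!is.finite(value) | value <= 0)) {
    abort_erq("IC50 values must be positive and finite", "erq_domain_error")
  }
  scale <- unit_to_molar(units)
  -log10(value * scale)
}

unit_to_molar <- function(units) {
  u <- tolower(trimws(units))
  u[u == "µm"] <- "um"
  scale <- c(nm = 1e-9, um = 1e-6, m = 1)[u]
  if (any(is.na(scale))) {
    bad <- unique(units[is.na(scale)])
    abort_erq(
      sprintf("unrecognized units: %s", paste(bad, collapse = ", ")),
      "erq_domain_error"
    )
  }
  unname(scale)
}

#' Assign activity class labels from pIC50
#'
#' Strict thresholds: pIC50 strictly above the active threshold (default 6,
#' i.e. IC50 < 1 uM) is `"active"`; strictly below the inactive threshold
#' (default 5, i.e. IC50 > 10 uM) is `"inactive"`; everything in between —
#' including the boundary values themselves — is `"intermediate"` and is
#' excluded from model building by [curate_activity()].
#'
#' @param pic50 Numeric vector of pIC50 values.
#' @param active_threshold pIC50 above which a compound is active (default 6).
#' @param inactive_threshold pIC50 below which a compound is inactive
#'   (default 5).
#' @return Character vector in `{"active", "inactive", "intermediate"}`.
#' @export
label_activity <- function(pic50, active_threshold = 6, inactive_threshold = 5) {
  if (active_threshold <= inactive_threshold) {
    abort_erq(
      "active_threshold must exceed inactive_threshold",
      "erq_config_error"
    )
  }
  if (any(!is.finite(pic50))) {
    abort_erq("pIC50 values must be finite", "erq_domain_error")
  }
  dplyr::case_when(
    pic50 > active_threshold ~ "active",
    pic50 < inactive_threshold ~ "inactive",
    TRUE ~ "intermediate"
  )
}

#' Curate an activity table into a labelled, non-redundant dataset
#'
#' Standardizes structures, converts values to pIC50, aggregates replicate
#' measurements of the same canonical structure (default: median pIC50),
#' drops compounds whose replicates straddle the active and inactive
#' regions (a median could otherwise fabricate a class), labels the rest,
#' and drops intermediates. Counts for every drop pathway are attached as
#' the curation report.
#'
#' @param data Activity tibble as returned by [read_activity_table()]
#'   (columns `compound_id`, `smiles`, `standard_type`, `standard_value`,
#'   `standard_units`).
#' @param activity_type Measurements whose `standard_type` differs (case
#'   insensitively) are dropped and counted. Default `"IC50"`.
#' @param active_threshold,inactive_threshold Passed to [label_activity()].
#' @param duplicate_rule `"median"` (default), `"mean"`, or
#'   `"drop_conflicting"` (any replicated compound is dropped).
#' @param on_parse_error Passed to [standardize_molecules()] as `on_error`;
#'   default `"drop"` (unparseable structures are counted, not fatal).
#' @return A tibble with one row per unique canonical structure: columns
#'   `compound_id`, `smiles`, `smiles_canonical`, `pic50`, `label`
#'   (`active`/`inactive` only), `n_measurements`. The curation report is
#'   attached as attribute `"curation_report"` (see [curation_report()]).
#' @export
curate_activity <- function(data,
                            activity_type = "IC50",
                            active_threshold = 6,
                            inactive_threshold = 5,
                            duplicate_rule = c("median", "mean", "drop_conflicting"),
                            on_parse_error = "drop") {
  duplicate_rule <- match.arg(duplicate_rule)
  if (nrow(data) == 0) {
    abort_erq("empty activity table", "erq_empty_error")
  }

  wrong_type <- tolower(trimws(data$standard_type)) != tolower(activity_type)
  data <- data[!wrong_type, , drop = FALSE]
  if (nrow(data) == 0) {
    abort_erq(
      sprintf("no rows with activity type '%s'", activity_type),
      "erq_empty_error"
    )
  }

  # standardize positionally: compound ids repeat across replicate rows
  std <- standardize_molecules(data$smiles,
    id = data$compound_id,
    on_error = if (on_parse_error == "abort") "abort" else "keep"
  )
  ok <- is.na(std$error)
  n_unparseable <- sum(!ok)
  std <- std[ok, , drop = FALSE]
  data <- data[ok, , drop = FALSE]

  recs <- tibble::tibble(
    compound_id = std$id,
    smiles = std$smiles_input,
    smiles_canonical = std$smiles_canonical,
    pic50 = to_pic50(data$standard_value, data$standard_units)
  )

  # group replicates by canonical structure
  grouped <- recs |>
    dplyr::group_by(.data$smiles_canonical) |>
    dplyr::summarise(
      compound_id = .data$compound_id[1],
      smiles = .data$smiles[1],
      n_measurements = dplyr::n(),
      pic50_agg = if (duplicate_rule == "mean") {
        mean(.data$pic50)
      } else {
        stats::median(.data$pic50)
      },
      any_active = any(.data$pic50 > active_threshold),
      any_inactive = any(.data$pic50 < inactive_threshold),
      .groups = "drop"
    )

  conflict <- grouped$any_active & grouped$any_inactive
  if (duplicate_rule == "drop_conflicting") {
    conflict <- conflict | grouped$n_measurements > 1
  }
  n_conflict <- sum(conflict)
  grouped <- grouped[!conflict, , drop = FALSE]

  grouped$label <- label_activity(
    grouped$pic50_agg, active_threshold, inactive_threshold
  )
  n_intermediate <- sum(grouped$label == "intermediate")
  grouped <- grouped[grouped$label != "intermediate", , drop = FALSE]

  out <- tibble::tibble(
    compound_id = grouped$compound_id,
    smiles = grouped$smiles,
    smiles_canonical = grouped$smiles_canonical,
    pic50 = grouped$pic50_agg,
    label = grouped$label,
    n_measurements = grouped$n_measurements
  )
  if (nrow(out) == 0) {
    abort_erq("curation removed every record", "erq_empty_error")
  }

  attr(out, "curation_report") <- tibble::tibble(
    n_input = length(wrong_type),
    n_wrong_type = sum(wrong_type),
    n_unparseable = n_unparseable,
    n_unique_structures = nrow(grouped) + n_intermediate + n_conflict,
    n_dropped_conflict = n_conflict,
    n_dropped_intermediate = n_intermediate,
    n_active = sum(out$label == "active"),
    n_inactive = sum(out$label == "inactive"),
    duplicate_rule = duplicate_rule,
    active_threshold = active_threshold,
    inactive_threshold = inactive_threshold
  )
  out
}

#' Retrieve the curation report
#' @param x A curated tibble from [curate_activity()].
#' @return One-row tibble of curation counts and settings.
#' @export
curation_report <- function(x) {
  attr(x, "curation_report") %||%
    abort_erq("no curation report attached to this object", "erq_state_error")
}

#' Write the curation report as JSON next to a curated CSV
#' @param x Curated tibble from [curate_activity()].
#' @param csv_path Path for the curated CSV; the report goes to the same
#'   path with extension `.report.json`.
#' @return Invisibly, the two paths written.
#' @export
write_curated <- function(x, csv_path) {
  readr::write_csv(x, csv_path, progress = FALSE)
  report_path <- paste0(sub("\\.csv$", "", csv_path), ".report.json")
  jsonlite::write_json(as.list(curation_report(x)), report_path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv_path, report_path))
}
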