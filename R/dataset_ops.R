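#' Remove constant and near-constant features
#'
#' Drops every feature column whose sample standard deviation falls below
#' `sd_threshold` (default 0.1), the near-constant screen applied to the
#' fingerprint block before model building. Column order of survivors is
#' preserved and the removal record is attached as attribute
#' `"filter_record"`.
#'
#' @param fpmat Feature-matrix tibble (`compound_id` + feature columns), as
#'   from [compute_fingerprints()].
#' @param sd_threshold Features with sample SD strictly below this are
#'   removed. Default 0.1.
#' @return The filtered tibble; retrieve the record with [filter_record()].
#' @export
variance_filter <- function(fpmat, sd_threshold = 0.1) {
  feats <- setdiff(names(fpmat), "compound_id")
  if (nrow(fpmat) < 2) {
    abort_erq("variance filter needs at least 2 rows", "erq_domain_error")
  }
  sds <- purrr::map_dbl(fpmat[feats], stats::sd)
  removed <- feats[sds < sd_threshold]
  retained <- setdiff(feats, removed)
  if (length(retained) == 0) {
    abort_erq(
      sprintf(
        "all %d features fall below SD %.3g; review the threshold",
        length(feats), sd_threshold
      ),
      "erq_filter_error"
    )
  }
  out <- fpmat[c("compound_id", retained)]
  attr(out, "dictionary") <- attr(fpmat, "dictionary")
  attr(out, "mode") <- attr(fpmat, "mode")
  attr(out, "filter_record") <- list(
    sd_threshold = sd_threshold,
    removed_features = removed,
    retained_count = length(retained)
  )
  out
}

#' Retrieve the feature-filter record
#' @param x A filtered feature matrix from [variance_filter()].
#' @return List with `sd_threshold`, `removed_features`, `retained_count`.
#' @export
filter_record <- function(x) {
  attr(x, "filter_record") %||%
    abort_erq("no filter record attached to this object", "erq_state_error")
}

#' Kennard-Stone rational train/test split
#'
#' Deterministic greedy maximin selection in Euclidean descriptor space:
#' the two mutually most distant compounds seed the internal (training)
#' set, then the candidate whose minimum distance to the selected set is
#' largest is added until `ceiling(fraction * n)` compounds are selected.
#' The remainder forms the external (test) set. On binary fingerprint bits
#' Euclidean distance is the square root of the Hamming distance. All ties
#' break on the lowest row index, making the split a pure function of the
#' ordered matrix — no random state is involved.
#'
#' @param fpmat Feature-matrix tibble (`compound_id` + numeric feature
#'   columns).
#' @param fraction Fraction assigned to the internal set, in (0, 1].
#'   Default 0.8.
#' @return A tibble manifest with columns `compound_id` and `partition`
#'   (`"internal"`/`"external"`), ordered internal-first in selection
#'   order; attributes `"internal_ids"` and `"external_ids"` carry the id
#'   lists.
#' @export
kennard_stone_split <- function(fpmat, fraction = 0.8) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
    fraction <= 0 || fraction > 1) {
    abort_erq("fraction must lie in (0, 1]", "erq_config_error")
  }
  feats <- setdiff(names(fpmat), "compound_id")
  x <- as.matrix(fpmat[feats])
  n <- nrow(x)
  if (n < 2) {
    abort_erq("Kennard-Stone needs at least 2 compounds", "erq_domain_error")
  }
  n_internal <- min(n, as.integer(ceiling(fraction * n)))

  d <- as.matrix(stats::dist(x, method = "euclidean"))
  selected <- integer(0)

  # seed: most distant pair; ties -> smallest row index pair
  maxd <- max(d)
  pair <- which(d == maxd, arr.ind = TRUE)
  pair <- pair[order(pmin(pair[, 1], pair[, 2]), pmax(pair[, 1], pair[, 2])), ,
    drop = FALSE
  ]
  selected <- sort(c(pair[1, 1], pair[1, 2]))
  if (n_internal == 1) selected <- selected[1]

  while (length(selected) < n_internal) {
    remaining <- setdiff(seq_len(n), selected)
    mind <- apply(d[remaining, selected, drop = FALSE], 1, min)
    pick <- remaining[which.max(mind)] # which.max returns first on ties
    selected <- c(selected, pick)
  }
  external <- setdiff(seq_len(n), selected)

  ids <- fpmat$compound_id
  out <- tibble::tibble(
    compound_id = c(ids[selected], ids[external]),
    partition = c(
      rep("internal", length(selected)),
      rep("external", length(external))
    )
  )
  attr(out, "fraction") <- fraction
  attr(out, "distance_metric") <- "euclidean"
  attr(out, "internal_ids") <- ids[selected]
  attr(out, "external_ids") <- ids[external]
  out
}

#' Write a split manifest
#' @param split Manifest from [kennard_stone_split()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  readr::write_csv(split, path, progress = FALSE)
  invisible(path)
}
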