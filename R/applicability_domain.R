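#' Fit a PCA bounding-box applicability domain
#'
#' Mean-centred (unscaled) principal component analysis of the internal
#' (training) feature block; the domain is the axis-aligned box spanned by
#' the minimum and maximum internal score on each retained component.
#' Binary fingerprint bits share a scale, so no unit-variance scaling is
#' applied. Membership uses closed intervals, so every internal compound
#' is inside its own domain by construction.
#'
#' @param fpmat Feature-matrix tibble (`compound_id` + feature columns) of
#'   the internal set.
#' @param n_components Number of retained components (default 2, matching
#'   the two-dimensional scores-plot convention).
#' @return An object of class `erq_domain`: loadings, centre, per-component
#'   score intervals, and the internal scores.
#' @export
fit_domain <- function(fpmat, n_components = 2) {
  feats <- setdiff(names(fpmat), "compound_id")
  x <- as.matrix(fpmat[feats])
  if (nrow(x) < 2) {
    abort_erq("domain fitting needs at least 2 compounds", "erq_domain_error")
  }
  if (all(apply(x, 2, function(v) length(unique(v)) == 1))) {
    abort_erq("degenerate internal set: all rows identical", "erq_domain_error")
  }
  rank <- qr(scale(x, center = TRUE, scale = FALSE))$rank
  if (n_components < 1 || n_components > min(ncol(x), nrow(x))) {
    abort_erq(
      sprintf(
        "n_components must be in 1..%d for a %d x %d matrix",
        min(ncol(x), nrow(x)), nrow(x), ncol(x)
      ),
      "erq_config_error"
    )
  }
  n_components <- min(n_components, rank)
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pca$x[, seq_len(n_components), drop = FALSE]
  structure(
    list(
      feature_names = feats,
      center = pca$center,
      loadings = pca$rotation[, seq_len(n_components), drop = FALSE],
      n_components = n_components,
      box = tibble::tibble(
        component = seq_len(n_components),
        lo = unname(apply(scores, 2, min)),
        hi = unname(apply(scores, 2, max))
      ),
      internal_scores = tibble::as_tibble(scores) |>
        dplyr::mutate(compound_id = fpmat$compound_id, .before = 1)
    ),
    class = "erq_domain"
  )
}

#' @export
print.erq_domain <- function(x, ...) {
  cat(sprintf(
    "<PCA bounding-box applicability domain: %d components over %d features>\n",
    x$n_components, length(x$feature_names)
  ))
  print(x$box)
  invisible(x)
}

#' Query the applicability domain
#'
#' Projects query fingerprints onto the domain's components and flags each
#' compound as in-domain iff every retained component score lies in the
#' closed interval `[lo, hi]` observed on the internal set.
#'
#' @param domain An `erq_domain` from [fit_domain()].
#' @param fpmat Feature-matrix tibble with the same (post-filter) feature
#'   columns the domain was fitted on.
#' @return Tibble: `compound_id`, `in_domain`, and one `PC<i>` score
#'   column per retained component.
#' @export
in_domain <- function(domain, fpmat) {
  if (!inherits(domain, "erq_domain")) {
    abort_erq("domain is not an erq_domain", "erq_state_error")
  }
  missing <- setdiff(domain$feature_names, names(fpmat))
  if (length(missing) > 0) {
    abort_erq(
      sprintf(
        "query lacks %d of the domain's features (e.g. %s)",
        length(missing), missing[1]
      ),
      "erq_dimension_error"
    )
  }
  x <- as.matrix(fpmat[domain$feature_names])
  scores <- sweep(x, 2, domain$center) %*% domain$loadings
  inside <- rep(TRUE, nrow(scores))
  for (j in seq_len(domain$n_components)) {
    inside <- inside &
      scores[, j] >= domain$box$lo[j] & scores[, j] <= domain$box$hi[j]
  }
  out <- tibble::as_tibble(scores)
  names(out) <- paste0("PC", seq_len(ncol(scores)))
  dplyr::bind_cols(
    tibble::tibble(
      compound_id = fpmat$compound_id %||% paste0("q", seq_len(nrow(out))),
      in_domain = inside
    ),
    out
  )
}

#' Tidy the applicability-domain box
#' @param x An `erq_domain`.
#' @param ... Unused.
#' @return Tibble of per-component `lo`/`hi` intervals.
#' @exportS3Method generics::tidy
tidy.erq_domain <- function(x, ...) x$box
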