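#' Lipinski rule-of-five profiles
#'
#' Computes molecular weight, an atom-additive octanol-water partition
#' coefficient (Open Babel's Wildman-Crippen-type logP, recorded as
#' `alogp`), and the classic Lipinski hydrogen-bonding counts: `n_hba` is
#' the number of N and O atoms, `n_hbd` the number of hydrogens borne by N
#' and O. `n_violations` counts `mw >= 500`, `alogp >= 5`, `n_hba >= 10`,
#' `n_hbd >= 5` (i.e. the drug-like region is MW < 500, ALogP < 5,
#' acceptors < 10, donors < 5).
#'
#' @param data Tibble with a SMILES column, or character vector of SMILES.
#' @param smiles_col,id_col Column names when `data` is a tibble.
#' @return Tibble: `compound_id`, `mw`, `alogp`, `n_hbd`, `n_hba`,
#'   `n_violations`.
#' @export
ro5_profile <- function(data, smiles_col = "smiles_canonical",
                        id_col = "compound_id") {
  if (is.character(data)) {
    data <- standardize_molecules(data)
    data$compound_id <- data$id
    smiles_col <- "smiles_canonical"
    id_col <- "compound_id"
  }
  if (!smiles_col %in% names(data)) {
    if ("smiles" %in% names(data)) {
      std <- standardize_molecules(data$smiles)
      data[[smiles_col]] <- std$smiles_canonical
    } else {
      abort_erq("no SMILES column in input", "erq_schema_error")
    }
  }
  smiles <- data[[smiles_col]]
  ids <- data[[id_col]] %||% paste0("mol", seq_len(nrow(data)))

  mols <- ob_mols(smiles)
  props <- ob_props(mols)

  # Lipinski donor count: hydrogens on N or O, via total-H SMARTS classes
  h_on <- function(h) {
    ob_smarts_count(mols, sprintf("[#7H%d,#8H%d]", h, h))
  }
  n_hbd <- h_on(1) + 2L * h_on(2) + 3L * h_on(3)
  n_hba <- ob_smarts_count(mols, "[#7,#8]")

  mw <- props$MW
  alogp <- props$logP
  n_violations <- (mw >= 500) + (alogp >= 5) + (n_hba >= 10) + (n_hbd >= 5)
  tibble::tibble(
    compound_id = ids, mw = mw, alogp = alogp,
    n_hbd = n_hbd, n_hba = n_hba, n_violations = as.integer(n_violations)
  )
}

#' Six-parameter descriptive summary
#'
#' Minimum, first quartile, median, mean, third quartile and maximum of a
#' numeric vector. Quartiles use the linear-interpolation convention of
#' `stats::quantile(type = 7)`, the common box-plot default.
#'
#' @param values Numeric vector, `n >= 1` (NAs removed).
#' @return One-row tibble: `min`, `q1`, `median`, `mean`, `q3`, `max`, `n`.
#' @export
summarize_descriptor <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    abort_erq("no values to summarize", "erq_empty_error")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(
    min = min(values), q1 = q[1], median = q[2], mean = mean(values),
    q3 = q[3], max = max(values), n = length(values)
  )
}

#' Mann-Whitney U comparison of two groups
#'
#' U statistic for group `a` against group `b` (number of pairs `(i, j)`
#' with `a_i > b_j`, counting ties one half), with a two-sided p-value. For
#' small samples (`n_a + n_b <= exact_limit`, default 12) the p-value is
#' computed by full enumeration of all rank splits under the null, with
#' mid-rank tie handling; two-sided p = `2 * min(tail, 1 - tail)` capped at
#' 1. Larger samples use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param exact_limit Largest `n_a + n_b` for which exact enumeration runs.
#' @return One-row tibble: `u_statistic`, `p_value`, `method`
#'   (`"exact"`/`"normal_approx"`), `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, exact_limit = 12) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    abort_erq("both groups must be non-empty", "erq_empty_error")
  }
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled) # mid-ranks on ties
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2

  if (na + nb <= exact_limit) {
    p <- exact_mwu_p(r, na, u)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    n <- na + nb
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sigma
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  tibble::tibble(
    u_statistic = u, p_value = p, method = method, n_a = na, n_b = nb
  )
}

# exact two-sided p by enumerating all C(n, na) assignments of the pooled
# mid-ranks to group a
exact_mwu_p <- function(r, na, u_obs) {
  n <- length(r)
  splits <- utils::combn(n, na)
  offset <- na * (na + 1) / 2
  us <- colSums(matrix(r[splits], nrow = na)) - offset
  eps <- 1e-9
  lower <- mean(us <= u_obs + eps)
  upper <- mean(us >= u_obs - eps)
  min(1, 2 * min(lower, upper))
}

#' Compare activity classes across rule-of-five descriptors
#'
#' The chemical-space comparison: for each Ro5 descriptor (MW, ALogP,
#' donor and acceptor counts) and each activity class, the six-parameter
#' summary plus SD, and the Mann-Whitney U test between classes. The
#' dispersion column is the sample standard deviation and is labelled as
#' such.
#'
#' @param profiles Tibble from [ro5_profile()] joined with a `label`
#'   column (`active`/`inactive`).
#' @return Tibble with one row per descriptor x class carrying the summary
#'   columns, `sd`, and the per-descriptor `u_statistic` and `p_value` of
#'   the active-vs-inactive comparison.
#' @export
class_comparison <- function(profiles) {
  if (!"label" %in% names(profiles)) {
    abort_erq("profiles must carry a 'label' column", "erq_schema_error")
  }
  descriptors <- c("mw", "alogp", "n_hbd", "n_hba")
  purrr::map_dfr(descriptors, function(d) {
    act <- profiles[[d]][profiles$label == "active"]
    inact <- profiles[[d]][profiles$label == "inactive"]
    cmp <- compare_groups(act, inact)
    per_class <- purrr::map_dfr(
      list(active = act, inactive = inact),
      function(v) dplyr::mutate(summarize_descriptor(v), sd = stats::sd(v)),
      .id = "label"
    )
    dplyr::mutate(per_class,
      descriptor = d,
      u_statistic = cmp$u_statistic, p_value = cmp$p_value,
      .before = 1
    )
  })
}
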