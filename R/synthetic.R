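#' Specification for a planted-signal synthetic benchmark
#'
#' The generator emulates a curated ChEMBL-style IC50 activity table with a
#' fully known ground truth: active compounds carry a planted substructure
#' motif (by default a 4-methylphenol fragment, one of the feature classes
#' repeatedly flagged as important in estrogen-receptor SAR), inactive
#' compounds are decorated aromatic scaffolds without free phenols. Class
#' pIC50 values are drawn clear of the 6/5 labelling thresholds (means 7.0
#' and 4.0, SD 0.4, resampled to stay strictly above 6 / below 5), so at
#' `label_noise = 0` labelling is unambiguous and the planted motif
#' perfectly separates the classes in fingerprint space.
#'
#' `label_noise` is the probability that a compound's structure is drawn
#' from the other class's grammar while keeping its measured activity —
#' i.e. actives contain the motif with probability `1 - label_noise`.
#'
#' @param n_active,n_inactive Class sizes (default 150 each).
#' @param planted_smarts SMARTS that detects the planted motif.
#' @param label_noise Structure/label discordance rate in `[0, 0.5)`.
#' @param pic50_active_mean,pic50_active_sd,pic50_inactive_mean,pic50_inactive_sd
#'   Class pIC50 distributions.
#' @param seed Integer seed; generation is byte-identical for a fixed spec.
#' @return A list of class `erq_benchmark_spec`.
#' @export
benchmark_spec <- function(n_active = 150L, n_inactive = 150L,
                           planted_smarts = "[OX2H]c1ccc(C)cc1",
                           label_noise = 0,
                           pic50_active_mean = 7.0, pic50_active_sd = 0.4,
                           pic50_inactive_mean = 4.0, pic50_inactive_sd = 0.4,
                           seed = 1L) {
  if (n_active < 1 || n_inactive < 1) {
    abort_erq("class sizes must be at least 1", "erq_config_error")
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    abort_erq("label_noise must lie in [0, 0.5)", "erq_config_error")
  }
  if (!smarts_syntax_ok(planted_smarts)$ok) {
    abort_erq(
      sprintf("planted SMARTS '%s' is invalid", planted_smarts),
      "erq_config_error"
    )
  }
  structure(
    list(
      n_active = as.integer(n_active), n_inactive = as.integer(n_inactive),
      planted_smarts = planted_smarts, label_noise = label_noise,
      pic50_active_mean = pic50_active_mean, pic50_active_sd = pic50_active_sd,
      pic50_inactive_mean = pic50_inactive_mean,
      pic50_inactive_sd = pic50_inactive_sd,
      seed = as.integer(seed)
    ),
    class = "erq_benchmark_spec"
  )
}

# motif-bearing structures: para-hydroxybenzyl fragment plus a tail, so the
# SMARTS Oc1ccc(C)cc1 always embeds
motif_grammar <- function() {
  tails <- c(
    "", "C", "CC", "CCC", "CCCC", "N", "CN", "CNC", "CO", "COC",
    "C(C)C", "CCN", "CCO", "CC(C)C", "CCCN", "CCCC(C)C"
  )
  aryl <- c("", "c2ccccc2", "c2ccncc2", "c2ccsc2")
  ring_sub <- c("", "C", "CC", "Cl", "F", "OC")
  out <- character(0)
  for (t in tails) {
    for (a in aryl) {
      if (t == "" && a != "") next # tail must separate the two rings
      for (s in ring_sub) {
        # para C of the phenol is fixed, so the planted motif always embeds
        out <- c(out, paste0("Oc1ccc(C", t, a, ")cc1", s))
      }
    }
  }
  unique(out)
}

# motif-free structures: substituted aromatic cores, no free aromatic OH
plain_grammar <- function() {
  templates <- c(
    "%sc1ccc(%s)cc1", "%sc1cccc(%s)c1", "%sc1ccnc(%s)c1",
    "%sc1ccc2ccccc2c1%.0s", "%sc1ccsc1%.0s"
  )
  subs <- c(
    "C", "CC", "CCC", "CC(C)", "CCCC", "CO", "CCO", "CN(C)", "N",
    "Cl", "F", "OC", "CC(=O)N", "OCC", "CSC", "CCN"
  )
  out <- character(0)
  for (tm in templates) {
    for (a in subs) {
      for (b in subs) {
        out <- c(out, sprintf(tm, a, b))
      }
    }
  }
  unique(out)
}

#' Generate a synthetic benchmark activity table
#'
#' Draws structures from the scaffold grammar according to the spec,
#' samples class pIC50 values, back-transforms them into IC50 measurements
#' (mostly nM, every third row in uM), and returns the activity table in
#' the standard five-column layout together with the truth manifest. Every
#' emitted SMILES is validated through the standardizer at generation
#' time, so downstream failures always implicate the pipeline, not the
#' fixtures.
#'
#' @param spec A [benchmark_spec()].
#' @return List of class `erq_benchmark`: `activity` (five-column activity
#'   tibble), `truth` (tibble: `compound_id`, `label_true`, `has_motif`,
#'   `pic50_true`), `spec`.
#' @export
generate_benchmark <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "erq_benchmark_spec"))
  set.seed(spec$seed)
  motif_pool <- motif_grammar()
  plain_pool <- plain_grammar()

  n <- spec$n_active + spec$n_inactive
  label <- c(rep("active", spec$n_active), rep("inactive", spec$n_inactive))
  noisy <- stats::runif(n) < spec$label_noise
  use_motif <- (label == "active") != noisy

  smiles <- ifelse(use_motif,
    sample(motif_pool, n, replace = TRUE),
    sample(plain_pool, n, replace = TRUE)
  )

  draw_pic50 <- function(m, s, lower = -Inf, upper = Inf, k) {
    out <- numeric(k)
    for (i in seq_len(k)) {
      repeat {
        v <- stats::rnorm(1, m, s)
        if (v > lower && v < upper) break
      }
      out[i] <- v
    }
    out
  }
  pic50 <- numeric(n)
  pic50[label == "active"] <- draw_pic50(
    spec$pic50_active_mean, spec$pic50_active_sd,
    lower = 6 + 1e-6, k = spec$n_active
  )
  pic50[label == "inactive"] <- draw_pic50(
    spec$pic50_inactive_mean, spec$pic50_inactive_sd,
    upper = 5 - 1e-6, k = spec$n_inactive
  )

  ids <- sprintf("BM%04d", seq_len(n))
  in_um <- seq_len(n) %% 3 == 0
  value <- ifelse(in_um, 10^(6 - pic50), 10^(9 - pic50))
  units <- ifelse(in_um, "uM", "nM")

  activity <- tibble::tibble(
    compound_id = ids, smiles = smiles, standard_type = "IC50",
    standard_value = value, standard_units = units
  )
  # generation-time validation: everything must standardize cleanly
  std <- standardize_molecules(unique(smiles), on_error = "keep")
  if (any(!is.na(std$error))) {
    abort_erq(
      sprintf(
        "generator emitted an unstandardizable SMILES: %s",
        std$smiles_input[!is.na(std$error)][1]
      ),
      "erq_internal_error"
    )
  }
  structure(
    list(
      activity = activity,
      truth = tibble::tibble(
        compound_id = ids, label_true = label,
        has_motif = use_motif, pic50_true = pic50
      ),
      spec = spec
    ),
    class = "erq_benchmark"
  )
}

#' Write a benchmark to disk
#' @param benchmark An `erq_benchmark`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`activity.csv`,
#'   `truth_manifest.json`).
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  act_path <- file.path(dir, "activity.csv")
  truth_path <- file.path(dir, "truth_manifest.json")
  readr::write_csv(benchmark$activity, act_path, progress = FALSE)
  jsonlite::write_json(
    list(
      spec = unclass(benchmark$spec),
      truth = benchmark$truth
    ),
    truth_path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(c(act_path, truth_path))
}

#' Inject replicates, salt forms and unit changes into an activity table
#'
#' Exercises the curation pathways with known ground truth: for a fraction
#' `rate` of rows, appends a replicate row whose value is expressed in the
#' other unit (nM/uM, same measurement), whose SMILES carries a
#' counter-ion, and whose value gets a small multiplicative jitter that
#' cannot cross a class boundary.
#'
#' @param activity Five-column activity tibble.
#' @param rate Fraction of rows to perturb, in `[0, 1]`.
#' @param seed Integer seed.
#' @param jitter_sd SD of the log10 value jitter (default 0.02, well inside
#'   a class region).
#' @return The activity tibble with injected rows appended.
#' @export
inject_duplicates_and_salts <- function(activity, rate, seed = 1L,
                                        jitter_sd = 0.02) {
  if (rate < 0 || rate > 1) {
    abort_erq("rate must lie in [0, 1]", "erq_config_error")
  }
  if (rate == 0) {
    return(activity)
  }
  set.seed(seed)
  n <- nrow(activity)
  pick <- which(stats::runif(n) < rate)
  if (length(pick) == 0) {
    return(activity)
  }
  extra <- activity[pick, , drop = FALSE]
  to_um <- extra$standard_units == "nM"
  extra$standard_value <- ifelse(to_um,
    extra$standard_value / 1000, extra$standard_value * 1000
  )
  extra$standard_units <- ifelse(to_um, "uM", "nM")
  extra$standard_value <- extra$standard_value *
    10^stats::rnorm(length(pick), 0, jitter_sd)
  ions <- c("[Na+]", "Cl", "[K+]")
  extra$smiles <- paste0(
    extra$smiles, ".", sample(ions, length(pick), replace = TRUE)
  )
  dplyr::bind_rows(activity, extra)
}
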