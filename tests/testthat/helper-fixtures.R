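# Shared fixtures, built in code and memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, builder) {
  hit <- .fixture_env[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  val <- builder()
  assign(key, val, envir = .fixture_env)
  val
}

toy_dictionary <- function(patterns, name = "toy") {
  erqsar:::new_fp_dictionary(
    tibble::tibble(
      index = seq_along(patterns) - 1L,
      rule_kind = "smarts_presence",
      pattern = unname(patterns),
      threshold = NA_integer_,
      description = names(patterns) %||% unname(patterns)
    ),
    name = name, prefix = "Toy"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a small labelled activity table exercising all curation paths
tiny_activity <- function() {
  tibble::tibble(
    compound_id = c("a1", "a2", "a2b", "i1", "m1", "c1", "c1b"),
    smiles = c(
      "Oc1ccc(C)cc1", # active
      "CCN(CC)CC", "CCN(CC)CC", # replicate pair, both active
      "c1ccccc1", # inactive
      "CCO", # intermediate
      "CCCCN", "CCCCN" # conflicting replicates
    ),
    standard_type = "IC50",
    standard_value = c(
      10, # 10 nM -> pIC50 8
      100, 160, # ~7.0, 6.8
      50, # 50 uM -> 4.3
      5, # 5 uM -> 5.3
      20, 50 # nM 7.7 / uM 4.3 -> conflict
    ),
    standard_units = c("nM", "nM", "nM", "uM", "uM", "nM", "uM")
  )
}

# small trained dual-target pipeline on the planted-signal benchmark
shared_pipeline <- function() {
  memo_fixture("pipeline", function() {
    bm_a <- generate_benchmark(benchmark_spec(
      n_active = 60, n_inactive = 60, seed = 101
    ))
    bm_b <- generate_benchmark(benchmark_spec(
      n_active = 60, n_inactive = 60, seed = 202
    ))
    cfg <- model_config(
      ntree_grid = c(100L, 200L), mtry_grid = c(4L, 8L), seed = 11
    )
    train_pipeline(bm_a$activity, bm_b$activity,
      dictionary = "demo24", config = cfg
    )
  })
}

shared_benchmark <- function() {
  memo_fixture("benchmark", function() {
    generate_benchmark(benchmark_spec(n_active = 60, n_inactive = 60, seed = 101))
  })
}

# benchmark config used by the end-to-end recovery checks
bench_config <- function(seed) {
  model_config(ntree_grid = c(100L, 200L), mtry_grid = c(4L, 8L), seed = seed)
}

run_benchmark_target <- function(seed, n_active = 150, n_inactive = 150,
                                 label_noise = 0) {
  key <- paste("tgt", seed, n_active, n_inactive, label_noise)
  memo_fixture(key, function() {
    bm <- generate_benchmark(benchmark_spec(
      n_active = n_active, n_inactive = n_inactive,
      label_noise = label_noise, seed = seed
    ))
    train_target(bm$activity,
      dictionary = "demo24",
      config = bench_config(seed), target_name = "bench"
    )
  })
}

# independent greedy-maximin oracle: recomputes distances naively each step
ks_oracle <- function(x, n_internal) {
  n <- nrow(x)
  euc <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  best <- c(NA, NA)
  bestd <- -1
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dij <- euc(i, j)
      if (dij > bestd + 1e-12) {
        bestd <- dij
        best <- c(i, j)
      }
    }
  }
  sel <- sort(best)
  while (length(sel) < n_internal) {
    rem <- setdiff(seq_len(n), sel)
    mind <- vapply(
      rem,
      function(r) min(vapply(sel, function(s) euc(r, s), numeric(1))),
      numeric(1)
    )
    sel <- c(sel, rem[which.max(mind)])
  }
  sel
}
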