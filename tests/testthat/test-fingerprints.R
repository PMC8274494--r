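test_that("shipped dictionary families have the documented cardinalities", {
  expect_equal(nrow(builtin_dictionary("pubchem_synthetic")), 881L)
  expect_equal(nrow(builtin_dictionary("substructure_synthetic")), 307L)
  expect_equal(nrow(builtin_dictionary("maccs_synthetic")), 166L)
  expect_equal(nrow(builtin_dictionary("klekota_roth_synthetic")), 4860L)
  for (nm in c("pubchem_synthetic", "maccs_synthetic")) {
    d <- builtin_dictionary(nm)
    expect_equal(d$index, seq_len(nrow(d)) - 1L)
    expect_false(anyDuplicated(paste(d$rule_kind, d$pattern, d$threshold)) > 0)
  }
})

test_that("dictionary TSV round-trips and bad files are rejected at load", {
  d <- builtin_dictionary("demo24")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fp_dictionary(d, path)
  back <- load_fp_dictionary(path, name = "demo24")
  expect_equal(back$pattern, d$pattern)
  expect_equal(back$index, d$index)

  tab <- tibble::as_tibble(d)
  tab$index[6] <- 3L # duplicate index
  readr::write_tsv(tab, path)
  err <- expect_error(load_fp_dictionary(path), class = "erq_dictionary_error")
  expect_match(conditionMessage(err), "3")

  tab <- tibble::as_tibble(d)
  tab$pattern[3] <- "c1ccc(" # uncompilable
  readr::write_tsv(tab, path)
  err <- expect_error(load_fp_dictionary(path), class = "erq_dictionary_error")
  expect_match(conditionMessage(err), "index 2")
})

test_that("presence bits follow exact substructure semantics", {
  d <- toy_dictionary(c(benzene = "c1ccccc1", oxygen = "[#8]"))
  fp <- compute_fingerprints(c("c1ccccc1", "CC", "c1ccccc1O"), d)
  expect_equal(unname(as.matrix(fp[, -1])),
    matrix(c(1L, 0L, 0L, 0L, 1L, 1L), nrow = 3, byrow = TRUE),
    ignore_attr = TRUE
  )
})

test_that("count mode counts symmetry-deduplicated embeddings", {
  d <- toy_dictionary(c(cc = "C-C"))
  fp <- compute_fingerprints("CCCCCCCC", d, mode = "count")
  expect_equal(fp$Toy0, 7L) # the 7 C-C bonds of octane
  # presence of the same bit is capped at 1
  fp1 <- compute_fingerprints("CCCCCCCC", d, mode = "presence")
  expect_equal(fp1$Toy0, 1L)
})

test_that("count >= presence element-wise across a molecule panel", {
  d <- builtin_dictionary("demo24")
  smi <- c(
    "Oc1ccc(C)cc1", "CCN(CC)CC", "c1ccc2ccccc2c1", "CC(=O)Nc1ccccc1",
    "COc1ccc(CCN)cc1"
  )
  p <- as.matrix(compute_fingerprints(smi, d, mode = "presence")[, -1])
  cnt <- as.matrix(compute_fingerprints(smi, d, mode = "count")[, -1])
  expect_true(all(cnt >= p))
  expect_true(all((cnt > 0) == (p > 0)))
  expect_true(all(p %in% c(0L, 1L)))
})

test_that("fingerprints are invariant to SMILES spelling", {
  d <- builtin_dictionary("demo24")
  a <- compute_fingerprints("Oc1ccc(C)cc1", d)
  b <- compute_fingerprints("Cc1ccc(O)cc1", d)
  expect_equal(as.matrix(a[, -1]), as.matrix(b[, -1]))
})

test_that("feature matrices preserve row and column order", {
  d <- toy_dictionary(c(n = "[#7]", o = "[#8]", arc = "c"))
  smi <- c("CCO", "CCN", "CCO")
  fp <- compute_fingerprints(smi, d)
  expect_equal(names(fp), c("compound_id", "Toy0", "Toy1", "Toy2"))
  expect_equal(nrow(fp), 3L)
  # duplicate molecules give identical rows
  expect_equal(unlist(fp[1, -1]), unlist(fp[3, -1]))
  expect_equal(attr(fp, "dictionary"), "toy")
  expect_error(
    compute_fingerprints(character(0), d),
    class = "erq_empty_error"
  )
})

test_that("feature-count rules threshold element, H and ring counts", {
  dict <- erqsar:::new_fp_dictionary(
    tibble::tibble(
      index = 0:3,
      rule_kind = "feature_count_at_least",
      pattern = c("element:C", "element:H", "ring:any6", "ring:aromatic6"),
      threshold = c(4L, 8L, 1L, 1L),
      description = "t"
    ),
    name = "feat", prefix = "F"
  )
  fp <- compute_fingerprints(
    c("CCCC", "CC", "C1CCCCC1", "c1ccccc1"), dict
  )
  m <- unname(as.matrix(fp[, -1]))
  # butane: 4 C, 10 H, no rings
  expect_equal(m[1, ], c(1L, 1L, 0L, 0L))
  # ethane: 2 C, 6 H
  expect_equal(m[2, ], c(0L, 0L, 0L, 0L))
  # cyclohexane: 6 C, 12 H, one non-aromatic 6-ring
  expect_equal(m[3, ], c(1L, 1L, 1L, 0L))
  # benzene: 6 C, 6 H, aromatic 6-ring (counts as an any-size-6 ring too)
  expect_equal(m[4, ], c(1L, 0L, 1L, 1L))
})

test_that("a sampled subset of every builtin family compiles and evaluates", {
  smi <- c("Oc1ccc(C)cc1", "CC(=O)Nc1ccccc1CCN")
  for (nm in c(
    "pubchem_synthetic", "substructure_synthetic",
    "maccs_synthetic", "klekota_roth_synthetic"
  )) {
    d <- builtin_dictionary(nm)
    set.seed(7)
    idx <- sort(sample(nrow(d), 40))
    sub <- erqsar:::new_fp_dictionary(
      dplyr::mutate(tibble::as_tibble(d)[idx, ], index = seq_along(idx) - 1L),
      name = paste0(nm, "_sub"), prefix = "S"
    )
    fp <- compute_fingerprints(smi, sub)
    expect_equal(dim(fp), c(2L, 41L))
    expect_true(all(as.matrix(fp[, -1]) %in% 0:1))
  }
})
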