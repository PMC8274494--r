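fp_tbl <- function(mat, ids = NULL) {
  colnames(mat) <- paste0("F", seq_len(ncol(mat)))
  dplyr::bind_cols(
    tibble::tibble(compound_id = ids %||% paste0("c", seq_len(nrow(mat)))),
    tibble::as_tibble(mat)
  )
}

test_that("variance filter removes constants and rare bits, keeps balanced", {
  set.seed(1)
  n <- 200
  mat <- cbind(
    rep(1, n), # constant -> SD 0, removed
    rep(c(0, 1), n / 2), # balanced -> SD ~0.5, retained
    c(1, rep(0, n - 1)) # 1-in-200 -> SD ~0.0707, removed
  )
  expect_equal(sd(mat[, 3]), sqrt(1 / 200 * (1 - 1 / 200) * n / (n - 1)),
    tolerance = 1e-12
  )
  filt <- variance_filter(fp_tbl(mat), sd_threshold = 0.1)
  expect_equal(setdiff(names(filt), "compound_id"), "F2")
  rec <- filter_record(filt)
  expect_setequal(rec$removed_features, c("F1", "F3"))
  expect_equal(rec$retained_count, 1L)
  expect_equal(rec$retained_count + length(rec$removed_features), 3L)
})

test_that("variance filter errors when nothing survives", {
  mat <- matrix(1, nrow = 10, ncol = 3)
  expect_error(variance_filter(fp_tbl(mat)), class = "erq_filter_error")
})

test_that("Kennard-Stone seeds with the farthest pair", {
  mat <- matrix(c(0, 1, 10), ncol = 1)
  split <- kennard_stone_split(fp_tbl(mat), fraction = 2 / 3)
  expect_setequal(attr(split, "internal_ids"), c("c1", "c3"))
  expect_equal(attr(split, "external_ids"), "c2")
})

test_that("fraction 1 selects everything; bad fractions error", {
  mat <- matrix(rnorm(20), ncol = 2)
  split <- kennard_stone_split(fp_tbl(mat), fraction = 1)
  expect_equal(length(attr(split, "internal_ids")), 10L)
  expect_equal(length(attr(split, "external_ids")), 0L)
  expect_error(kennard_stone_split(fp_tbl(mat), fraction = 0),
    class = "erq_config_error"
  )
  expect_error(kennard_stone_split(fp_tbl(mat), fraction = 1.2),
    class = "erq_config_error"
  )
})

test_that("selection equals the exhaustive greedy-maximin oracle", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    d <- sample(1:5, 1)
    x <- matrix(sample(0:1, n * d, replace = TRUE), ncol = d)
    # ensure no duplicate rows confuse the tie-break comparison
    x <- x + matrix(runif(n * d, 0, 1e-6), ncol = d)
    frac <- runif(1, 0.3, 0.9)
    n_int <- ceiling(frac * n)
    split <- kennard_stone_split(fp_tbl(x), fraction = frac)
    oracle <- ks_oracle(x, n_int)
    expect_equal(attr(split, "internal_ids"), paste0("c", oracle))
  }
})

test_that("split is deterministic and permutation-invariant as a set", {
  set.seed(7)
  x <- matrix(rnorm(30 * 4), ncol = 4)
  tbl <- fp_tbl(x)
  s1 <- kennard_stone_split(tbl, 0.8)
  s2 <- kennard_stone_split(tbl, 0.8)
  expect_identical(s1, s2)
  perm <- sample(nrow(tbl))
  s3 <- kennard_stone_split(tbl[perm, ], 0.8)
  expect_setequal(attr(s1, "internal_ids"), attr(s3, "internal_ids"))
})

test_that("every external point lies close to the internal set (maximin cover)", {
  set.seed(13)
  x <- matrix(rnorm(40 * 3), ncol = 3)
  tbl <- fp_tbl(x)
  split <- kennard_stone_split(tbl, 0.8)
  int_idx <- match(attr(split, "internal_ids"), tbl$compound_id)
  ext_idx <- match(attr(split, "external_ids"), tbl$compound_id)
  d <- as.matrix(dist(x))
  # distance from the last-added internal point to its predecessors
  last <- int_idx[length(int_idx)]
  last_gap <- min(d[last, int_idx[-length(int_idx)]])
  ext_gaps <- apply(d[ext_idx, int_idx, drop = FALSE], 1, min)
  expect_true(all(ext_gaps <= last_gap + 1e-12))
})

test_that("filtering then splitting composes without hidden reordering", {
  set.seed(3)
  mat <- cbind(
    matrix(sample(0:1, 30 * 5, replace = TRUE), ncol = 5),
    rep(1, 30) # constant column
  )
  tbl <- fp_tbl(mat)
  filtered <- variance_filter(tbl)
  s_direct <- kennard_stone_split(filtered, 0.8)
  manual <- tbl[, c("compound_id", paste0("F", 1:5))]
  s_manual <- kennard_stone_split(manual, 0.8)
  expect_equal(s_direct$compound_id, s_manual$compound_id)
  expect_equal(filtered$compound_id, tbl$compound_id)
})
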