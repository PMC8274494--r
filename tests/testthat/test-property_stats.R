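test_that("Ro5 profile matches hand-computed ethanol and methane values", {
  p <- ro5_profile(c("CCO", "C"))
  # ethanol: C2H6O from standard atomic masses
  expect_equal(p$mw[1], 2 * 12.011 + 6 * 1.008 + 15.999, tolerance = 1e-3)
  expect_equal(p$n_hbd[1], 1L) # the O-H hydrogen
  expect_equal(p$n_hba[1], 1L) # the single oxygen
  expect_equal(p$n_violations[1], 0L)
  # methane: no N/O at all
  expect_equal(p$n_hbd[2], 0L)
  expect_equal(p$n_hba[2], 0L)
})

test_that("Ro5 violations use the 500/5/10/5 cutoffs", {
  # triacontane C30H62: MW ~423, logP far above 5 -> exactly 1 violation
  big <- paste(rep("C", 30), collapse = "")
  p <- ro5_profile(big)
  expect_true(p$alogp >= 5)
  expect_equal(p$n_violations, 1L)
  # glucose: 5 OH donors, 6 O acceptors -> donor violation only
  glu <- ro5_profile("OCC1OC(O)C(O)C(O)C1O")
  expect_equal(glu$n_hbd, 5L)
  expect_equal(glu$n_hba, 6L)
  expect_equal(glu$n_violations, 1L)
})

test_that("Ro5 profile is invariant to SMILES spelling", {
  a <- ro5_profile("Oc1ccc(C)cc1")
  b <- ro5_profile("Cc1ccc(O)cc1")
  expect_equal(a[, -1], b[, -1])
})

test_that("six-parameter summaries are exact on closed-form cases", {
  s <- summarize_descriptor(1:5)
  expect_equal(
    unlist(s),
    c(min = 1, q1 = 2, median = 3, mean = 3, q3 = 4, max = 5, n = 5)
  )
  s1 <- summarize_descriptor(7)
  expect_true(all(unlist(s1[1:6]) == 7))
  s2 <- summarize_descriptor(c(1, 1, 1, 9))
  expect_equal(s2$mean, 3)
  expect_equal(s2$median, 1)
  expect_true(s2$min <= s2$q1 && s2$q1 <= s2$median &&
    s2$median <= s2$q3 && s2$q3 <= s2$max)
  expect_error(summarize_descriptor(numeric(0)), class = "erq_empty_error")
})

test_that("Mann-Whitney U and exact p match full enumeration", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$method, "exact")
  # the lower tail is 1/20 of the C(6,3) splits; two-sided doubles it
  expect_equal(r$p_value, 2 * 1 / 20)

  # identical multisets: U = n^2/2, p = 1
  r2 <- compare_groups(c(2, 4, 9), c(2, 4, 9))
  expect_equal(r2$u_statistic, 9 / 2)
  expect_equal(r2$p_value, 1)

  expect_error(compare_groups(numeric(0), 1), class = "erq_empty_error")
})

test_that("exact p agrees with wilcox.test on tie-free small samples", {
  set.seed(5)
  for (i in 1:25) {
    na <- sample(2:6, 1)
    nb <- sample(2:6, 1)
    vals <- sample(1:100, na + nb) # distinct -> tie-free
    a <- vals[seq_len(na)]
    b <- vals[-seq_len(na)]
    mine <- compare_groups(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(mine$u_statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("U statistics of the two orderings sum to n_a * n_b", {
  set.seed(11)
  for (i in 1:20) {
    na <- sample(2:8, 1)
    nb <- sample(2:8, 1)
    a <- rnorm(na)
    b <- rnorm(nb)
    if (i %% 3 == 0) b[1] <- a[1] # inject ties sometimes
    expect_equal(
      compare_groups(a, b)$u_statistic + compare_groups(b, a)$u_statistic,
      na * nb
    )
  }
})

test_that("normal approximation tracks the exact p on 6+6 samples", {
  set.seed(9)
  for (i in 1:15) {
    vals <- sample(1:1000, 12)
    a <- vals[1:6]
    b <- vals[7:12]
    p_exact <- compare_groups(a, b, exact_limit = 12)$p_value
    p_norm <- compare_groups(a, b, exact_limit = 0)$p_value
    expect_equal(compare_groups(a, b, exact_limit = 0)$method, "normal_approx")
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("class comparison emits summaries and tests per descriptor", {
  profiles <- dplyr::bind_rows(
    dplyr::mutate(ro5_profile(c(
      "Oc1ccc(C)cc1", "Oc1ccc(CC)cc1", "Oc1ccc(CCC)cc1", "Oc1ccc(CCN)cc1"
    )), label = "active"),
    dplyr::mutate(ro5_profile(c(
      "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1"
    )), label = "inactive")
  )
  cmp <- class_comparison(profiles)
  expect_equal(nrow(cmp), 4 * 2) # 4 descriptors x 2 classes
  expect_true(all(c("min", "q1", "median", "mean", "q3", "max", "sd",
    "u_statistic", "p_value") %in% names(cmp)))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  nhbd <- cmp[cmp$descriptor == "n_hbd" & cmp$label == "active", ]
  expect_equal(nhbd$median, 1)
})
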