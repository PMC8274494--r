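test_that("pIC50 transform matches the defining thresholds", {
  expect_equal(to_pic50(1, "uM"), 6)
  expect_equal(to_pic50(10, "uM"), 5)
  expect_equal(to_pic50(1, "nM"), 9)
  expect_equal(to_pic50(1, "M"), 0)
  expect_error(to_pic50(0, "nM"), class = "erq_domain_error")
  expect_error(to_pic50(1, "mg/mL"), class = "erq_domain_error")
})

test_that("pIC50 is strictly decreasing and unit-consistent", {
  x <- c(0.3, 1, 7, 40, 900)
  expect_true(all(diff(to_pic50(x, "uM")) < 0))
  expect_equal(to_pic50(x, "uM"), to_pic50(1000 * x, "nM"))
  expect_equal(to_pic50(x, "M"), to_pic50(1e6 * x, "uM"))
})

test_that("activity labels use strict thresholds with intermediates between", {
  expect_equal(
    label_activity(c(6.5, 4.2, 5.5)),
    c("active", "inactive", "intermediate")
  )
  # boundary values are intermediate (strict < 1 uM / > 10 uM reading)
  expect_equal(label_activity(c(6, 5)), c("intermediate", "intermediate"))
  expect_error(
    label_activity(1, active_threshold = 5, inactive_threshold = 6),
    class = "erq_config_error"
  )
})

test_that("curation aggregates, drops conflicts and intermediates, labels", {
  cur <- curate_activity(tiny_activity())
  rep <- curation_report(cur)
  # replicate pair a2 (pIC50 7, ~6.8) -> one active with median pIC50
  a2 <- cur[cur$compound_id == "a2", ]
  expect_equal(nrow(a2), 1L)
  expect_equal(a2$label, "active")
  expect_equal(a2$pic50, median(to_pic50(c(100, 160), "nM")))
  expect_equal(a2$n_measurements, 2L)
  # conflicting replicates c1 dropped; intermediate m1 dropped
  expect_false("c1" %in% cur$compound_id)
  expect_equal(rep$n_dropped_conflict, 1L)
  expect_equal(rep$n_dropped_intermediate, 1L)
  expect_setequal(unique(cur$label), c("active", "inactive"))
  expect_equal(rep$n_active + rep$n_inactive, nrow(cur))
  expect_false(anyDuplicated(cur$smiles_canonical) > 0)
})

test_that("explicit median example: replicates 6.2/6.4 become one active 6.3", {
  tab <- tibble::tibble(
    compound_id = c("x", "x"),
    smiles = c("CCN(CC)CC", "CCN(CC)CC"),
    standard_type = "IC50",
    standard_value = 10^(9 - c(6.2, 6.4)), # nM values for pIC50 6.2, 6.4
    standard_units = "nM"
  )
  cur <- curate_activity(tab)
  expect_equal(nrow(cur), 1L)
  expect_equal(cur$pic50, 6.3, tolerance = 1e-9)
  expect_equal(cur$label, "active")
})

test_that("curation is invariant to input row order", {
  tab <- tiny_activity()
  cur1 <- curate_activity(tab)
  set.seed(42)
  perm <- sample(nrow(tab))
  cur2 <- curate_activity(tab[perm, ])
  ord <- function(d) d[order(d$smiles_canonical), c("smiles_canonical", "pic50", "label")]
  expect_equal(ord(cur1), ord(cur2))
})

test_that("curation rejects empty and all-filtered inputs", {
  expect_error(curate_activity(tiny_activity()[0, ]), class = "erq_empty_error")
  tab <- tiny_activity()
  tab$standard_type <- "Ki"
  expect_error(curate_activity(tab), class = "erq_empty_error")
})

test_that("unit-swapped and salt-form replicates collapse without drift", {
  tab <- tibble::tibble(
    compound_id = "z1",
    smiles = "Oc1ccc(CC)cc1",
    standard_type = "IC50",
    standard_value = 50, standard_units = "nM"
  )
  pert <- inject_duplicates_and_salts(tab, rate = 1, seed = 3, jitter_sd = 0)
  expect_equal(nrow(pert), 2L)
  expect_equal(pert$standard_units, c("nM", "uM"))
  cur <- curate_activity(pert)
  expect_equal(nrow(cur), 1L)
  expect_equal(cur$pic50, to_pic50(50, "nM"))
  expect_equal(cur$n_measurements, 2L)
})

test_that("injected conflicting replicate pairs are dropped by curation", {
  tab <- tibble::tibble(
    compound_id = c("k", "k"),
    smiles = "CCCCN",
    standard_type = "IC50",
    standard_value = c(10^(9 - 7), 10^(9 - 4)), # pIC50 7 and 4
    standard_units = "nM"
  )
  expect_error(curate_activity(tab), class = "erq_empty_error")
  tab2 <- dplyr::bind_rows(
    tab,
    tibble::tibble(
      compound_id = "ok", smiles = "CCO", standard_type = "IC50",
      standard_value = 1, standard_units = "nM"
    )
  )
  cur <- curate_activity(tab2)
  expect_equal(cur$compound_id, "ok")
  expect_equal(curation_report(cur)$n_dropped_conflict, 1L)
})
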