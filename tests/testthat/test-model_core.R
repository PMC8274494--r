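test_that("metrics match closed forms on canonical confusion matrices", {
  perfect <- classification_metrics(50, 50, 0, 0)
  expect_equal(unlist(perfect[c("ac", "sn", "sp", "mcc")]),
    c(ac = 100, sn = 100, sp = 100, mcc = 1)
  )
  anti <- classification_metrics(0, 0, 50, 50)
  expect_equal(anti$mcc, -1)
  expect_equal(anti$ac, 0)
  # all-positive predictor: zero-denominator convention gives MCC 0
  allpos <- classification_metrics(50, 0, 50, 0)
  expect_equal(allpos$sn, 100)
  expect_equal(allpos$sp, 0)
  expect_equal(allpos$mcc, 0)
  expect_error(classification_metrics(0, 0, 0, 0), class = "erq_domain_error")
})

test_that("metrics agree with brute-force recomputation from label pairs", {
  set.seed(123)
  for (i in 1:300) {
    cm <- stats::rmultinom(1, size = sample(1:200, 1), prob = runif(4))
    tp <- cm[1]; tn <- cm[2]; fp <- cm[3]; fn <- cm[4]
    if (sum(cm) == 0) next
    truth <- c(
      rep("active", tp), rep("inactive", tn),
      rep("inactive", fp), rep("active", fn)
    )
    pred <- c(
      rep("active", tp), rep("inactive", tn),
      rep("active", fp), rep("inactive", fn)
    )
    m <- classification_metrics(tp, tn, fp, fn)
    expect_equal(m$ac, 100 * mean(truth == pred))
    if (tp + fn > 0) {
      expect_equal(m$sn, 100 * mean(pred[truth == "active"] == "active"))
    }
    if (tn + fp > 0) {
      expect_equal(m$sp, 100 * mean(pred[truth == "inactive"] == "inactive"))
    }
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    # direct Pearson correlation of indicator vectors where defined
    yt <- as.integer(truth == "active")
    yp <- as.integer(pred == "active")
    if (length(yt) > 1 && sd(yt) > 0 && sd(yp) > 0) {
      expect_equal(m$mcc, cor(yt, yp), tolerance = 1e-12)
    }
    # symmetry under class swap
    m2 <- classification_metrics(tn, tp, fn, fp)
    expect_equal(m2$mcc, m$mcc)
    expect_equal(evaluate_predictions(truth, pred)$mcc, m$mcc)
  }
})

test_that("stratified folds are balanced, seeded, and exhaustive", {
  y <- rep(c("active", "inactive"), c(30, 20))
  f1 <- erqsar:::stratified_folds(y, 5, seed = 4)
  f2 <- erqsar:::stratified_folds(y, 5, seed = 4)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:5)
  per_fold <- table(f1, y)
  expect_true(all(per_fold[, "active"] == 6))
  expect_true(all(per_fold[, "inactive"] == 4))
  f3 <- erqsar:::stratified_folds(y, 5, seed = 5)
  expect_false(identical(f1, f3))
})

test_that("cross-validation pools fold confusions over the full sample", {
  set.seed(2)
  x <- matrix(rnorm(60 * 5), ncol = 5)
  y <- rep(c("active", "inactive"), 30)
  cv <- cross_validate_rf(x, y, k = 5, ntree = 50, seed = 9)
  totals <- cv$pooled$tp + cv$pooled$tn + cv$pooled$fp + cv$pooled$fn
  expect_equal(totals, 60L)
  expect_equal(nrow(cv$per_fold), 5L)
  expect_equal(sum(cv$per_fold$tp), cv$pooled$tp)
  cv2 <- cross_validate_rf(x, y, k = 5, ntree = 50, seed = 9)
  expect_equal(cv$pooled, cv2$pooled)
  expect_error(
    cross_validate_rf(x, rep("active", 60), k = 5),
    class = "erq_domain_error"
  )
})

test_that("the default tuning grid spans 60 candidate pairs", {
  cfg <- model_config()
  grid <- expand.grid(ntree = cfg$ntree_grid, mtry = cfg$mtry_grid)
  expect_equal(nrow(grid), 60L)
  expect_equal(range(cfg$ntree_grid), c(100L, 1000L))
  expect_equal(range(cfg$mtry_grid), c(5L, 30L))
})

test_that("tuning searches the grid, skips oversized mtry, breaks ties low", {
  set.seed(10)
  n <- 60
  noise <- matrix(rnorm(n * 3), ncol = 3,
    dimnames = list(NULL, paste0("noise", 1:3))
  )
  x <- cbind(sig = rep(c(1, 0), each = n / 2), noise)
  y <- rep(c("active", "inactive"), each = n / 2)
  cfg <- model_config(
    ntree_grid = c(50L, 100L), mtry_grid = c(2L, 10L), seed = 3
  )
  expect_warning(
    model <- tune_and_train(x, y, cfg),
    "mtry exceeds"
  )
  # mtry 10 > 4 features: only the two ntree x mtry=2 points remain
  expect_equal(nrow(model$tuning_table), 2L)
  # perfectly separable signal: all points tie at MCC 1 -> smallest ntree wins
  expect_equal(model$chosen_ntree, 50L)
  expect_equal(model$chosen_mtry, 2L)
  expect_equal(model$training_report$mcc, 1)
  expect_error(
    tune_and_train(x, rep("active", n), cfg),
    class = "erq_domain_error"
  )
})

test_that("feature ranking orders by Gini importance with planted signal first", {
  set.seed(21)
  n <- 120
  x <- cbind(
    planted = rep(c(1, 0), each = n / 2),
    noise1 = sample(0:1, n, replace = TRUE),
    noise2 = sample(0:1, n, replace = TRUE),
    flat = rep(1, n)
  )
  y <- rep(c("active", "inactive"), each = n / 2)
  cfg <- model_config(ntree_grid = 100L, mtry_grid = 2L, seed = 5)
  model <- tune_and_train(x, y, cfg)
  imp <- rank_features(model)
  expect_equal(nrow(imp), 4L)
  expect_equal(imp$rank, 1:4)
  expect_true(all(diff(imp$mdgi) <= 0))
  expect_equal(imp$feature_name[1], "planted")
  expect_equal(imp$mdgi[imp$feature_name == "flat"], 0)
  expect_equal(nrow(rank_features(model, top_k = 2)), 2L)
  expect_error(rank_features(list()), class = "erq_state_error")
})

test_that("resubstitution accuracy dominates CV accuracy on separable data", {
  model <- run_benchmark_target(seed = 31, n_active = 40, n_inactive = 40)
  expect_gte(
    model$model$training_report$ac,
    model$model$cv_report$ac - 1e-9
  )
})

test_that("tidy and glance expose importance and headline metrics", {
  model <- run_benchmark_target(seed = 31, n_active = 40, n_inactive = 40)
  td <- generics::tidy(model$model)
  expect_true(all(c("feature_name", "mdgi", "rank") %in% names(td)))
  gl <- generics::glance(model$model)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("ntree", "mtry", "mcc_cv", "ac_training") %in% names(gl)))
})
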