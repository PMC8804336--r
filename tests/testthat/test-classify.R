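test_that("standardization uses training statistics only", {
  sc <- standardize_fit_apply(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.vector(sc$train), c(-1, 0, 1) * 1.2247449, tolerance = 1e-6)

  const <- standardize_fit_apply(matrix(c(5, 5, 5), ncol = 1))
  expect_equal(as.vector(const$train), c(0, 0, 0))
  expect_equal(const$constant_features, 1)

  tr <- matrix(c(8, 12, 8, 12), ncol = 1) # mean 10, population sd 2
  sc2 <- standardize_fit_apply(tr, matrix(12, ncol = 1))
  expect_equal(as.vector(sc2$test), 1)
  # test-fold statistics are not those of the training fold: no leakage
  expect_false(isTRUE(all.equal(mean(sc2$test), 0)))
})

test_that("feature selection ranks separating features first", {
  set.seed(2)
  x <- matrix(rnorm(40 * 20), 40, 20)
  y <- rep(c("normal", "tumor"), each = 20)
  x[, 7] <- ifelse(y == "tumor", 5, -5) + rnorm(40, 0, 0.01)
  expect_equal(select_features(x, y, 1), 7)
  expect_setequal(select_features(x, y, 20), 1:20)
})

test_that("informative wavelengths are recovered across seeds", {
  hits <- vapply(1:5, function(seed) {
    set.seed(seed)
    n <- 60
    x <- matrix(rnorm(n * 505), n, 505)
    y <- rep(c("normal", "tumor"), each = n / 2)
    informative <- seq(50, 500, by = 50)
    for (j in informative) {
      x[, j] <- x[, j] + ifelse(y == "tumor", 1.5, -1.5)
    }
    sel <- select_features(x, y, 10)
    length(intersect(sel, informative))
  }, numeric(1))
  expect_true(all(hits >= 8))
})

test_that("stratified folds partition sites and balance classes", {
  y <- rep(c("normal", "tumor"), each = 5)
  plan <- make_cv_plan(y, n_folds = 5, n_repeats = 5, seed = 3)
  for (r in 1:5) {
    f <- plan$folds[, r]
    # each fold holds exactly one site of each class
    for (k in 1:5) {
      expect_equal(sum(f == k & y == "normal"), 1)
      expect_equal(sum(f == k & y == "tumor"), 1)
    }
  }
  # across 5 repeats every site is tested exactly 5 times
  tested <- rowSums(plan$folds >= 1)
  expect_true(all(tested == 5))

  plan2 <- make_cv_plan(y, n_folds = 5, n_repeats = 5, seed = 3)
  expect_identical(plan$folds, plan2$folds)

  expect_error(make_cv_plan(rep(c("a", "b"), c(3, 20)), n_folds = 5), "n_folds")
})

test_that("per-fold class proportions stay within one site of global", {
  set.seed(9)
  y <- rep(c("normal", "tumor"), c(37, 23))
  plan <- make_cv_plan(y, n_folds = 5, n_repeats = 3, seed = 5)
  for (r in 1:3) {
    f <- plan$folds[, r]
    for (k in 1:5) {
      n_k <- sum(f == k)
      for (cl in c("normal", "tumor")) {
        got <- sum(f == k & y == cl)
        want <- n_k * mean(y == cl)
        expect_lte(abs(got - want), 1)
      }
    }
  }
})

test_that("patient-grouped folding keeps patients whole", {
  y <- rep(c("normal", "tumor"), each = 10)
  pid <- rep(sprintf("p%02d", 1:5), 4)
  plan <- make_cv_plan(y, pid, n_folds = 5, n_repeats = 2, seed = 2,
                       group_by_patient = TRUE)
  for (r in 1:2) {
    split <- tapply(plan$folds[, r], pid, function(v) length(unique(v)))
    expect_true(all(split == 1))
  }
})

test_that("every classifier family trains and scores sanely", {
  res <- make_dataset(n_per_class = 15, separation = 2, noise_sd = 0.02,
                      seed = 17)
  ds <- process_spectra(res$sim)
  plan <- make_cv_plan(ds$labels, n_folds = 3, n_repeats = 1, seed = 4)
  for (fam in c("xgb", "gbt_hist", "mlp", "svm")) {
    rep <- run_cv(ds, classifier_spec(fam), plan, k_features = 50)
    acc <- rep$summary$mean[rep$summary$metric == "accuracy"]
    expect_gt(acc, 80)
    expect_true(all(rep$summary$mean <= 100 & rep$summary$mean >= 0, na.rm = TRUE))
  }
})

test_that("cross-validation reports are deterministic under a fixed seed", {
  res <- make_dataset(n_per_class = 10, seed = 23)
  ds <- process_spectra(res$sim)
  plan <- make_cv_plan(ds$labels, n_folds = 3, n_repeats = 2, seed = 6)
  r1 <- run_cv(ds, classifier_spec("xgb"), plan, k_features = 30)
  r2 <- run_cv(ds, classifier_spec("xgb"), plan, k_features = 30)
  expect_identical(r1$per_fold, r2$per_fold)
})

test_that("accuracy rises with configured class separation", {
  accs <- vapply(c(0.1, 0.6, 2), function(sep) {
    res <- make_dataset(n_per_class = 12, separation = sep,
                        noise_sd = 0.06, seed = 19)
    ds <- process_spectra(res$sim)
    plan <- make_cv_plan(ds$labels, n_folds = 3, n_repeats = 2, seed = 7)
    rep <- run_cv(ds, classifier_spec("xgb"), plan, k_features = 50)
    rep$summary$mean[rep$summary$metric == "accuracy"]
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("single-spectrum scoring separates the class centroids", {
  res <- make_dataset(n_per_class = 12, separation = 2, seed = 29)
  ds <- process_spectra(res$sim)
  trained <- train_classifier(ds, classifier_spec("xgb"), k_features = 50)
  cent_t <- colMeans(ds$features[ds$labels == "tumor", ])
  cent_n <- colMeans(ds$features[ds$labels == "normal", ])
  expect_gt(predict_site(trained, cent_t), 0.5)
  expect_lt(predict_site(trained, cent_n), 0.5)
  # the two one-vs-rest probabilities are complementary
  p <- predict_site(trained, cent_t)
  expect_equal(p + (1 - p), 1)
  expect_error(predict_site(trained, cent_t[-1]), "grid mismatch")
})

test_that("perfect confusion counts give perfect metrics", {
  m <- drsprobe:::fold_metrics(
    rep(c("tumor", "normal"), each = 5),
    c(rep(0.9, 5), rep(0.1, 5))
  )
  expect_equal(unname(m["accuracy"]), 100)
  expect_equal(unname(m["sensitivity"]), 100)
  expect_equal(unname(m["specificity"]), 100)
  expect_equal(unname(m["auc"]), 100)
})
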