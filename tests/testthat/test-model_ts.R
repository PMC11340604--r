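test_that("metric suite matches hand-checkable cases", {
  # perfectly separated scores
  m <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(m$auc, 1.0)
  expect_equal(m$mcc, 1.0)
  expect_equal(m$bacc, 1.0)

  # TP = FP = TN = FN = 1
  cv <- confusion_vectors(1, 1, 1, 1)
  m2 <- compute_metrics(cv$labels, cv$scores)
  expect_equal(m2$mcc, 0.0)
  expect_equal(m2$bacc, 0.5)

  # all scores equal: full ties average to AUC 0.5
  m3 <- compute_metrics(c(0, 1, 0, 1, 1), rep(0.4, 5))
  expect_equal(m3$auc, 0.5)

  # single-class truth: AUC warns and is NA, other metrics computed
  expect_warning(m4 <- compute_metrics(c(1, 1, 1), c(0.9, 0.2, 0.8)),
                 "one class")
  expect_true(is.na(m4$auc))
  expect_equal(m4$recall, 2 / 3)
})

test_that("AUC equals brute-force concordant-pair counting", {
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(4:50, 1L)
    y <- c(0, 1, sample(0:1, n - 2L, replace = TRUE))
    s <- round(runif(n), 2)          # rounding forces ties
    expect_equal(compute_metrics(y, s)$auc, oracle_auc(y, s),
                 tolerance = 1e-12)
  }
})

test_that("cross-validation is stratified, exhaustive, and deterministic", {
  d <- separable_xy(n = 100L, seed = 7L)
  cv <- cross_validate(d$X, d$y, k = 5L, seed = 3L,
                       config = gbt_config(nrounds = 10L, max_depth = 2L))
  expect_length(cv$per_fold, 5L)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(as.vector(table(cv$folds)), rep(20L, 5L))
  expect_equal(cv$mean[["auc"]], 1.0)       # separable by construction
  cv2 <- cross_validate(d$X, d$y, k = 5L, seed = 3L,
                        config = gbt_config(nrounds = 10L, max_depth = 2L))
  expect_identical(cv$mean, cv2$mean)
  expect_error(cross_validate(d$X, d$y, k = 60L), "smaller than")
  expect_error(cross_validate(d$X, d$y, k = 1L), ">= 2")
})

test_that("greedy selection finds the separating feature first", {
  d <- separable_xy(n = 80L, p_noise = 10L, seed = 5L)
  traj <- greedy_forward_selection(d$X, d$y, k = 5L, seed = 2L,
                                   config = gbt_config(nrounds = 10L,
                                                       max_depth = 2L),
                                   max_features = 3L)
  expect_equal(traj$feature[1L], "signal")
  expect_gt(traj$cv_mcc[1L], 0.95)

  # round-1 winner equals the argmax of single-feature CV MCC computed
  # through the public cross-validation path
  singles <- vapply(colnames(d$X), function(f) {
    cross_validate(d$X[, f, drop = FALSE], d$y, k = 5L, seed = 2L,
                   config = gbt_config(nrounds = 10L,
                                       max_depth = 2L))$mean[["mcc"]]
  }, numeric(1L))
  expect_equal(traj$feature[1L], names(which.max(singles)))
  expect_equal(traj$cv_mcc[1L], max(singles), tolerance = 1e-9)
})

test_that("greedy selection: single candidate and duplicate tie-break", {
  d <- separable_xy(n = 60L, p_noise = 2L, seed = 9L)
  one <- greedy_forward_selection(d$X, d$y, candidates = "noise1", k = 5L,
                                  seed = 1L,
                                  config = gbt_config(nrounds = 5L,
                                                      max_depth = 2L))
  expect_equal(nrow(one), 1L)

  # two identical columns: the candidate-earlier one wins round 1
  X2 <- cbind(dupA = d$X[, "signal"], dupB = d$X[, "signal"])
  traj <- greedy_forward_selection(X2, d$y, k = 5L, seed = 1L,
                                   config = gbt_config(nrounds = 5L,
                                                       max_depth = 2L),
                                   max_features = 1L)
  expect_equal(traj$feature[1L], "dupA")
})

test_that("TS training, prediction, and serialization behave per contract", {
  d <- separable_xy(n = 100L, seed = 13L)
  b <- train_ts(d$X, d$y, seed = 13L)
  p <- predict_sites(b, d$X)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(compute_metrics(d$y, p)$auc, 0.99)

  tmp <- withr::local_tempfile(fileext = ".json")
  write_bundle(b, tmp)
  b2 <- read_bundle(tmp)
  expect_identical(predict_sites(b2, d$X), p)

  Xr <- d$X
  colnames(Xr)[1] <- "renamed"
  expect_error(predict_sites(b, Xr), "missing")
  expect_error(train_ts(d$X, d$y, features = "ghost"), "unknown feature")
  expect_length(predict_sites(b, d$X[0, , drop = FALSE]), 0L)
})

test_that("missing values are handled internally at fit and predict", {
  d <- separable_xy(n = 120L, seed = 17L)
  X <- d$X
  X[sample(length(X), length(X) %/% 5)] <- NA
  b <- train_ts(X, d$y, config = gbt_config(nrounds = 30L))
  p <- predict_sites(b, X)
  expect_false(anyNA(p))
  expect_gte(compute_metrics(d$y, p)$auc, 0.9)
})

test_that("permutation importance ranks the signal feature first", {
  d <- separable_xy(n = 100L, p_noise = 3L, seed = 19L)
  b <- train_ts(d$X, d$y, config = gbt_config(nrounds = 20L))
  imp <- permutation_importance(b, d$X, d$y, n_perm = 3L, seed = 4L)
  expect_equal(imp$feature[1L], "signal")
})
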