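test_that("classification metrics match hand-computed confusion counts", {
  # perfect prediction
  m <- compute_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1), c(.1, .9, .2, .8))
  expect_equal(unlist(m[c("ACC", "SEN", "SPE", "AUC")]),
               c(ACC = 1, SEN = 1, SPE = 1, AUC = 1))

  # everything called positive on balanced labels
  m2 <- compute_metrics(c(0, 1, 0, 1), c(1, 1, 1, 1), rep(0.9, 4))
  expect_equal(m2$ACC, 0.5)
  expect_equal(m2$SEN, 1)
  expect_equal(m2$SPE, 0)

  # TP=62 FN=8 TN=48 FP=13
  truth <- c(rep(1, 70), rep(0, 61))
  pred <- c(rep(1, 62), rep(0, 8), rep(0, 48), rep(1, 13))
  m3 <- compute_metrics(truth, pred, runif(131))
  expect_equal(m3$SEN, 62 / 70)
  expect_equal(m3$SPE, 48 / 61)
  expect_equal(m3$ACC, 110 / 131)

  expect_error(compute_metrics(rep(1, 4), rep(1, 4), runif(4)),
               "one class")
})

test_that("the rank-based AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(42)
  for (rep in 1:5) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- runif(40)
    p[y == 1] <- p[y == 1] + rnorm(sum(y), 0.3, 0.4)
    p <- round(pmin(pmax(p, 0), 1), 2)  # force ties
    ours <- compute_metrics(y, as.integer(p >= 0.5), p)$AUC
    ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("stratified folds preserve class balance within one subject", {
  labels <- c(rep(1, 70), rep(0, 61))
  folds <- make_folds(labels, 10, seed = 2)
  for (f in 1:10) {
    expect_equal(sum(labels == 1 & folds == f), 7)
    expect_true(sum(labels == 0 & folds == f) %in% c(6, 7))
    expect_true(sum(folds == f) %in% c(13, 14))
  }
  expect_error(make_folds(c(rep(1, 3), rep(0, 20)), 5),
               "lose one class")
  # fold construction does not disturb the caller's RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(make_folds(labels, 10, seed = 2)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("a singleton grid reduces nested CV to plain outer CV", {
  ph <- small_phantom(grid = 10L, n1 = 9L, n0 = 9L, seed = 15L)
  g <- list(t_s = 0.6, t_h = 0.5, w = 3)
  rep1 <- nested_cv(ph$st$store_full, ph$st$store_pre, g, outer_k = 3L,
                    inner_k = 2L, seed = 5L)
  # manual outer loop at the same fixed point
  labels <- ph$st$store_full$labels
  folds <- make_folds(labels, 3L, seed = 5L)
  accs <- sapply(1:3, function(f) {
    tr <- which(folds != f); te <- which(folds == f)
    cm <- fit_conversion_model(subset_store(ph$st$store_full, tr),
                               subset_store(ph$st$store_pre, tr),
                               0.6, 0.5, 3, seed = 5L + f)
    mean(predict_conversion(cm, subset_store(ph$st$store_pre, te))$label ==
           labels[te])
  })
  expect_equal(rep1$per_fold$ACC, accs)
  expect_true(all(rep1$per_fold$t_s == 0.6))

  # bit-for-bit reproducibility under the same seed
  rep2 <- nested_cv(ph$st$store_full, ph$st$store_pre, g, outer_k = 3L,
                    inner_k = 2L, seed = 5L)
  expect_identical(rep1$pooled_probabilities, rep2$pooled_probabilities)
})

test_that("hyperparameter selection scores the grid and breaks ties small", {
  ph <- small_phantom(grid = 10L, n1 = 9L, n0 = 9L, seed = 15L)
  g <- list(t_s = c(0.55, 0.6), t_h = c(0, 0.5), w = c(1, 3))
  rep <- nested_cv(ph$st$store_full, ph$st$store_pre, g, outer_k = 3L,
                   inner_k = 2L, seed = 5L)
  expect_true(all(rep$per_fold$t_s %in% g$t_s))
  expect_true(all(rep$per_fold$t_h %in% g$t_h))
  expect_true(all(rep$per_fold$w %in% g$w))
  expect_true(all(rep$per_fold$ACC >= 0 & rep$per_fold$ACC <= 1))

  # tie-break: with identical scores everywhere the smallest point wins
  acc <- array(0.8, dim = c(2, 2, 2))
  chosen <- voxhier:::choose_params(acc, g)
  expect_equal(unlist(chosen), c(t_s = 0.55, t_h = 0, w = 1))
  acc[2, 1, 2] <- 0.9
  expect_equal(unlist(voxhier:::choose_params(acc, g)),
               c(t_s = 0.6, t_h = 0, w = 3))
  expect_error(voxhier:::choose_params(array(NA_real_, dim = c(2, 2, 2)),
                                       g), "failed")
})

test_that("training a fold never touches held-out subjects", {
  ph <- small_phantom(grid = 10L, n1 = 9L, n0 = 9L, seed = 15L)
  labels <- ph$st$store_full$labels
  folds <- make_folds(labels, 3L, seed = 1L)
  tr <- which(folds != 1); te <- which(folds == 1)
  corrupted_full <- ph$st$store_full
  corrupted_pre <- ph$st$store_pre
  corrupted_full$features[te, , ] <- 1e6
  corrupted_pre$features[te, , ] <- 1e6
  cm_clean <- fit_conversion_model(subset_store(ph$st$store_full, tr),
                                   subset_store(ph$st$store_pre, tr),
                                   0.6, 0.5, 3, seed = 2L)
  cm_dirty <- fit_conversion_model(subset_store(corrupted_full, tr),
                                   subset_store(corrupted_pre, tr),
                                   0.6, 0.5, 3, seed = 2L)
  probe <- subset_store(ph$st$store_pre, te)
  expect_identical(predict_conversion(cm_clean, probe)$probability,
                   predict_conversion(cm_dirty, probe)$probability)
})

test_that("condition comparisons share folds and reduce baseline features", {
  ph <- small_phantom(grid = 10L, n1 = 9L, n0 = 9L, seed = 15L)
  cc <- compare_conditions(ph$st$store_full, ph$st$store_pre, t_s = 0.6,
                           t_h = 0.5, w = 3, outer_k = 3L, seed = 4L)
  expect_named(cc, c("longitudinal_hierarchy", "longitudinal_single",
                     "baseline_hierarchy", "baseline_single"))
  for (r in cc) expect_equal(r$per_fold$n_test, cc[[1]]$per_fold$n_test)
  # identical seeds give identical fold assignments across conditions
  expect_equal(make_folds(ph$st$store_full$labels, 3L, 4L),
               make_folds(baseline_store(ph$st$store_full)$labels, 3L, 4L))
})

test_that("evaluation reports export as delimited text", {
  ph <- small_phantom(grid = 10L, n1 = 9L, n0 = 9L, seed = 15L)
  rep <- nested_cv(ph$st$store_full, ph$st$store_pre,
                   list(t_s = 0.6, t_h = 0.5, w = 3), outer_k = 3L,
                   seed = 5L)
  d <- tempfile()
  paths <- write_report(rep, d)
  tab <- read.delim(paths[1])
  expect_equal(nrow(tab), 4L)  # 3 folds + aggregate row
  roc <- read.delim(paths[2])
  expect_equal(names(roc), c("fpr", "tpr"))
  expect_true(all(diff(roc$fpr) >= 0))
})
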