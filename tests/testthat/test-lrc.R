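test_that("cost of the zero model is log 2 and scales with fit quality", {
  m0 <- raw_lrc(c(0, 0), 0)
  x <- rbind(c(1, 2), c(-3, 4), c(0, 0))
  expect_equal(lrc_cost(m0, x, c(0, 1, 0)), log(2), tolerance = 1e-12)

  # near-perfect fit on a single positive sample: cost ~ 0
  m1 <- raw_lrc(0, 40)
  expect_lt(lrc_cost(m1, matrix(0), 1), 1e-10)

  # w = 1, b = 0 on x = {-2, 2} with labels {0, 1}: both terms -log sigma(2)
  m2 <- raw_lrc(1, 0)
  expect_equal(lrc_cost(m2, matrix(c(-2, 2)), c(0, 1)),
               -log(plogis(2)), tolerance = 1e-12)

  expect_error(lrc_cost(m2, matrix(c(-2, 2)), c(0, 2)), "labels")
})

test_that("gradient descent solves separable data with monotone cost", {
  fit <- fit_lrc(matrix(c(-1, 1)), c(0, 1))
  expect_equal(predict_label(fit, matrix(c(-1, 1))), c(0L, 1L))
  trace <- attr(fit, "cost_trace")
  expect_true(all(diff(trace) <= 1e-12))
  expect_equal(trace[1], log(2), tolerance = 1e-12)
  expect_lte(trace[length(trace)], trace[1])

  # labels independent of features: posterior collapses to prevalence
  x <- matrix(1, nrow = 4, ncol = 2)
  fit2 <- fit_lrc(x, c(0, 1, 0, 1))
  expect_equal(unname(predict_proba(fit2, x)), rep(0.5, 4),
               tolerance = 1e-6)
})

test_that("fitted parameters match an independent grid-search minimizer", {
  d <- oracle_dataset()
  cfg <- fit_config(max_iter = 50000L, tol = 1e-14, l2 = 1e-3)
  fit <- fit_lrc(d$x, d$y, cfg)

  # independent oracle: dense coarse-to-fine grid search over (w1, w2, b)
  # on the standardized features, evaluating the penalized cross-entropy
  # directly
  xs <- scale(d$x)
  cost_fn <- function(w1, w2, b) {
    p <- plogis(xs[, 1] * w1 + xs[, 2] * w2 + b)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    mean(-d$y * log(p) - (1 - d$y) * log(1 - p)) +
      1e-3 / 2 * (w1^2 + w2^2)
  }
  center <- c(0, 0, 0)
  width <- 8
  for (pass in 1:6) {
    g1 <- seq(center[1] - width, center[1] + width, length.out = 21)
    g2 <- seq(center[2] - width, center[2] + width, length.out = 21)
    g3 <- seq(center[3] - width, center[3] + width, length.out = 21)
    grid <- expand.grid(w1 = g1, w2 = g2, b = g3)
    costs <- mapply(cost_fn, grid$w1, grid$w2, grid$b)
    center <- as.numeric(grid[which.min(costs), ])
    width <- width / 8
  }
  expect_equal(fit$weights[1], center[1], tolerance = 1e-3)
  expect_equal(fit$weights[2], center[2], tolerance = 1e-3)
  expect_equal(fit$bias, center[3], tolerance = 1e-3)
})

test_that("posterior and decision identities hold", {
  m0 <- raw_lrc(c(0, 0, 0), 0)
  expect_equal(unname(predict_proba(m0, c(3, -1, 2))), 0.5)
  expect_equal(predict_label(m0, c(3, -1, 2)), 1L)  # tie goes positive

  # standardized input of 1.0 under w = 2: sigma(2)
  m2 <- raw_lrc(2, 0)
  expect_equal(unname(predict_proba(m2, 1)), plogis(2), tolerance = 1e-12)

  # input equal to the training mean maps to 0.5 when b = 0
  mm <- voxhier:::new_lrc(5, 0, center = 7, scale = 3)
  expect_equal(unname(predict_proba(mm, 7)), 0.5)

  expect_equal(predict_label(raw_lrc(1, qlogis(0.49)), 0), 0L)
  expect_equal(predict_label(raw_lrc(1, qlogis(0.51)), 0), 1L)
  expect_error(predict_proba(m2, c(1, 2)), "does not match")
})

test_that("fit is invariant to row permutation and matches the R reference", {
  set.seed(11)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c(0, 1), 10)
  f1 <- fit_lrc(x, y)
  perm <- sample(20)
  f2 <- fit_lrc(x[perm, ], y[perm])
  expect_equal(f1$weights, f2$weights, tolerance = 1e-12)
  expect_equal(f1$bias, f2$bias, tolerance = 1e-12)

  # a tiny tolerance makes both implementations run the same fixed number
  # of updates, so the comparison is not sensitive to a stopping rule
  # firing one iteration apart
  for (l2 in c(0, 1e-2)) {
    cfg <- fit_config(max_iter = 300L, tol = 1e-14, l2 = l2)
    fr <- voxhier:::fit_lrc_r(x, y, cfg)
    fc <- fit_lrc(x, y, cfg)
    expect_equal(fc$weights, fr$weights, tolerance = 1e-10)
    expect_equal(fc$bias, fr$bias, tolerance = 1e-10)
    expect_equal(attr(fc, "cost_trace"), attr(fr, "cost_trace"),
                 tolerance = 1e-10)
  }
})

test_that("the compiled voxel bank equals a per-voxel fit_lrc loop", {
  ph <- small_phantom(grid = 10L, n1 = 8L, n0 = 8L, seed = 9L)
  st <- ph$st$store_full
  idx <- seq_len(25)
  sub <- subset_store(st, seq_along(st$labels))
  sub$features <- st$features[, , idx, drop = FALSE]
  sub$voxels <- st$voxels[idx, , drop = FALSE]
  bank <- fit_voxel_bank(sub)
  for (v in c(1L, 7L, 25L)) {
    ref <- fit_lrc(st$features[, , v], st$labels)
    expect_equal(unname(bank$weights[v, ]), ref$weights, tolerance = 1e-10)
    expect_equal(unname(bank$bias[v]), ref$bias, tolerance = 1e-10)
    expect_equal(unname(bank$confident[v]),
                 confident_value(ref, st$features[, , v], st$labels))
    expect_equal(unname(bank$posteriors[, v]),
                 unname(predict_proba(ref, st$features[, , v])),
                 tolerance = 1e-10)
  }
  expect_error(fit_lrc(matrix(1:4, 2), c(1, 1)), "both classes")
})
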