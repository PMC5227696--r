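test_that("the patch tiling is a true partition of the voxel set", {
  set.seed(5)
  gs <- c(20L, 20L, 20L)
  coords <- unique(cbind(sample(0:19, 200, TRUE), sample(0:19, 200, TRUE),
                         sample(0:19, 200, TRUE)))
  part <- patch_partition(coords, 5L, gs)
  covered <- sort(unlist(lapply(part$blocks, `[[`, "voxel_idx")))
  expect_equal(covered, seq_len(nrow(coords)))  # disjoint and exhaustive
  for (blk in part$blocks) {
    co <- coords[blk$voxel_idx, , drop = FALSE]
    expect_true(all(sweep(co, 2L, blk$block * 5L, "-") >= 0))
    expect_true(all(sweep(co, 2L, blk$block * 5L, "-") < 5))
  }
  # w = 1: every voxel is its own patch
  p1 <- patch_partition(coords, 1L, gs)
  expect_length(p1$blocks, nrow(coords))
  expect_error(patch_partition(rbind(c(0, 0, 25)), 5L, gs), "outside")
})

test_that("t_h = 0 is a no-op gate and gating is monotone in t_h", {
  ph <- small_phantom(grid = 12L, seed = 3L)
  sel <- select_voxels(ph$st$store_full, 0.65)
  m0 <- train_hierarchy(ph$st$store_pre, sel, t_h = 0, w = 5L,
                        store_full = ph$st$store_full)
  expect_equal(m0$n_gated_voxels, m0$n_selected)
  expect_equal(m0$n_blocks_gated, m0$n_blocks_total)

  counts <- sapply(c(0, 0.5, 0.6), function(th) {
    m <- train_hierarchy(ph$st$store_pre, sel, t_h = th, w = 5L,
                         store_full = ph$st$store_full)
    c(m$n_gated_voxels, m$n_blocks_gated)
  })
  expect_true(all(diff(counts[1, ]) <= 0))
  expect_true(all(diff(counts[2, ]) <= 0))
})

test_that("w = 1 degenerates the patch level to single-voxel classifiers", {
  ph <- small_phantom(grid = 10L, n1 = 8L, n0 = 8L, seed = 9L)
  sel <- select_voxels(ph$st$store_full, 0.6)
  m <- train_hierarchy(ph$st$store_pre, sel, t_h = 0.5, w = 1L,
                       store_full = ph$st$store_full)
  expect_true(all(vapply(m$blocks, function(b) length(b$voxel_idx), 0L) ==
                    1L))
  expect_true(all(vapply(m$blocks, function(b) b$model$input_dim, 0L) ==
                    1L))
})

test_that("an easy cohort trains a hierarchy that separates the classes", {
  ph <- small_phantom(grid = 12L, seed = 3L)
  sel <- select_voxels(ph$st$store_full, 0.65)
  m <- train_hierarchy(ph$st$store_pre, sel, store_full = ph$st$store_full)
  expect_gte(m$n_gated_voxels, 1L)
  expect_gte(m$n_blocks_gated, 1L)
  expect_gte(m$image_confident, 0.95)
  pred <- predict_subject(m, ph$st$store_pre)
  expect_gte(mean(pred$label == ph$st$store_pre$labels), 0.9)
})

test_that("confidence images carry posteriors at gated voxels and zeros
           elsewhere", {
  ph <- small_phantom(grid = 12L, seed = 3L)
  sel <- select_voxels(ph$st$store_full, 0.65)
  m <- train_hierarchy(ph$st$store_pre, sel, store_full = ph$st$store_full)
  fe <- model_features(ph$st$store_pre, m)
  img <- subject_confidence_image(m, fe[1, , , drop = FALSE])
  expect_equal(dim(img), m$grid_shape)
  inside <- img[m$voxel$coords + 1L]
  expect_true(all(inside > 0 & inside < 1))
  outside <- img
  outside[m$voxel$coords + 1L] <- 0
  expect_true(all(outside == 0))
  # identical to the model's own posterior path
  post <- voxhier:::hier_posteriors(m, fe)$voxel
  expect_equal(unname(inside), unname(post[1, ]))
})

test_that("hand-built degenerate models obey the tie rule at every level", {
  T_ <- 7L
  model <- structure(list(
    t_h = 0.5, w = 1L, months = scan_schedule()$months,
    grid_shape = c(6L, 6L, 6L),
    voxel = list(weights = matrix(0, 1, T_), bias = 0,
                 center = matrix(0, 1, T_), scale = matrix(1, 1, T_),
                 coords = matrix(c(2L, 3L, 4L), 1)),
    blocks = list(list(block = c(2L, 3L, 4L), voxel_idx = 1L,
                       model = raw_lrc(1, 0), confident = 1)),
    image_model = raw_lrc(0, 0), image_confident = 0.5,
    n_selected = 1L, n_gated_voxels = 1L, n_blocks_total = 1L,
    n_blocks_gated = 1L), class = "hierarchical_model")
  fe <- array(rnorm(T_), dim = c(1L, T_, 1L))
  img <- subject_confidence_image(model, fe)
  expect_equal(img[3, 4, 5], 0.5)  # zero-weight voxel model
  expect_equal(sum(img != 0), 1L)
  pred <- predict_subject(model, fe)
  expect_equal(pred$probability, 0.5)  # zero-weight image model
  expect_equal(pred$label, 1L)         # tie goes to converter
})

test_that("prediction is stateless and deterministic", {
  ph <- small_phantom(grid = 12L, seed = 3L)
  sel <- select_voxels(ph$st$store_full, 0.65)
  m <- train_hierarchy(ph$st$store_pre, sel, store_full = ph$st$store_full)
  p1 <- predict_subject(m, ph$st$store_pre)
  perm <- rev(seq_along(ph$st$store_pre$labels))
  p2 <- predict_subject(m, subset_store(ph$st$store_pre, perm))
  expect_equal(p2$probability, p1$probability[perm])
  expect_equal(predict_subject(m, ph$st$store_pre), p1)
})

test_that("the single global classifier flattens all selected voxels", {
  ph <- small_phantom(grid = 10L, n1 = 8L, n0 = 8L, seed = 9L)
  sel <- select_voxels(ph$st$store_full, 0.6)
  g <- fit_single_global(ph$st$store_pre, sel)
  expect_equal(g$model$input_dim, length(sel$selected_idx) * 7L)
  pr <- predict_single_global(g, ph$st$store_pre)
  expect_true(all(pr$probability > 0 & pr$probability < 1))
})

test_that("model containers round-trip bit-faithfully", {
  ph <- small_phantom(grid = 12L, seed = 3L)
  sel <- select_voxels(ph$st$store_full, 0.65)
  m <- train_hierarchy(ph$st$store_pre, sel, store_full = ph$st$store_full)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict_subject(m2, ph$st$store_pre)$probability,
                   predict_subject(m, ph$st$store_pre)$probability)
  expect_error(load_model({p <- tempfile(); saveRDS(1, p); p}),
               "container")
})
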