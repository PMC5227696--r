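#' Non-overlapping patch partition of voxel coordinates
#'
#' Tiles the image grid into w x w x w cells anchored at the origin (cells
#' at the far edges are truncated by the grid boundary) and assigns every
#' voxel to the unique cell containing it. Blocks are ordered
#' lexicographically by block index and voxels within a block
#' lexicographically by coordinate; empty blocks are omitted.
#'
#' @param coords Integer matrix (n x 3) of 0-based voxel coordinates.
#' @param w Positive integer patch edge length; \code{w = 1} makes every
#'   voxel its own patch.
#' @param grid_shape Integer triple.
#' @return A \code{patch_partition}: \code{w}, \code{grid_shape} and
#'   \code{blocks}, a list of \code{list(block, voxel_idx)} with
#'   \code{voxel_idx} indexing rows of \code{coords}.
#' @export
patch_partition <- function(coords, w, grid_shape) {
  stopifnot(w >= 1, nrow(coords) >= 1)
  if (any(coords < 0) || any(sweep(coords, 2L, grid_shape, ">="))) {
    stop("voxel coordinates outside the grid")
  }
  b <- coords %/% as.integer(w)
  ord <- order(b[, 1], b[, 2], b[, 3], coords[, 1], coords[, 2], coords[, 3])
  key <- paste(b[ord, 1], b[ord, 2], b[ord, 3])
  runs <- rle(key)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1L
  blocks <- lapply(seq_along(runs$values), function(j) {
    idx <- ord[starts[j]:stops[j]]
    list(block = as.integer(b[idx[1], ]), voxel_idx = idx)
  })
  structure(list(w = as.integer(w), grid_shape = as.integer(grid_shape),
                 blocks = blocks),
            class = "patch_partition")
}

# Out-of-fold voxel posteriors: for each cross-fit fold, voxel classifiers
# are refit without that fold's subjects and applied to them, so the
# resulting posterior matrix mimics the distribution the upper levels will
# see on held-out data. sub: a store-like list restricted to the gated
# voxels; folds: cross-fit fold assignment.
oof_voxel_posteriors <- function(sub, cfg, folds) {
  P <- matrix(NA_real_, length(sub$labels), dim(sub$features)[3])
  for (j in sort(unique(folds))) {
    tr <- which(folds != j)
    te <- which(folds == j)
    bj <- fit_voxel_bank(subset_store(sub, tr), cfg)
    P[te, ] <- predict_voxel_bank(bj, sub$features[te, , , drop = FALSE])
  }
  P
}

# Selection-aware cross-fit stack. Voxel selection is part of training, so
# honest upper-level inputs must account for it: for each cross-fit fold,
# voxel classifiers AND selection confidences are recomputed without that
# fold's subjects. A fold's subjects receive honest posteriors at voxels
# that would still have been selected without them, and an uninformative
# 0.5 where the voxel's selection depended on them. Without this, noise
# voxels admitted by the winner's curse keep their spurious class
# separation in every fold (all training subjects took part in selection)
# and the upper levels learn to rely on it, inflating held-out posteriors.
# sub_pre / sub_full: store-like lists over the same voxels, carrying
# pre-conversion and full longitudinal features respectively.
oof_voxel_stack <- function(sub_pre, sub_full, cfg, folds) {
  V <- dim(sub_pre$features)[3]
  ids <- sort(unique(folds))
  P <- matrix(NA_real_, length(sub_pre$labels), V)
  CONF <- matrix(NA_real_, length(ids), V)
  for (j in ids) {
    tr <- which(folds != j)
    te <- which(folds == j)
    bank_pre <- fit_voxel_bank(subset_store(sub_pre, tr), cfg)
    P[te, ] <- predict_voxel_bank(bank_pre,
                                  sub_pre$features[te, , , drop = FALSE])
    bank_full <- fit_voxel_bank(subset_store(sub_full, tr), cfg)
    CONF[j, ] <- bank_full$confident
  }
  list(P = P, conf = CONF, folds = folds)
}

# Blank out a fold's posteriors at voxels that fold's subjects helped
# select (selection confidence without them at or below t_s).
apply_selection_mask <- function(stack, t_s) {
  P <- stack$P
  for (j in seq_len(nrow(stack$conf))) {
    rows <- which(stack$folds == j)
    P[rows, stack$conf[j, ] <= t_s] <- 0.5
  }
  P
}

# Out-of-fold patch posteriors over the kept blocks, using the same
# cross-fit fold assignment as the voxel level.
oof_patch_posteriors <- function(P, blocks, labels, cfg, folds) {
  Q <- matrix(NA_real_, nrow(P), length(blocks))
  for (j in sort(unique(folds))) {
    tr <- which(folds != j)
    te <- which(folds == j)
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]$voxel_idx
      m <- fit_lrc(P[tr, idx, drop = FALSE], labels[tr], cfg)
      Q[te, b] <- predict_proba(m, P[te, idx, drop = FALSE])
    }
  }
  Q
}

# Cross-fit fold assignment for stacking; NULL when a class is too small
# to be split (falls back to in-sample stacking).
cf_fold_plan <- function(labels, cf_folds, seed) {
  k <- min(cf_folds, sum(labels == 1), sum(labels == 0))
  if (k < 2L) return(NULL)
  make_folds(labels, k, seed)
}

# Patch- and image-level classifiers on top of gated voxel posteriors.
# P_train: N x g matrix of voxel posteriors used as patch-level training
# inputs (out-of-fold posteriors under cross-fitted stacking, in-sample
# training posteriors otherwise); coords: g x 3 gated voxel coordinates.
# A block is gated when its confident value is at least t_h, so t_h = 0 is
# a no-op gate. Under cross-fitted stacking (cf_folds_vec non-NULL) a
# block's confident value is the accuracy of its out-of-fold posteriors,
# so the gate measures usefulness on the same distribution the image level
# consumes; in-sample stacking uses the block's training accuracy.
fit_upper_levels <- function(P_train, coords, labels, t_h, w, cfg,
                             grid_shape, cf_folds_vec = NULL) {
  partition <- patch_partition(coords, w, grid_shape)
  block_fits <- lapply(partition$blocks, function(blk) {
    x <- P_train[, blk$voxel_idx, drop = FALSE]
    m <- fit_lrc(x, labels, cfg)
    list(block = blk$block, voxel_idx = blk$voxel_idx, model = m,
         confident = confident_value(m, x, labels),
         posterior = predict_proba(m, x))
  })
  if (is.null(cf_folds_vec)) {
    conf_b <- vapply(block_fits, function(f) f$confident, 0)
    Q_all <- NULL
  } else {
    Q_all <- oof_patch_posteriors(P_train, block_fits, labels, cfg,
                                  cf_folds_vec)
    conf_b <- colMeans((Q_all >= 0.5) == labels)
    for (b in seq_along(block_fits)) block_fits[[b]]$confident <- conf_b[b]
  }
  gate_b <- conf_b >= t_h
  if (!any(gate_b)) {
    stop(sprintf("no patches passed the gate at the patch level (t_h=%g)",
                 t_h))
  }
  kept <- block_fits[gate_b]
  q <- if (is.null(cf_folds_vec)) {
    do.call(cbind, lapply(kept, function(f) f$posterior))
  } else {
    Q_all[, gate_b, drop = FALSE]
  }
  image_model <- fit_lrc(q, labels, cfg)
  list(partition = partition,
       blocks = lapply(kept, function(f) f[c("block", "voxel_idx",
                                             "model", "confident")]),
       n_blocks_total = length(block_fits),
       image_model = image_model,
       image_confident = confident_value(image_model, q, labels))
}

#' Train the three-level voxel/patch/image classifier
#'
#' On the selected voxels and pre-conversion longitudinal features: (1) a
#' logistic classifier is fit per voxel and voxels whose confident value
#' reaches t_h are gated through; (2) each subject's gated-voxel posteriors
#' form a confidence image on the original grid (zero elsewhere); (3) a
#' classifier is fit per non-empty w x w x w patch on its gated voxels'
#' posteriors, and patches reaching t_h gate through; (4) one image-level
#' classifier on the gated patches' posteriors makes the final decision.
#' The gate threshold t_h is shared by all levels.
#'
#' @param store A \code{feature_store} of pre-conversion features (see
#'   \code{\link{preconversion_store}}).
#' @param selection A \code{voxel_selection}, or an integer vector of voxel
#'   indices into the store.
#' @param t_h Gate threshold in [0, 1); default 0.5. Units with confident
#'   value below t_h are discarded; \code{t_h = 0} keeps everything.
#' @param w Patch edge length; default 5.
#' @param cfg A \code{\link{fit_config}}.
#' @param seed Integer; drives the cross-fit fold assignment.
#' @param stack How upper-level training inputs are produced:
#'   \code{"crossfit"} (default) trains the patch and image levels on
#'   out-of-fold posteriors from the level below, so their inputs have the
#'   distribution seen on new subjects; \code{"insample"} trains them on
#'   the lower level's own training posteriors. In-sample stacking
#'   preserves the ranking of subjects but mis-calibrates the 0.5 decision
#'   threshold, because held-out posteriors shrink towards 0.5 relative to
#'   the overfit training posteriors.
#' @param cf_folds Number of cross-fit folds (default 5; reduced to the
#'   smaller class size when needed).
#' @param store_full Optional \code{feature_store} of the FULL longitudinal
#'   features (the ones voxel selection was run on). When given together
#'   with a \code{voxel_selection}, cross-fitted stacking also recomputes
#'   the selection step without each fold, so upper-level training inputs
#'   carry none of the selection winner's curse.
#' @return A \code{hierarchical_model}.
#' @export
train_hierarchy <- function(store, selection, t_h = 0.5, w = 5L,
                            cfg = fit_config(), seed = 0L,
                            stack = c("crossfit", "insample"),
                            cf_folds = 5L, store_full = NULL) {
  stack <- match.arg(stack)
  sel_idx <- if (inherits(selection, "voxel_selection")) {
    selection$selected_idx
  } else {
    as.integer(selection)
  }
  if (length(sel_idx) < 1L) stop("empty voxel selection")
  sub <- store
  sub$features <- store$features[, , sel_idx, drop = FALSE]
  sub$voxels <- store$voxels[sel_idx, , drop = FALSE]
  bank <- fit_voxel_bank(sub, cfg, seed)
  folds_cf <- NULL
  if (stack == "crossfit") {
    folds_cf <- cf_fold_plan(store$labels, cf_folds, seed + 77L)
    if (is.null(folds_cf)) {
      message("a class is too small for cross-fitted stacking; ",
              "falling back to in-sample stacking")
    }
  }
  if (is.null(folds_cf)) {
    # in-sample stacking: gate voxels by training accuracy, feed upper
    # levels the training posteriors
    gate_v <- bank$confident >= t_h
    P_all <- NULL
  } else {
    P_all <- if (!is.null(store_full) &&
                 inherits(selection, "voxel_selection")) {
      sub_f <- store_full
      sub_f$features <- store_full$features[, , sel_idx, drop = FALSE]
      sub_f$voxels <- store_full$voxels[sel_idx, , drop = FALSE]
      st <- oof_voxel_stack(sub, sub_f, cfg, folds_cf)
      apply_selection_mask(st, selection$t_s)
    } else {
      oof_voxel_posteriors(sub, cfg, folds_cf)
    }
    # gate voxels by out-of-fold accuracy: the gate then measures
    # usefulness on the distribution the patch level actually consumes
    gate_v <- colMeans((P_all >= 0.5) == store$labels) >= t_h
  }
  if (!any(gate_v)) {
    stop(sprintf("no voxels passed the gate at the voxel level (t_h=%g)",
                 t_h))
  }
  gated <- subset_bank(bank, which(gate_v))
  P_train <- if (is.null(folds_cf)) gated$posteriors else {
    P_all[, gate_v, drop = FALSE]
  }
  upper <- fit_upper_levels(P_train, gated$coords, store$labels,
                            t_h, w, cfg, store$grid_shape, folds_cf)
  structure(list(t_h = t_h, w = as.integer(w), months = store$months,
                 grid_shape = store$grid_shape,
                 voxel = gated,
                 partition = upper$partition,
                 blocks = upper$blocks,
                 image_model = upper$image_model,
                 image_confident = upper$image_confident,
                 n_selected = length(sel_idx),
                 n_gated_voxels = sum(gate_v),
                 n_blocks_total = upper$n_blocks_total,
                 n_blocks_gated = length(upper$blocks),
                 stack = if (is.null(folds_cf)) "insample" else "crossfit",
                 cf_folds = if (is.null(folds_cf)) NA_integer_ else
                   max(folds_cf)),
            class = "hierarchical_model")
}

# Match a model's gated voxel coordinates to store voxel rows.
align_store_to_coords <- function(store, coords) {
  store_key <- paste(store$voxels[, 1], store$voxels[, 2], store$voxels[, 3])
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  idx <- match(key, store_key)
  if (anyNA(idx)) {
    stop("missing feature at a gated voxel: store does not cover the model")
  }
  idx
}

#' Extract a model-aligned feature array from a store
#'
#' @param store A \code{feature_store} on the model's grid.
#' @param model A \code{hierarchical_model} or \code{single_global} model.
#' @return N x T x g array aligned with the model's voxel ordering.
#' @export
model_features <- function(store, model) {
  coords <- if (inherits(model, "hierarchical_model")) model$voxel$coords
            else model$coords
  idx <- align_store_to_coords(store, coords)
  if (length(store$months) != length(model$months) ||
      any(store$months != model$months)) {
    stop("store schedule does not match the model's time points")
  }
  store$features[, , idx, drop = FALSE]
}

# Posteriors at all three levels for model-aligned features.
hier_posteriors <- function(model, feats) {
  g <- nrow(model$voxel$weights)
  if (length(dim(feats)) != 3L || dim(feats)[3] != g ||
      dim(feats)[2] != ncol(model$voxel$weights)) {
    stop("dimension mismatch at the voxel level")
  }
  post <- predict_voxel_bank(model$voxel, feats)
  q <- do.call(cbind, lapply(model$blocks, function(blk) {
    if (max(blk$voxel_idx) > ncol(post)) {
      stop("dimension mismatch at the patch level")
    }
    predict_proba(blk$model, post[, blk$voxel_idx, drop = FALSE])
  }))
  if (ncol(q) != model$image_model$input_dim) {
    stop("dimension mismatch at the image level")
  }
  list(voxel = post, patch = q,
       image = predict_proba(model$image_model, q))
}

#' Per-subject confidence image
#'
#' A 3D map on the original grid holding the subject's voxel-level
#' posteriors at the gated voxel sites and exactly 0 everywhere else.
#'
#' @param model A \code{hierarchical_model}.
#' @param features The subject's features: a T x g matrix (or 1 x T x g
#'   array) aligned with the model's gated voxels, e.g. one row of
#'   \code{\link{model_features}}.
#' @return 3D numeric array of size \code{model$grid_shape}.
#' @export
subject_confidence_image <- function(model, features) {
  if (is.matrix(features)) {
    features <- array(features, dim = c(1L, dim(features)))
  }
  stopifnot(dim(features)[1] == 1L)
  post <- hier_posteriors(model, features)$voxel
  img <- array(0, dim = model$grid_shape)
  img[model$voxel$coords + 1L] <- post[1L, ]
  img
}

#' Predict conversion for subjects
#'
#' Voxel posteriors feed the gated patch classifiers, whose posteriors feed
#' the image-level classifier; its output is the final decision. Label 1
#' (converter) iff the image-level posterior is at least 0.5.
#'
#' @param model A \code{hierarchical_model}.
#' @param features N x T x g model-aligned array (see
#'   \code{\link{model_features}}), or a \code{feature_store}.
#' @return Data frame with columns \code{probability} and \code{label}.
#' @export
predict_subject <- function(model, features) {
  if (inherits(features, "feature_store")) {
    features <- model_features(features, model)
  }
  p <- hier_posteriors(model, features)$image
  data.frame(probability = p, label = as.integer(p >= 0.5))
}

#' Single global classifier baseline
#'
#' One logistic classifier on the concatenation of all selected voxels'
#' longitudinal features (input dimension |V_s| * T), the flat alternative
#' to the hierarchy on the same voxel set.
#'
#' @param store A \code{feature_store} (pre-conversion features for a fair
#'   comparison with the hierarchy).
#' @param selection A \code{voxel_selection} or integer voxel indices.
#' @param cfg A \code{\link{fit_config}}.
#' @return A \code{single_global} model.
#' @export
fit_single_global <- function(store, selection, cfg = fit_config()) {
  sel_idx <- if (inherits(selection, "voxel_selection")) {
    selection$selected_idx
  } else {
    as.integer(selection)
  }
  if (length(sel_idx) < 1L) stop("empty voxel selection")
  feats <- store$features[, , sel_idx, drop = FALSE]
  x <- matrix(feats, nrow = dim(feats)[1])  # column order: time within voxel
  model <- fit_lrc(x, store$labels, cfg)
  structure(list(model = model, coords = store$voxels[sel_idx, , drop = FALSE],
                 months = store$months, grid_shape = store$grid_shape,
                 n_selected = length(sel_idx)),
            class = "single_global")
}

#' @rdname predict_subject
#' @export
predict_single_global <- function(model, features) {
  if (inherits(features, "feature_store")) {
    features <- model_features(features, model)
  }
  x <- matrix(features, nrow = dim(features)[1])
  p <- predict_proba(model$model, x)
  data.frame(probability = p, label = as.integer(p >= 0.5))
}

#' Save / load a trained model
#'
#' Serializes the full model container (thresholds, grid, schedule, sparse
#' voxel-model table, patch and image classifiers) to a single RDS file;
#' the round trip is bit-faithful on posteriors.
#'
#' @param model A \code{hierarchical_model} or \code{single_global}.
#' @param path File path.
#' @return \code{save_model} returns the path invisibly;
#'   \code{load_model} returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(container_version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$container_version)) {
    stop("not a voxhier model container")
  }
  obj$model
}

#' @export
print.hierarchical_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<hierarchical_model> t_h=%.2f, w=%d\n",
    "  voxels: %d selected -> %d gated\n",
    "  patches: %d non-empty -> %d gated\n",
    "  image-level training accuracy: %.3f\n"),
    x$t_h, x$w, x$n_selected, x$n_gated_voxels, x$n_blocks_total,
    x$n_blocks_gated, x$image_confident))
  invisible(x)
}
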