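# Run code under a given RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Stratified cross-validation folds
#'
#' Each class is permuted once under the seed and dealt round-robin into k
#' folds, so every fold's class proportions match the cohort's within one
#' subject. A 70/61 cohort at k = 10 yields folds of 13-14 subjects with 7
#' converters and 6-7 non-converters each.
#'
#' @param labels Binary 0/1 vector.
#' @param k Number of folds; must not exceed the size of either class (a
#'   fold losing a class entirely is an error, raised before any fitting).
#' @param seed Integer seed of the per-class permutation.
#' @return Integer vector of fold assignments in 1..k.
#' @export
make_folds <- function(labels, k, seed = 1L) {
  labels <- check_labels(labels)
  k <- as.integer(k)
  if (k < 2L) stop("need at least 2 folds")
  if (min(sum(labels == 1), sum(labels == 0)) < k) {
    stop("k exceeds the size of a class: a fold would lose one class entirely")
  }
  folds <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in c(1, 0)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Classification performance metrics
#'
#' Accuracy, sensitivity (converter recall), specificity (non-converter
#' recall), and the area under the empirical ROC curve. AUC is computed by
#' the rank-based Mann-Whitney statistic (ties rank-averaged), which equals
#' the trapezoidal area under the empirical ROC.
#'
#' @param labels True 0/1 labels; both classes must be present.
#' @param predicted_labels Hard 0/1 decisions.
#' @param probabilities Posterior probabilities for the ROC/AUC.
#' @return List with \code{ACC}, \code{SEN}, \code{SPE}, \code{AUC} and
#'   \code{roc}, a data frame of (FPR, TPR) points.
#' @export
compute_metrics <- function(labels, predicted_labels, probabilities) {
  labels <- check_labels(labels)
  predicted_labels <- check_labels(predicted_labels)
  stopifnot(length(labels) == length(predicted_labels),
            length(labels) == length(probabilities))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("sensitivity/specificity undefined: only one class in the truth")
  }
  acc <- mean(predicted_labels == labels)
  sen <- mean(predicted_labels[labels == 1] == 1)
  spe <- mean(predicted_labels[labels == 0] == 0)
  r <- rank(probabilities)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  roc <- data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(probabilities[labels == 0] >= t), 0),
    tpr = vapply(th, function(t) mean(probabilities[labels == 1] >= t), 0))
  list(ACC = acc, SEN = sen, SPE = spe, AUC = auc, roc = roc)
}

#' Train the full prediction pipeline on a cohort
#'
#' Voxel selection on the full longitudinal features (post-conversion scans
#' included), then either the three-level hierarchy or the single global
#' classifier on the pre-conversion features of the selected voxels.
#'
#' @param store_full \code{feature_store} of full longitudinal features.
#' @param store_pre \code{feature_store} of pre-conversion features (same
#'   subjects, same voxel order).
#' @param t_s Voxel-selection threshold.
#' @param t_h Hierarchy gate threshold.
#' @param w Patch edge length.
#' @param cfg A \code{\link{fit_config}}.
#' @param method \code{"hierarchy"} or \code{"single"}.
#' @param stack Upper-level stacking mode for the hierarchy, see
#'   \code{\link{train_hierarchy}}.
#' @param cf_folds Cross-fit folds for stacking.
#' @param seed Integer.
#' @return A \code{conversion_model} wrapping the selection summary and the
#'   fitted classifier.
#' @export
fit_conversion_model <- function(store_full, store_pre, t_s = 0.65,
                                 t_h = 0.5, w = 5L, cfg = fit_config(),
                                 method = c("hierarchy", "single"),
                                 stack = c("crossfit", "insample"),
                                 cf_folds = 5L, seed = 0L) {
  method <- match.arg(method)
  stack <- match.arg(stack)
  sel <- select_voxels(store_full, t_s, cfg, seed)
  if (length(sel$selected_idx) < 1L) {
    stop(sprintf("no voxels selected at t_s=%g", t_s))
  }
  model <- if (method == "hierarchy") {
    train_hierarchy(store_pre, sel, t_h, w, cfg, seed, stack, cf_folds,
                    store_full = store_full)
  } else {
    fit_single_global(store_pre, sel, cfg)
  }
  structure(list(method = method, t_s = t_s, t_h = t_h, w = as.integer(w),
                 n_selected = length(sel$selected_idx), model = model),
            class = "conversion_model")
}

#' @rdname fit_conversion_model
#' @param object A \code{conversion_model}.
#' @param store Pre-conversion \code{feature_store} of the subjects to
#'   score.
#' @export
predict_conversion <- function(object, store) {
  if (object$method == "hierarchy") {
    predict_subject(object$model, store)
  } else {
    predict_single_global(object$model, store)
  }
}

new_report <- function(per_fold, pooled_labels, pooled_probs,
                       pooled_pred, seed) {
  pooled <- compute_metrics(pooled_labels, pooled_pred, pooled_probs)
  structure(list(
    per_fold = per_fold,
    mean = list(ACC = mean(per_fold$ACC), SEN = mean(per_fold$SEN),
                SPE = mean(per_fold$SPE), AUC = mean(per_fold$AUC)),
    pooled = list(ACC = pooled$ACC, SEN = pooled$SEN, SPE = pooled$SPE,
                  AUC = pooled$AUC),
    roc = pooled$roc,
    pooled_probabilities = pooled_probs,
    pooled_labels = pooled_labels,
    seed = seed), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d folds (seed %d)\n",
              nrow(x$per_fold), x$seed))
  cat(sprintf("  fold means : ACC %.3f  SEN %.3f  SPE %.3f  AUC %.3f\n",
              x$mean$ACC, x$mean$SEN, x$mean$SPE, x$mean$AUC))
  cat(sprintf("  pooled     : ACC %.3f  SEN %.3f  SPE %.3f  AUC %.3f\n",
              x$pooled$ACC, x$pooled$SEN, x$pooled$SPE, x$pooled$AUC))
  invisible(x)
}

# Score one hyperparameter grid over one inner train/validation split,
# reusing a single selection bank and a single pre-conversion voxel bank.
# Returns an ACC array indexed [ts, th, w]; NA where a grid point is
# infeasible (empty selection or empty gate) on this split.
score_grid_split <- function(store_full, store_pre, itr, ival, grids, cfg,
                             method, stack = "crossfit", cf_seed = 0L) {
  ts_grid <- grids$t_s; th_grid <- grids$t_h; w_grid <- grids$w
  acc <- array(NA_real_, dim = c(length(ts_grid), length(th_grid),
                                 length(w_grid)))
  sf <- subset_store(store_full, itr)
  sp <- subset_store(store_pre, itr)
  sel_bank <- fit_voxel_bank(sf, cfg)
  conf <- sel_bank$confident
  union_idx <- which(conf > min(ts_grid))
  if (length(union_idx) < 1L) return(acc)
  labels_tr <- store_pre$labels[itr]
  labels_val <- store_pre$labels[ival]
  if (method == "single") {
    for (a in seq_along(ts_grid)) {
      sel_idx <- which(conf > ts_grid[a])
      if (length(sel_idx) < 1L) next
      m <- fit_single_global(sp, sel_idx, cfg)
      val <- subset_store(store_pre, ival)
      pr <- predict_single_global(m, val)
      acc[a, , ] <- mean(pr$label == labels_val)
    }
    return(acc)
  }
  sub_pre <- sp
  sub_pre$features <- sp$features[, , union_idx, drop = FALSE]
  sub_pre$voxels <- sp$voxels[union_idx, , drop = FALSE]
  pre_bank <- fit_voxel_bank(sub_pre, cfg)
  folds_cf <- if (stack == "crossfit") {
    cf_fold_plan(labels_tr, 5L, cf_seed)
  } else NULL
  cf_stack <- if (is.null(folds_cf)) NULL else {
    sub_full <- sf
    sub_full$features <- sf$features[, , union_idx, drop = FALSE]
    sub_full$voxels <- sf$voxels[union_idx, , drop = FALSE]
    oof_voxel_stack(sub_pre, sub_full, cfg, folds_cf)
  }
  val_feats <- store_pre$features[ival, , union_idx, drop = FALSE]
  for (a in seq_along(ts_grid)) {
    in_sel <- which(conf[union_idx] > ts_grid[a])
    if (length(in_sel) < 1L) next
    P_masked <- if (is.null(cf_stack)) NULL else {
      apply_selection_mask(cf_stack, ts_grid[a])
    }
    oof_acc <- if (is.null(cf_stack)) NULL else {
      colMeans((P_masked[, in_sel, drop = FALSE] >= 0.5) == labels_tr)
    }
    for (b in seq_along(th_grid)) {
      gate <- if (is.null(cf_stack)) {
        in_sel[pre_bank$confident[in_sel] >= th_grid[b]]
      } else {
        in_sel[oof_acc >= th_grid[b]]
      }
      if (length(gate) < 1L) next
      gb <- subset_bank(pre_bank, gate)
      post_tr <- if (is.null(folds_cf)) gb$posteriors else {
        P_masked[, gate, drop = FALSE]
      }
      post_val <- predict_voxel_bank(gb, val_feats[, , gate, drop = FALSE])
      for (d in seq_along(w_grid)) {
        upper <- tryCatch(
          fit_upper_levels(post_tr, gb$coords, labels_tr, th_grid[b],
                           w_grid[d], cfg, store_pre$grid_shape, folds_cf),
          error = function(e) NULL)
        if (is.null(upper)) next
        q_val <- do.call(cbind, lapply(upper$blocks, function(blk) {
          predict_proba(blk$model, post_val[, blk$voxel_idx, drop = FALSE])
        }))
        p_val <- predict_proba(upper$image_model, q_val)
        acc[a, b, d] <- mean(as.integer(p_val >= 0.5) == labels_val)
      }
    }
  }
  acc
}

# Argmax of mean inner-CV accuracy with ties broken towards the smallest
# t_s, then t_h, then w (sparser models win ties).
choose_params <- function(mean_acc, grids) {
  if (all(is.na(mean_acc))) {
    stop("every hyperparameter grid point failed during inner validation")
  }
  best <- max(mean_acc, na.rm = TRUE)
  for (a in seq_along(grids$t_s)) for (b in seq_along(grids$t_h)) {
    for (d in seq_along(grids$w)) {
      v <- mean_acc[a, b, d]
      if (!is.na(v) && v >= best - 1e-12) {
        return(list(t_s = grids$t_s[a], t_h = grids$t_h[b],
                    w = grids$w[d]))
      }
    }
  }
}

#' Nested stratified cross-validation of the pipeline
#'
#' Outer k-fold loop for performance estimation; for each outer training
#' portion, an inner k-fold loop scores every (t_s, t_h, w) grid point by
#' mean validation accuracy, and the winner (ties towards the smallest
#' t_s, then t_h, then w) is refit on the whole training portion and
#' applied to the held-out fold. Voxel selection always uses the full
#' longitudinal features of the training subjects only; hierarchy training,
#' validation and testing use pre-conversion features. With singleton grids
#' the inner loop is skipped and this reduces to plain outer CV at the
#' fixed parameters.
#'
#' @inheritParams fit_conversion_model
#' @param grids List with numeric vectors \code{t_s}, \code{t_h}, \code{w}.
#' @param outer_k,inner_k Fold counts (defaults 10 and 10).
#' @param seed Integer; drives fold construction.
#' @return An \code{evaluation_report} with per-fold metrics, chosen
#'   hyperparameters per fold, fold-mean and pooled metrics, and the pooled
#'   ROC curve.
#' @export
nested_cv <- function(store_full, store_pre,
                      grids = list(t_s = c(0.5, 0.55, 0.6, 0.65),
                                   t_h = c(0, 0.5, 0.55, 0.6, 0.65),
                                   w = c(1, 3, 5, 7, 9, 11)),
                      outer_k = 10L, inner_k = 10L, seed = 1L,
                      cfg = fit_config(),
                      method = c("hierarchy", "single"),
                      stack = c("crossfit", "insample")) {
  method <- match.arg(method)
  stack <- match.arg(stack)
  stopifnot(length(grids$t_s) >= 1, length(grids$t_h) >= 1,
            length(grids$w) >= 1)
  labels <- check_labels(store_full$labels)
  folds <- make_folds(labels, outer_k, seed)
  singleton <- length(grids$t_s) == 1L && length(grids$t_h) == 1L &&
    length(grids$w) == 1L
  rows <- list()
  pooled_probs <- numeric(0)
  pooled_labels <- integer(0)
  pooled_pred <- integer(0)
  for (f in seq_len(outer_k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (singleton) {
      chosen <- list(t_s = grids$t_s, t_h = grids$t_h, w = grids$w)
    } else {
      inner_folds <- make_folds(labels[tr], inner_k, seed + 1000L + f)
      acc_sum <- array(0, dim = c(length(grids$t_s), length(grids$t_h),
                                  length(grids$w)))
      acc_n <- array(0L, dim = dim(acc_sum))
      for (g in seq_len(inner_k)) {
        itr <- tr[inner_folds != g]
        ival <- tr[inner_folds == g]
        acc <- score_grid_split(store_full, store_pre, itr, ival, grids,
                                cfg, method, stack,
                                cf_seed = seed + 10000L * f + 100L * g)
        ok <- !is.na(acc)
        acc_sum[ok] <- acc_sum[ok] + acc[ok]
        acc_n[ok] <- acc_n[ok] + 1L
      }
      mean_acc <- ifelse(acc_n == inner_k, acc_sum / inner_k, NA_real_)
      chosen <- choose_params(mean_acc, grids)
    }
    cm <- fit_conversion_model(subset_store(store_full, tr),
                               subset_store(store_pre, tr),
                               chosen$t_s, chosen$t_h, chosen$w, cfg,
                               method, stack, seed = seed + f)
    pred <- predict_conversion(cm, subset_store(store_pre, te))
    met <- compute_metrics(labels[te], pred$label, pred$probability)
    rows[[f]] <- data.frame(fold = f, n_test = length(te), ACC = met$ACC,
                            SEN = met$SEN, SPE = met$SPE, AUC = met$AUC,
                            t_s = chosen$t_s, t_h = chosen$t_h,
                            w = chosen$w)
    pooled_probs <- c(pooled_probs, pred$probability)
    pooled_labels <- c(pooled_labels, labels[te])
    pooled_pred <- c(pooled_pred, pred$label)
  }
  new_report(do.call(rbind, rows), pooled_labels, pooled_probs,
             pooled_pred, seed)
}

#' Compare data and classifier conditions on identical folds
#'
#' Runs outer cross-validation at fixed hyperparameters for the four
#' conditions {longitudinal, baseline-only} x {hierarchy, single global
#' classifier}, sharing one stratified fold plan so the comparisons are
#' paired. The baseline-only conditions rebuild T = 1 feature stores from
#' the baseline scan for both voxel selection and classification.
#'
#' @inheritParams nested_cv
#' @param t_s,t_h,w Fixed hyperparameters (defaults 0.65, 0.5, 5).
#' @return Named list of \code{evaluation_report}s:
#'   \code{longitudinal_hierarchy}, \code{longitudinal_single},
#'   \code{baseline_hierarchy}, \code{baseline_single}.
#' @export
compare_conditions <- function(store_full, store_pre, t_s = 0.65,
                               t_h = 0.5, w = 5L, outer_k = 10L,
                               seed = 1L, cfg = fit_config()) {
  bl <- baseline_store(store_full)
  grids <- function(ts, th, ww) list(t_s = ts, t_h = th, w = ww)
  list(
    longitudinal_hierarchy = nested_cv(store_full, store_pre,
                                       grids(t_s, t_h, w), outer_k, 2L,
                                       seed, cfg, "hierarchy"),
    longitudinal_single = nested_cv(store_full, store_pre,
                                    grids(t_s, t_h, w), outer_k, 2L, seed,
                                    cfg, "single"),
    baseline_hierarchy = nested_cv(bl, bl, grids(t_s, t_h, w), outer_k,
                                   2L, seed, cfg, "hierarchy"),
    baseline_single = nested_cv(bl, bl, grids(t_s, t_h, w), outer_k, 2L,
                                seed, cfg, "single"))
}

#' Write an evaluation report to delimited text
#'
#' Per-fold rows plus an aggregate row, and the pooled ROC points as a
#' separate two-column file for plotting.
#'
#' @param report An \code{evaluation_report}.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- report$per_fold
  agg <- data.frame(fold = NA, n_test = sum(tab$n_test),
                    ACC = report$mean$ACC, SEN = report$mean$SEN,
                    SPE = report$mean$SPE, AUC = report$mean$AUC,
                    t_s = NA, t_h = NA, w = NA)
  p1 <- file.path(dir, "metrics.tsv")
  p2 <- file.path(dir, "roc.tsv")
  utils::write.table(rbind(tab, agg), p1, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(report$roc[, c("fpr", "tpr")], p2, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
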