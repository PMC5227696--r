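#' Confident value of a trained classifier
#'
#' The confident value of a classifier is its training accuracy: the
#' fraction of training subjects whose hard decision matches the label. It
#' always lies in {0, 1/N, ..., 1}.
#'
#' @param model An \code{lrc} model.
#' @param features Numeric matrix (one row per subject).
#' @param labels Binary 0/1 vector.
#' @return Training accuracy in [0, 1].
#' @export
confident_value <- function(model, features, labels) {
  labels <- check_labels(labels)
  if (length(labels) < 1L) stop("confident value of an empty cohort")
  mean(predict_label(model, features) == labels)
}

#' Fit one logistic classifier per voxel site
#'
#' Runs the compiled per-voxel fitter over every voxel in the store:
#' independent zero-initialized full-batch gradient descent at each site,
#' algorithmically identical to \code{\link{fit_lrc}} on that site's N x T
#' feature matrix. Voxels whose features are constant at every time point
#' are not fit; they receive the majority-class confident value.
#'
#' @param store A \code{feature_store} (or any N x T x n array via
#'   \code{features}) with both classes present.
#' @param cfg A \code{\link{fit_config}}.
#' @param seed Integer; the optimizer is deterministic, kept for interface
#'   stability.
#' @return A \code{voxel_bank}: per-voxel \code{weights} (n x T),
#'   \code{bias}, \code{center}, \code{scale}, \code{confident} (training
#'   accuracy), \code{posteriors} (N x n training posteriors),
#'   \code{degenerate} flags and the voxel \code{coords}.
#' @export
fit_voxel_bank <- function(store, cfg = fit_config(), seed = 0L) {
  feats <- store$features
  labels <- check_labels(store$labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to fit voxel classifiers")
  }
  res <- fit_voxel_bank_cpp(feats, labels, cfg$learning_rate, cfg$max_iter,
                            cfg$tol, cfg$l2)
  n_deg <- sum(res$degenerate)
  if (n_deg > 0L) {
    message(n_deg, " degenerate voxel(s) assigned the majority-class ",
            "confident value without fitting")
  }
  structure(list(weights = res$weights, bias = drop(res$bias),
                 center = res$center, scale = res$scale,
                 confident = drop(res$confident),
                 posteriors = res$posteriors,
                 n_updates = drop(res$n_updates),
                 degenerate = drop(res$degenerate) == 1L,
                 coords = store$voxels,
                 months = store$months,
                 grid_shape = store$grid_shape,
                 n_subjects = length(labels)),
            class = "voxel_bank")
}

#' Posteriors of a voxel bank on new subjects
#'
#' @param bank A \code{voxel_bank} (possibly subset).
#' @param features N x T x n array aligned with the bank's voxel order.
#' @return N x n matrix of posteriors in (0, 1).
#' @export
predict_voxel_bank <- function(bank, features) {
  if (dim(features)[3] != nrow(bank$weights) ||
      dim(features)[2] != ncol(bank$weights)) {
    stop("feature array does not match the voxel bank dimensions")
  }
  predict_voxel_bank_cpp(features, bank$weights, bank$bias, bank$center,
                         bank$scale)
}

subset_bank <- function(bank, idx) {
  bank$weights <- bank$weights[idx, , drop = FALSE]
  bank$bias <- bank$bias[idx]
  bank$center <- bank$center[idx, , drop = FALSE]
  bank$scale <- bank$scale[idx, , drop = FALSE]
  bank$confident <- bank$confident[idx]
  bank$posteriors <- bank$posteriors[, idx, drop = FALSE]
  bank$n_updates <- bank$n_updates[idx]
  bank$degenerate <- bank$degenerate[idx]
  bank$coords <- bank$coords[idx, , drop = FALSE]
  bank
}

#' Select significant voxels by confident value
#'
#' Trains one logistic classifier per in-mask voxel on the full
#' longitudinal features (post-conversion scans included, which carry the
#' strongest conversion signal), computes each voxel's confident value
#' (training accuracy), and keeps the voxels whose value strictly exceeds
#' the threshold t_s.
#'
#' @param store A \code{feature_store} of the full longitudinal features.
#' @param t_s Selection threshold in (0, 1); default 0.65.
#' @param cfg A \code{\link{fit_config}}.
#' @param seed Integer, see \code{\link{fit_voxel_bank}}.
#' @return A \code{voxel_selection}: \code{confident} (vector over store
#'   voxels), \code{selected} (logical vector), \code{selected_idx},
#'   \code{confident_map} and \code{selected_mask} (3D arrays; the
#'   confident map is NA outside the brain mask), \code{t_s}, and the
#'   fitted \code{bank}.
#' @export
select_voxels <- function(store, t_s = 0.65, cfg = fit_config(),
                          seed = 0L) {
  stopifnot(t_s > 0, t_s < 1)
  bank <- fit_voxel_bank(store, cfg, seed)
  selection_from_bank(bank, store, t_s)
}

selection_from_bank <- function(bank, store, t_s) {
  conf <- bank$confident
  selected <- conf > t_s
  conf_map <- array(NA_real_, dim = store$grid_shape)
  conf_map[store$mask] <- conf
  sel_mask <- array(FALSE, dim = store$grid_shape)
  sel_mask[store$mask] <- selected
  structure(list(confident = conf, selected = selected,
                 selected_idx = which(selected),
                 confident_map = conf_map, selected_mask = sel_mask,
                 coords = store$voxels, t_s = t_s, bank = bank,
                 grid_shape = store$grid_shape,
                 n_subjects = bank$n_subjects,
                 n_timepoints = length(store$months)),
            class = "voxel_selection")
}

#' Selected-set sizes across a threshold grid
#'
#' Confident values are computed once; the curve is obtained by
#' re-thresholding only, so the selected sets shrink monotonically (by set
#' containment) as t_s grows.
#'
#' @param selection A \code{voxel_selection} (or \code{voxel_bank}).
#' @param ts_grid Thresholds, default \code{c(0.5, 0.55, 0.6, 0.65)}.
#' @return Named integer vector of selected-set sizes |V_s(t_s)|.
#' @export
selection_curve <- function(selection, ts_grid = c(0.5, 0.55, 0.6, 0.65)) {
  conf <- selection$confident
  sizes <- vapply(ts_grid, function(t) sum(conf > t), 0L)
  names(sizes) <- as.character(ts_grid)
  sizes
}

#' Persist a voxel selection map
#'
#' Writes the confident-value map and the binary selection mask as NIfTI
#' volumes plus a JSON sidecar with the threshold and cohort dimensions.
#'
#' @param selection A \code{voxel_selection}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_selection <- function(selection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conf <- selection$confident_map
  conf[is.na(conf)] <- 0
  p1 <- file.path(dir, "confident_values.nii.gz")
  p2 <- file.path(dir, "selected_mask.nii.gz")
  p3 <- file.path(dir, "selection.json")
  RNifti::writeNifti(conf, p1)
  RNifti::writeNifti(array(as.integer(selection$selected_mask),
                           dim = selection$grid_shape), p2)
  jsonlite::write_json(list(t_s = selection$t_s,
                            n_subjects = selection$n_subjects,
                            n_timepoints = selection$n_timepoints,
                            n_selected = length(selection$selected_idx),
                            grid_shape = selection$grid_shape),
                       p3, auto_unbox = TRUE)
  invisible(c(p1, p2, p3))
}

#' @export
print.voxel_selection <- function(x, ...) {
  cat(sprintf(
    "<voxel_selection> %d/%d voxels selected at t_s=%.2f (N=%d, T=%d)\n",
    length(x$selected_idx), length(x$confident), x$t_s, x$n_subjects,
    x$n_timepoints))
  invisible(x)
}
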