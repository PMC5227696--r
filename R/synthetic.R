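# Separable Gaussian smoothing of a 3D array; edge-truncated kernels are
# renormalized so smoothing preserves a constant field.
gaussian_smooth_3d <- function(arr, sigma) {
  smooth_axis <- function(a, axis) {
    n <- dim(a)[axis]
    x <- seq_len(n)
    k <- outer(x, x, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
    k <- k / rowSums(k)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    d <- dim(ap)
    sm <- k %*% matrix(ap, nrow = d[1])
    dim(sm) <- d
    aperm(sm, order(perm))
  }
  for (axis in 1:3) arr <- smooth_axis(arr, axis)
  arr
}

ellipsoid_mask <- function(grid_shape, center, radii) {
  cx <- center[1]; cy <- center[2]; cz <- center[3]
  x <- seq_len(grid_shape[1]); y <- seq_len(grid_shape[2])
  z <- seq_len(grid_shape[3])
  dx2 <- ((x - cx) / radii[1])^2
  dy2 <- ((y - cy) / radii[2])^2
  dz2 <- ((z - cz) / radii[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

#' Configuration of the synthetic longitudinal phantom cohort
#'
#' The phantom emulates the data model the classifier assumes: a shared
#' "anatomical" template (smoothed random field in [20, 80] inside a
#' spherical brain, 0 outside), smooth subject-level variation, a
#' progressive localized intensity decrease (atrophy proxy) in converters
#' that grows linearly from baseline and reaches its full depth at the
#' subject's conversion month, stationary intensities in non-converters,
#' i.i.d. additive noise, and randomly missed follow-up visits.
#'
#' @param grid_shape Integer triple; default 32 x 32 x 32.
#' @param n_converters,n_nonconverters Class sizes; defaults 30/30.
#' @param schedule A \code{\link{scan_schedule}}.
#' @param signal_regions List of \code{list(center, radii)} ellipsoids in
#'   1-based voxel units; by default two ellipsoids placed at fixed
#'   fractional positions inside the brain sphere, scaled to the grid.
#' @param effect_size Full-progression intensity decrease in units of the
#'   noise standard deviation; default 2.
#' @param noise_sd Additive noise standard deviation on the [0, 100]
#'   intensity scale; default 5.
#' @param subject_jitter Standard deviation of the smooth subject-level
#'   template perturbation; default 2.
#' @param conversion_months Candidate conversion visit months.
#' @param conversion_probs Sampling probabilities over
#'   \code{conversion_months}; the default is proportional to the observed
#'   conversion timing of a 70-converter MCI cohort (11, 28, 17, 7, 7 over
#'   months 6-36).
#' @param missing_rate Probability that a follow-up visit is missed
#'   (baseline is never missed); default 0.1.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the seed.
#' @return A \code{phantom_config}.
#' @export
phantom_config <- function(grid_shape = c(32L, 32L, 32L),
                           n_converters = 30L, n_nonconverters = 30L,
                           schedule = scan_schedule(),
                           signal_regions = NULL,
                           effect_size = 2, noise_sd = 5,
                           subject_jitter = 2,
                           conversion_months = c(6L, 12L, 18L, 24L, 36L),
                           conversion_probs = c(11, 28, 17, 7, 7) / 70,
                           missing_rate = 0.1, seed = 0L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            n_converters >= 1L, n_nonconverters >= 1L,
            effect_size >= 0, noise_sd > 0, subject_jitter >= 0,
            missing_rate >= 0, missing_rate < 1,
            length(conversion_months) == length(conversion_probs))
  if (abs(sum(conversion_probs) - 1) > 1e-8) {
    stop("conversion_probs must sum to 1")
  }
  if (!all(conversion_months %in% schedule$months[-1])) {
    stop("conversion months must be follow-up schedule visits")
  }
  if (is.null(signal_regions)) {
    # two large ellipsoids (~20% of the brain together), a coarse proxy for
    # the distributed medial-temporal plus temporoparietal atrophy pattern
    signal_regions <- list(
      list(center = 0.38 * grid_shape,
           radii = c(0.22, 0.23, 0.22) * grid_shape),
      list(center = 0.62 * grid_shape,
           radii = c(0.20, 0.19, 0.20) * grid_shape))
  }
  for (r in signal_regions) {
    if (any(r$center - r$radii < 1) || any(r$center + r$radii > grid_shape)) {
      stop("signal region extends outside the grid")
    }
  }
  structure(list(grid_shape = grid_shape, n_converters = n_converters,
                 n_nonconverters = n_nonconverters, schedule = schedule,
                 signal_regions = signal_regions,
                 effect_size = effect_size, noise_sd = noise_sd,
                 subject_jitter = subject_jitter,
                 conversion_months = as.integer(conversion_months),
                 conversion_probs = conversion_probs,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Simulate a longitudinal two-class phantom cohort
#'
#' Generates the cohort described by \code{\link{phantom_config}} together
#' with its ground truth. With \code{dir} given, every scan is written as a
#' NIfTI volume and a matching manifest is produced, exercising the same
#' on-disk interface as a real cohort.
#'
#' @param cfg A \code{\link{phantom_config}}.
#' @param dir Optional output directory for NIfTI volumes and the
#'   manifest.
#' @return List with \code{cohort} (list of \code{longitudinal_subject}
#'   with the observed visits only), \code{truth} (a \code{phantom_truth}:
#'   \code{signal_mask}, \code{brain_mask}, per-subject conversion months
#'   and noiseless signal-voxel trajectories), and \code{manifest} (path,
#'   or NULL).
#' @export
simulate_cohort <- function(cfg = phantom_config(), dir = NULL) {
  gs <- cfg$grid_shape
  months <- cfg$schedule$months
  brain <- ellipsoid_mask(gs, (gs + 1) / 2, rep(0.44 * min(gs), 3))
  signal <- array(FALSE, dim = gs)
  for (r in cfg$signal_regions) {
    signal <- signal | ellipsoid_mask(gs, r$center, r$radii)
  }
  signal <- signal & brain
  sig_idx <- which(signal)
  n_total <- cfg$n_converters + cfg$n_nonconverters

  with_local_seed(cfg$seed, {
    template <- gaussian_smooth_3d(array(rnorm(prod(gs)), dim = gs),
                                   sigma = 0.08 * min(gs))
    template <- 20 + (template - min(template)) /
      (max(template) - min(template)) * 60
    # dark CSF-like rim and bright white-matter-like core: dense voxel
    # populations at both intensity extremes pin the 0.1%/99.9% rescaling
    # quantiles, so the localized atrophy (which lives in mid intensities)
    # cannot shift the per-image rescaling map and thereby couple itself to
    # out-of-region voxels
    core <- ellipsoid_mask(gs, (gs + 1) / 2, rep(0.18 * min(gs), 3))
    rim <- brain & !ellipsoid_mask(gs, (gs + 1) / 2, rep(0.40 * min(gs), 3))
    template[core] <- 78 + (template[core] - 20) / 60 * 4
    template[rim] <- 18 + (template[rim] - 20) / 60 * 4
    # signal regions are near-homogeneous mid-intensity tissue ([56, 58]),
    # several noise SDs away from either quantile anchor at every
    # progression stage
    template[sig_idx] <- 56 + (template[sig_idx] - 20) / 60 * 2
    template[!brain] <- 0

    labels <- rep(c(1L, 0L), c(cfg$n_converters, cfg$n_nonconverters))
    conv_month <- rep(NA_integer_, n_total)
    conv_month[labels == 1L] <- sample(cfg$conversion_months,
                                       cfg$n_converters, replace = TRUE,
                                       prob = cfg$conversion_probs)
    cohort <- vector("list", n_total)
    trajectories <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      jitter <- gaussian_smooth_3d(array(rnorm(prod(gs)), dim = gs),
                                   sigma = 0.08 * min(gs))
      jitter <- jitter / stats::sd(jitter[brain]) * cfg$subject_jitter
      base <- template + jitter
      base[!brain] <- 0
      observed <- c(0L, months[-1][runif(length(months) - 1) >=
                                     cfg$missing_rate])
      scans <- vector("list", length(observed))
      names(scans) <- as.character(observed)
      traj <- matrix(NA_real_, nrow = length(observed),
                     ncol = length(sig_idx),
                     dimnames = list(as.character(observed), NULL))
      for (m in observed) {
        img <- base
        prog <- if (labels[i] == 1L) min(m / conv_month[i], 1) else 0
        if (prog > 0) {
          img[sig_idx] <- img[sig_idx] -
            prog * cfg$effect_size * cfg$noise_sd
        }
        traj[as.character(m), ] <- img[sig_idx]
        img[brain] <- img[brain] + rnorm(sum(brain), sd = cfg$noise_sd)
        scans[[as.character(m)]] <- img
      }
      cohort[[i]] <- new_subject(sprintf("sub%03d", i), labels[i],
                                 conv_month[i], scans, gs,
                                 observed_months = observed)
      trajectories[[i]] <- traj
    }
  })

  truth <- structure(list(signal_mask = signal, brain_mask = brain,
                          labels = labels, conversion_months = conv_month,
                          signal_voxel_idx = sig_idx,
                          trajectories = trajectories,
                          template = template),
                     class = "phantom_truth")
  manifest <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    stubs <- lapply(cohort, function(s) {
      paths <- rep(NA_character_, cfg$schedule$T)
      names(paths) <- as.character(months)
      for (m in names(s$scans)) {
        fn <- sprintf("%s_%02dm.nii.gz", s$subject_id, as.integer(m))
        RNifti::writeNifti(s$scans[[m]], file.path(dir, fn))
        paths[m] <- fn
      }
      list(subject_id = s$subject_id, label = s$label,
           conversion_month = s$conversion_month, scan_paths = paths)
    })
    manifest <- file.path(dir, "manifest.csv")
    write_manifest(stubs, manifest, cfg$schedule)
  }
  list(cohort = cohort, truth = truth, manifest = manifest)
}

#' Dice overlap between a voxel selection and the implanted signal
#'
#' @param selection A \code{voxel_selection} (or a logical 3D array).
#' @param truth A \code{phantom_truth} (or a logical 3D array).
#' @return Dice coefficient 2|A&B| / (|A| + |B|) in [0, 1].
#' @export
truth_dice <- function(selection, truth) {
  a <- if (inherits(selection, "voxel_selection")) selection$selected_mask
       else selection
  b <- if (inherits(truth, "phantom_truth")) truth$signal_mask else truth
  if (!identical(dim(a), dim(b))) stop("grid mismatch between masks")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) stop("both masks are empty: Dice undefined")
  2 * sum(a & b) / (na + nb)
}

#' Prepare feature stores straight from a simulated cohort
#'
#' Convenience wrapper for in-memory phantoms: rescales intensities on the
#' brain mask, imputes missing visits, and returns the full and
#' pre-conversion feature stores.
#'
#' @param sim Result of \code{\link{simulate_cohort}}.
#' @param cfg The \code{\link{phantom_config}} used.
#' @param rescale Apply quantile intensity rescaling (default TRUE).
#' @return List with \code{store_full}, \code{store_pre} and \code{mask}.
#' @export
phantom_stores <- function(sim, cfg = phantom_config(), rescale = TRUE) {
  mask <- brain_mask(sim$cohort)
  cohort <- sim$cohort
  if (rescale) cohort <- rescale_cohort(cohort, mask)
  cohort <- lapply(cohort, impute_missing_timepoints, schedule = cfg$schedule)
  store_full <- build_feature_matrix(cohort, mask, cfg$schedule)
  list(store_full = store_full, store_pre = preconversion_store(store_full),
       mask = mask)
}
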