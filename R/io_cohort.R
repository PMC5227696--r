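#' Default longitudinal scan schedule
#'
#' Visit months of the default acquisition schedule: baseline plus follow-up
#' scans at 6, 12, 18, 24, 36 and 48 months (seven time points). Any
#' strictly increasing integer schedule starting at month 0 with at least
#' two visits is accepted throughout the package.
#'
#' @param months Integer vector of visit months.
#' @return An object of class \code{scan_schedule} with fields
#'   \code{months} and \code{T} (number of time points).
#' @export
scan_schedule <- function(months = c(0L, 6L, 12L, 18L, 24L, 36L, 48L)) {
  months <- as.integer(months)
  if (length(months) < 2L) stop("schedule needs at least two time points")
  if (months[1] != 0L) stop("schedule must start at baseline (month 0)")
  if (any(diff(months) <= 0L)) stop("schedule months must strictly increase")
  structure(list(months = months, T = length(months)),
            class = "scan_schedule")
}

scan_column <- function(month) sprintf("scan_%02dm", month)

#' Read a cohort manifest
#'
#' The manifest is delimited text (comma or tab, auto-detected) with a
#' header row and columns \code{subject_id}, \code{label},
#' \code{conversion_month}, plus one scan-path column per schedule month
#' (\code{scan_00m}, \code{scan_06m}, ...). An empty scan cell marks a
#' missed visit.
#'
#' @param path Manifest file.
#' @param schedule A \code{\link{scan_schedule}}.
#' @return List of subject stubs: \code{subject_id}, \code{label},
#'   \code{conversion_month} (\code{NA} for non-converters) and
#'   \code{scan_paths}, a named character vector over schedule months with
#'   \code{NA} for absent visits.
#' @export
read_manifest <- function(path, schedule = scan_schedule()) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           na.strings = c("", "NA"))
  required <- c("subject_id", "label", "conversion_month",
                scan_column(schedule$months))
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$subject_id)) {
    stop("duplicate subject_id in manifest: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]),
               collapse = ", "))
  }
  lapply(seq_len(nrow(tab)), function(i) {
    label <- as.integer(tab$label[i])
    if (!label %in% c(0L, 1L)) {
      stop("label must be 0 or 1 for subject ", tab$subject_id[i])
    }
    cm <- suppressWarnings(as.integer(tab$conversion_month[i]))
    if (label == 1L) {
      if (is.na(cm)) {
        stop("converter ", tab$subject_id[i], " has no conversion_month")
      }
      if (!(cm %in% schedule$months) || cm <= 0L) {
        stop("conversion_month of ", tab$subject_id[i],
             " must be a positive schedule month")
      }
    } else {
      cm <- NA_integer_
    }
    paths <- as.character(tab[i, scan_column(schedule$months)])
    names(paths) <- as.character(schedule$months)
    list(subject_id = tab$subject_id[i], label = label,
         conversion_month = cm, scan_paths = paths)
  })
}

#' Write a cohort manifest
#'
#' @param stubs List of subject stubs as returned by
#'   \code{\link{read_manifest}}.
#' @param path Output file (comma-delimited).
#' @param schedule A \code{\link{scan_schedule}}.
#' @export
write_manifest <- function(stubs, path, schedule = scan_schedule()) {
  rows <- lapply(stubs, function(s) {
    c(subject_id = s$subject_id, label = as.character(s$label),
      conversion_month = if (is.na(s$conversion_month)) "" else
        as.character(s$conversion_month),
      setNames(ifelse(is.na(s$scan_paths), "", s$scan_paths),
               scan_column(schedule$months)))
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

new_subject <- function(subject_id, label, conversion_month, scans,
                        grid_shape, observed_months = NULL) {
  structure(list(subject_id = subject_id, label = as.integer(label),
                 conversion_month = conversion_month, scans = scans,
                 grid_shape = as.integer(grid_shape),
                 observed_months = observed_months),
            class = "longitudinal_subject")
}

#' Load a cohort of longitudinal subjects from a manifest
#'
#' Reads every listed NIfTI scan into memory. Relative scan paths are
#' resolved against the manifest's directory.
#'
#' @inheritParams read_manifest
#' @return List of \code{longitudinal_subject} objects; each holds a named
#'   list \code{scans} (visit month to 3D array) for the observed visits.
#' @export
read_cohort <- function(path, schedule = scan_schedule()) {
  stubs <- read_manifest(path, schedule)
  base <- dirname(path)
  lapply(stubs, function(s) {
    present <- !is.na(s$scan_paths)
    if (!present[1]) stop("baseline scan absent for subject ", s$subject_id)
    scans <- lapply(s$scan_paths[present], function(p) {
      if (!file.exists(p)) p <- file.path(base, p)
      arr <- as.array(RNifti::readNifti(p))
      if (length(dim(arr)) != 3L) {
        stop("expected a single 3D volume in ", p)
      }
      arr
    })
    shapes <- vapply(scans, function(a) paste(dim(a), collapse = "x"), "")
    if (length(unique(shapes)) != 1L) {
      stop("subject ", s$subject_id, " has scans on different grids")
    }
    new_subject(s$subject_id, s$label, s$conversion_month, scans,
                dim(scans[[1]]),
                observed_months = as.integer(names(scans)))
  })
}

#' Brain mask from baseline scans
#'
#' Default masking policy: a voxel is in the brain mask when it is nonzero
#' in at least a given fraction of the cohort's baseline images. Input
#' images are expected to be skull-stripped (zero outside the brain).
#'
#' @param cohort List of \code{longitudinal_subject}.
#' @param frac Minimum fraction of nonzero baselines (default 0.5).
#' @return List with \code{mask} (logical 3D array) and \code{n} (number of
#'   in-mask voxels).
#' @export
brain_mask <- function(cohort, frac = 0.5) {
  shapes <- vapply(cohort, function(s) paste(s$grid_shape, collapse = "x"), "")
  if (length(unique(shapes)) != 1L) stop("cohort images are on mixed grids")
  acc <- array(0, dim = cohort[[1]]$grid_shape)
  for (s in cohort) acc <- acc + (s$scans[["0"]] != 0)
  mask <- acc >= frac * length(cohort)
  n <- sum(mask)
  if (n < 1L) stop("brain mask is empty")
  list(mask = mask, n = n, grid_shape = dim(mask))
}

#' Rescale image intensities to [0, 100]
#'
#' Linearly maps the in-mask intensities so that the \code{low_q} quantile
#' goes to 0 and the \code{high_q} quantile goes to 100 (defaults 0.1\% and
#' 99.9\%), then clips to [0, 100]. Voxels outside the mask are set to 0.
#' A constant image (equal quantiles) yields all zeros with a warning.
#'
#' @param image 3D numeric array.
#' @param mask Brain mask as returned by \code{\link{brain_mask}} (or a
#'   logical array).
#' @param low_q,high_q Quantile fractions anchoring the linear map.
#' @return Rescaled 3D array.
#' @export
rescale_intensities <- function(image, mask, low_q = 0.001, high_q = 0.999) {
  m <- if (is.list(mask)) mask$mask else mask
  stopifnot(identical(dim(image), dim(m)))
  vals <- image[m]
  if (length(vals) < 1L) stop("mask is empty")
  q <- stats::quantile(vals, c(low_q, high_q), names = FALSE)
  out <- array(0, dim = dim(image))
  if (q[2] <= q[1]) {
    warning("constant image inside mask; rescaled values set to 0")
    return(out)
  }
  scaled <- (vals - q[1]) / (q[2] - q[1]) * 100
  out[m] <- pmin(pmax(scaled, 0), 100)
  out
}

#' Rescale every scan of a cohort
#'
#' @inheritParams rescale_intensities
#' @param cohort List of \code{longitudinal_subject}.
#' @return Cohort with all scans rescaled.
#' @export
rescale_cohort <- function(cohort, mask, low_q = 0.001, high_q = 0.999) {
  lapply(cohort, function(s) {
    s$scans <- lapply(s$scans, rescale_intensities, mask = mask,
                      low_q = low_q, high_q = high_q)
    s
  })
}

#' Complete a subject's series by last observation carried forward
#'
#' Every schedule month missing from the subject's series is filled with
#' the most recent earlier available scan, so that all subjects end up with
#' the same number of time points. For example, a subject scanned at months
#' 0, 6, 24 and 36 gets the month-6 scan as month-12 data and the month-36
#' scan as month-48 data.
#'
#' @param subject A \code{longitudinal_subject}.
#' @param schedule A \code{\link{scan_schedule}}.
#' @return Subject with one scan per schedule month; \code{observed_months}
#'   records which visits were actually acquired.
#' @export
impute_missing_timepoints <- function(subject, schedule = scan_schedule()) {
  have <- as.integer(names(subject$scans))
  if (!(0L %in% have)) {
    stop("baseline scan absent for subject ", subject$subject_id,
         ": nothing earlier to carry forward")
  }
  scans <- vector("list", schedule$T)
  names(scans) <- as.character(schedule$months)
  last <- NULL
  for (m in schedule$months) {
    key <- as.character(m)
    if (!is.null(subject$scans[[key]])) last <- subject$scans[[key]]
    scans[[key]] <- last
  }
  subject$scans <- scans
  subject$observed_months <- intersect(schedule$months, have)
  subject
}

#' Restrict a converter's series to pre-conversion data
#'
#' For a converter with conversion month m, only visits at least 6 months
#' before conversion (month <= m - 6) are legitimately available at
#' prediction time. Later visits are replaced by carrying the last eligible
#' scan forward so the series keeps its full length; the baseline visit is
#' always retained. Non-converters are returned unchanged.
#'
#' @param subject A \code{longitudinal_subject} with a complete series.
#' @param schedule A \code{\link{scan_schedule}}.
#' @return Subject whose series contains only pre-conversion information.
#' @export
filter_preconversion <- function(subject, schedule = scan_schedule()) {
  if (subject$label != 1L) return(subject)
  if (!setequal(names(subject$scans), as.character(schedule$months))) {
    stop("subject must be imputed to the full schedule first")
  }
  cutoff <- subject$conversion_month - 6L
  eligible <- schedule$months <= cutoff
  eligible[1] <- TRUE  # baseline always available
  last_key <- as.character(max(schedule$months[eligible]))
  for (m in schedule$months[!eligible]) {
    subject$scans[[as.character(m)]] <- subject$scans[[last_key]]
  }
  subject
}

#' Extract the per-voxel longitudinal feature store
#'
#' For each in-mask voxel site v, subject i contributes the feature vector
#' of its T intensities across the schedule. The store holds all sites in a
#' subjects x time points x voxels array, plus the voxel coordinates
#' (0-based (x, y, z) array indices) and subject metadata.
#'
#' @param cohort List of complete (imputed, rescaled)
#'   \code{longitudinal_subject} on a common grid.
#' @param mask Brain mask (list with \code{mask}, or logical array).
#' @param schedule A \code{\link{scan_schedule}}.
#' @return An object of class \code{feature_store} with fields
#'   \code{features} (N x T x n array), \code{labels}, \code{subject_ids},
#'   \code{conversion_months}, \code{months}, \code{voxels} (n x 3 integer
#'   matrix, 0-based), \code{grid_shape} and \code{mask}.
#' @export
build_feature_matrix <- function(cohort, mask, schedule = scan_schedule()) {
  m <- if (is.list(mask)) mask$mask else mask
  n <- sum(m)
  N <- length(cohort)
  idx <- which(m)
  coords <- arrayInd(idx, dim(m)) - 1L
  colnames(coords) <- c("x", "y", "z")
  feats <- array(NA_real_, dim = c(N, schedule$T, n))
  for (i in seq_len(N)) {
    s <- cohort[[i]]
    if (!identical(as.integer(s$grid_shape), as.integer(dim(m)))) {
      stop("grid mismatch between mask and subject ", s$subject_id)
    }
    if (!setequal(names(s$scans), as.character(schedule$months))) {
      stop("subject ", s$subject_id, " is not complete on the schedule; ",
           "run impute_missing_timepoints first")
    }
    for (t in seq_len(schedule$T)) {
      feats[i, t, ] <- s$scans[[as.character(schedule$months[t])]][idx]
    }
  }
  structure(list(features = feats,
                 labels = vapply(cohort, function(s) s$label, 0L),
                 subject_ids = vapply(cohort, function(s) s$subject_id, ""),
                 conversion_months = vapply(cohort, function(s) {
                   if (is.na(s$conversion_month)) NA_integer_ else
                     as.integer(s$conversion_month)
                 }, 0L),
                 months = schedule$months,
                 voxels = coords,
                 grid_shape = as.integer(dim(m)),
                 mask = m),
            class = "feature_store")
}

#' Subset a feature store by subject
#'
#' @param store A \code{feature_store}.
#' @param idx Integer subject indices.
#' @return Store restricted to those subjects.
#' @export
subset_store <- function(store, idx) {
  store$features <- store$features[idx, , , drop = FALSE]
  store$labels <- store$labels[idx]
  store$subject_ids <- store$subject_ids[idx]
  store$conversion_months <- store$conversion_months[idx]
  store
}

#' Apply the pre-conversion rule directly to a feature store
#'
#' Equivalent to running \code{\link{filter_preconversion}} on every
#' subject and rebuilding the store: for each converter, time points after
#' (conversion month - 6) are overwritten with the last eligible time
#' point's values.
#'
#' @param store A \code{feature_store}.
#' @return Store whose features carry only pre-conversion information.
#' @export
preconversion_store <- function(store) {
  months <- store$months
  for (i in which(store$labels == 1L)) {
    cutoff <- store$conversion_months[i] - 6L
    eligible <- months <= cutoff
    eligible[1] <- TRUE
    last <- max(which(eligible))
    for (t in which(!eligible)) {
      store$features[i, t, ] <- store$features[i, last, ]
    }
  }
  store
}

#' Reduce a feature store to baseline-only features
#'
#' @param store A \code{feature_store}.
#' @return Store with T = 1 (the baseline visit only).
#' @export
baseline_store <- function(store) {
  store$features <- store$features[, 1L, , drop = FALSE]
  store$months <- store$months[1L]
  store
}

#' Read a pipeline configuration file
#'
#' YAML file with optional keys \code{schedule} (vector of visit months),
#' \code{mask_frac} (baseline nonzero fraction for the brain mask) and
#' \code{rescale} (list with \code{low_q}, \code{high_q}).
#'
#' @param path YAML file.
#' @return List with \code{schedule} (a \code{\link{scan_schedule}}),
#'   \code{mask_frac}, \code{low_q}, \code{high_q}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  list(schedule = if (is.null(raw$schedule)) scan_schedule() else
         scan_schedule(raw$schedule),
       mask_frac = if (is.null(raw$mask_frac)) 0.5 else raw$mask_frac,
       low_q = if (is.null(raw$rescale$low_q)) 0.001 else raw$rescale$low_q,
       high_q = if (is.null(raw$rescale$high_q)) 0.999 else raw$rescale$high_q)
}

#' Load, rescale, and complete a cohort in one call
#'
#' Convenience wrapper: read the manifest and images, build the brain mask
#' from baselines, rescale intensities to [0, 100], and impute missing
#' visits by last observation carried forward.
#'
#' @inheritParams read_manifest
#' @param mask_frac Baseline nonzero fraction defining the brain mask.
#' @return List with \code{cohort} (complete subjects), \code{mask} and
#'   \code{schedule}.
#' @export
prepare_cohort <- function(path, schedule = scan_schedule(),
                           mask_frac = 0.5) {
  cohort <- read_cohort(path, schedule)
  mask <- brain_mask(cohort, frac = mask_frac)
  cohort <- rescale_cohort(cohort, mask)
  cohort <- lapply(cohort, impute_missing_timepoints, schedule = schedule)
  list(cohort = cohort, mask = mask, schedule = schedule)
}
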