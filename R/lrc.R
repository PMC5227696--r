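#' Fitting configuration for the logistic regression classifier
#'
#' Bundles the gradient-descent settings shared by every classifier in the
#' hierarchy: the per-voxel classifiers, the patch-level classifiers and the
#' image-level classifier all use the same full-batch optimizer.
#'
#' @param learning_rate Positive step size of full-batch gradient descent.
#' @param max_iter Maximum number of gradient updates.
#' @param tol Convergence tolerance on the relative decrease of the cost
#'   between successive iterations; descent stops once
#'   \code{(J_prev - J) < tol * J_prev}.
#' @param l2 Non-negative ridge penalty \code{l2/2 * ||w||^2} added to the
#'   mean cross-entropy. Defaults to 0 (unpenalized).
#' @return An object of class \code{fit_config}.
#' @export
fit_config <- function(learning_rate = 0.1, max_iter = 500L, tol = 1e-6,
                       l2 = 0) {
  stopifnot(learning_rate > 0, max_iter >= 1, tol > 0, l2 >= 0)
  structure(list(learning_rate = as.numeric(learning_rate),
                 max_iter = as.integer(max_iter),
                 tol = as.numeric(tol),
                 l2 = as.numeric(l2)),
            class = "fit_config")
}

logistic <- function(z) 1 / (1 + exp(-z))

check_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be coded 0 (non-converter) / 1 (converter)")
  }
  as.numeric(labels)
}

new_lrc <- function(weights, bias, center, scale, l2 = 0) {
  structure(list(weights = as.numeric(weights),
                 bias = as.numeric(bias),
                 center = as.numeric(center),
                 scale = as.numeric(scale),
                 input_dim = length(weights),
                 l2 = as.numeric(l2)),
            class = "lrc")
}

standardize_features <- function(features, center, scale) {
  sweep(sweep(features, 2L, center, "-"), 2L, scale, "/")
}

as_feature_matrix <- function(features, input_dim) {
  if (is.null(dim(features))) {
    if (length(features) != input_dim) {
      stop(sprintf("feature length %d does not match input_dim %d",
                   length(features), input_dim))
    }
    features <- matrix(features, nrow = 1L)
  }
  if (ncol(features) != input_dim) {
    stop(sprintf("feature matrix has %d columns but input_dim is %d",
                 ncol(features), input_dim))
  }
  features
}

#' Cost of a logistic regression classifier
#'
#' Mean binary cross-entropy of the classifier on a labelled feature matrix,
#' plus the ridge term \code{l2/2 * ||w||^2}. Probabilities are clipped to
#' \code{[1e-12, 1 - 1e-12]} before taking logarithms. Features are passed
#' through the model's standardizer, so a model with zero center and unit
#' scale evaluates the cost on the raw features.
#'
#' @param model An \code{lrc} model.
#' @param features Numeric matrix, one row per subject.
#' @param labels Binary 0/1 vector.
#' @param l2 Ridge penalty; defaults to the value stored in the model.
#' @return Non-negative scalar cost.
#' @export
lrc_cost <- function(model, features, labels, l2 = model$l2) {
  labels <- check_labels(labels)
  features <- as_feature_matrix(features, model$input_dim)
  stopifnot(nrow(features) == length(labels))
  x <- standardize_features(features, model$center, model$scale)
  p <- logistic(drop(x %*% model$weights) + model$bias)
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-labels * log(p) - (1 - labels) * log(1 - p)) +
    l2 / 2 * sum(model$weights^2)
}

#' Fit a logistic regression classifier by full-batch gradient descent
#'
#' Features are standardized column-wise (training mean and standard
#' deviation; zero-variance columns get unit scale), weights and bias start
#' at zero, and full-batch gradient descent runs until the relative cost
#' decrease falls below \code{cfg$tol} or \code{cfg$max_iter} updates have
#' been made. The optimizer is deterministic; \code{seed} is accepted for
#' interface stability but does not influence the result.
#'
#' @param features Numeric matrix, one row per subject.
#' @param labels Binary 0/1 vector with both classes present.
#' @param cfg A \code{\link{fit_config}}.
#' @param seed Integer, unused by the deterministic optimizer.
#' @return An \code{lrc} model with attribute \code{cost_trace}, the vector
#'   of cost values visited (first entry is the zero-model cost, log 2 when
#'   \code{l2 = 0}).
#' @export
fit_lrc <- function(features, labels, cfg = fit_config(), seed = 0L) {
  labels <- check_labels(labels)
  if (is.null(dim(features))) features <- matrix(features, ncol = 1L)
  storage.mode(features) <- "double"
  n <- nrow(features)
  d <- ncol(features)
  if (d < 1L) stop("features must have at least one column")
  if (n != length(labels)) stop("features and labels disagree in length")
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to fit an LRC")
  }
  res <- fit_lrc_cpp(features, labels, cfg$learning_rate, cfg$max_iter,
                     cfg$tol, cfg$l2)
  model <- new_lrc(drop(res$weights), res$bias, drop(res$center),
                   drop(res$scale), l2 = cfg$l2)
  attr(model, "cost_trace") <- drop(res$cost_trace)
  attr(model, "n_updates") <- res$n_updates
  model
}

# Reference implementation of the same optimizer in plain R; used to
# validate the compiled path.
fit_lrc_r <- function(features, labels, cfg = fit_config()) {
  labels <- check_labels(labels)
  if (is.null(dim(features))) features <- matrix(features, ncol = 1L)
  storage.mode(features) <- "double"
  n <- nrow(features)
  d <- ncol(features)
  center <- colMeans(features)
  scale <- apply(features, 2L, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  x <- standardize_features(features, center, scale)

  w <- numeric(d)
  b <- 0
  eps <- 1e-12
  prev <- NA_real_
  trace <- numeric(0)
  updates <- 0L
  repeat {
    p <- logistic(drop(x %*% w) + b)
    pc <- pmin(pmax(p, eps), 1 - eps)
    cost <- mean(-labels * log(pc) - (1 - labels) * log(1 - pc)) +
      cfg$l2 / 2 * sum(w^2)
    trace <- c(trace, cost)
    if (!is.na(prev) && (prev - cost) < cfg$tol * prev) break
    if (updates >= cfg$max_iter) break
    r <- p - labels
    w <- w - cfg$learning_rate * (drop(crossprod(x, r)) / n + cfg$l2 * w)
    b <- b - cfg$learning_rate * mean(r)
    updates <- updates + 1L
    prev <- cost
  }
  model <- new_lrc(w, b, center, scale, l2 = cfg$l2)
  attr(model, "cost_trace") <- trace
  attr(model, "n_updates") <- updates
  model
}

#' Posterior probability of conversion
#'
#' @param model An \code{lrc} model.
#' @param feature Numeric vector of length \code{input_dim}, or a matrix
#'   with one row per subject.
#' @return Probability (or vector of probabilities) in the open interval
#'   (0, 1).
#' @export
predict_proba <- function(model, feature) {
  x <- as_feature_matrix(feature, model$input_dim)
  x <- standardize_features(x, model$center, model$scale)
  p <- logistic(drop(x %*% model$weights) + model$bias)
  eps <- 1e-12
  pmin(pmax(p, eps), 1 - eps)
}

#' Hard class decision
#'
#' Label 1 (converter) iff the posterior is at least 0.5; the tie at exactly
#' 0.5 goes to the positive class, so the zero-weight model labels
#' everything a converter.
#'
#' @inheritParams predict_proba
#' @return Integer 0/1 label (or vector).
#' @export
predict_label <- function(model, feature) {
  as.integer(predict_proba(model, feature) >= 0.5)
}

#' @export
print.lrc <- function(x, ...) {
  cat(sprintf("<lrc> input_dim=%d, bias=%.4f, |w|=%.4f, l2=%g\n",
              x$input_dim, x$bias, sqrt(sum(x$weights^2)), x$l2))
  invisible(x)
}
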