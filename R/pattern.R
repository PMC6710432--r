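#' Derive a metabolic brain pattern from preprocessed scans
#'
#' The core fitting function. A principal component analysis is fitted on the
#' full training set (patient and control groups together), the component
#' coordinates are passed to a linear support vector machine — a soft-margin
#' classifier between the groups (disease-specific pattern) or an
#' epsilon-insensitive regressor of the motor scores (motor pattern) — and
#' the voxel-space pattern is reconstructed as `p = t(A) %*% (w / s)`, with
#' `s` the kernel scale. The pattern's sign is fixed so that the patient
#' (positive) group has the larger mean raw expression score; if the fitted
#' direction had to be flipped this is recorded in the returned object.
#'
#' Hyperparameters are chosen by grid search with inner k-fold
#' cross-validation unless `C` and `kernel_scale` are supplied.
#'
#' @param data A `feature_matrix` (see [feature_matrix()]).
#' @param timepoint Timepoint label used for training (default: all rows).
#' @param mode `"classification"` (group-discriminative pattern) or
#'   `"regression"` (motor-score pattern).
#' @param response Optional explicit response: labels in {-1, +1} for
#'   classification (default: `+1` for `positive_group`), numeric targets for
#'   regression (default: `meta$motor_score`).
#' @param positive_group Group label coded `+1` (default `"PD"`).
#' @param C,kernel_scale,epsilon Fixed hyperparameters; any `NULL` among
#'   `C`/`kernel_scale` triggers the grid search.
#' @param C_grid,scale_grid,epsilon_grid Grids for the search (log-spaced
#'   defaults).
#' @param cv_folds Folds for the inner cross-validation. For classification
#'   the folds are stratified and `cv_folds` is capped at the smallest class
#'   size.
#' @param seed Integer seed for the fold assignment.
#' @param tol,max_iter SMO solver controls.
#' @return Object of class `metabolic_pattern` with elements `pattern`
#'   (length-D voxel weights), `basis` (`pca_basis`), `model` (`svm_fit`),
#'   `mode`, `hyperparameters`, `sign_flipped`, `training` (metadata,
#'   response and raw training scores), `mask_index`, `dim`, `voxel_size`,
#'   `timepoint`.
#' @seealso [predict.metabolic_pattern()], [expression_scores()],
#'   [loocv_pattern()], [longitudinal_projection()], [region_weighting()]
#' @export
metabolic_pattern <- function(data, timepoint = NULL,
                              mode = c("classification", "regression"),
                              response = NULL, positive_group = "PD",
                              C = NULL, kernel_scale = NULL, epsilon = NULL,
                              C_grid = 10^(-3:3), scale_grid = 2^(-3:3),
                              epsilon_grid = NULL, cv_folds = 10, seed = 1,
                              tol = 1e-3, max_iter = 1e5) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "feature_matrix"))
  fm <- subset_rows(data, timepoint = timepoint)
  n <- nrow(fm$X)
  if (n < 3L) stop("need at least 3 training scans", call. = FALSE)
  if (is.null(response)) {
    response <- if (mode == "classification") {
      ifelse(fm$meta$group == positive_group, 1, -1)
    } else {
      if (is.null(fm$meta$motor_score))
        stop("regression mode needs `motor_score` metadata or `response`",
             call. = FALSE)
      fm$meta$motor_score
    }
  }
  if (length(response) != n) stop("response length mismatch", call. = FALSE)

  basis <- fit_pca(fm)
  feats <- pca_transform(basis, fm$X)

  search <- NULL
  if (is.null(C) || is.null(kernel_scale)) {
    k <- cv_folds
    if (mode == "classification")
      k <- min(k, min(table(response)))
    search <- grid_search_nested_cv(feats, response, C_grid = C_grid,
                                    scale_grid = scale_grid,
                                    epsilon_grid = epsilon_grid, k = k,
                                    seed = seed, mode = mode, tol = tol,
                                    max_iter = max_iter)
    C <- C %||% search$C
    kernel_scale <- kernel_scale %||% search$kernel_scale
    if (mode == "regression") epsilon <- epsilon %||% search$epsilon
  }
  model <- if (mode == "classification") {
    train_svc(feats, response, C = C, kernel_scale = kernel_scale,
              tol = tol, max_iter = max_iter)
  } else {
    train_svr(feats, response, C = C, epsilon = epsilon,
              kernel_scale = kernel_scale, tol = tol, max_iter = max_iter)
  }

  p <- drop(crossprod(basis$A, model$w / model$kernel_scale))
  if (max(abs(p)) == 0)
    stop("degenerate fit: all-zero pattern (w = 0)", call. = FALSE)
  raw <- drop(sweep(fm$X, 2L, basis$mean, "-") %*% p)
  flipped <- FALSE
  grp_pos <- fm$meta$group == positive_group
  if (any(grp_pos) && any(!grp_pos) &&
      mean(raw[grp_pos]) < mean(raw[!grp_pos])) {
    p <- -p
    raw <- -raw
    flipped <- TRUE
  }

  structure(list(pattern = p, basis = basis, model = model, mode = mode,
                 hyperparameters = list(C = C, kernel_scale = kernel_scale,
                                        epsilon = model$epsilon,
                                        cv = search, cv_folds = cv_folds,
                                        seed = seed),
                 sign_flipped = flipped,
                 training = list(meta = fm$meta, response = response,
                                 raw_scores = raw,
                                 positive_group = positive_group),
                 mask_index = fm$mask_index, dim = fm$dim,
                 voxel_size = fm$voxel_size, timepoint = timepoint,
                 call = match.call()),
            class = "metabolic_pattern")
}

#' Raw expression scores of scans on a pattern
#'
#' Projects each preprocessed scan onto the voxel-space pattern by inner
#' product. By default the pattern's training mean is subtracted first
#' (`<p, x - m>`); the SVM bias is never included — the score measures
#' pattern expression, not class membership.
#'
#' @param pattern A `metabolic_pattern`.
#' @param data A `feature_matrix` sharing the pattern's mask, or an N x D
#'   matrix of feature vectors.
#' @param centering Subtract the training mean before projecting?
#'   Default `TRUE`.
#' @return Numeric vector of raw scores, one per scan.
#' @export
expression_scores <- function(pattern, data, centering = TRUE) {
  stopifnot(inherits(pattern, "metabolic_pattern"))
  X <- if (inherits(data, "feature_matrix")) {
    if (!identical(data$mask_index, pattern$mask_index))
      stop("feature matrix mask does not match the pattern mask",
           call. = FALSE)
    data$X
  } else as.matrix(data)
  if (ncol(X) != length(pattern$pattern))
    stop("dimension mismatch", call. = FALSE)
  if (centering) X <- sweep(X, 2L, pattern$basis$mean, "-")
  drop(X %*% pattern$pattern)
}

#' Control-referenced standardization of expression scores
#'
#' @param raw Numeric raw scores to standardize.
#' @param reference Either a numeric vector of control raw scores (>= 2
#'   values) or the list returned by [control_reference()].
#' @return Numeric Z-values `(raw - mu) / sigma` with attributes `mu` and
#'   `sigma` (standard deviation with N-1 denominator).
#' @export
zscore <- function(raw, reference) {
  if (is.list(reference)) {
    mu <- reference$mu; sigma <- reference$sigma
  } else {
    if (length(reference) < 2L)
      stop("need at least 2 control scores", call. = FALSE)
    mu <- mean(reference); sigma <- stats::sd(reference)
  }
  if (!is.finite(sigma) || sigma <= 0)
    stop("zero standard deviation in the control reference", call. = FALSE)
  structure((raw - mu) / sigma, mu = mu, sigma = sigma)
}

#' Control-scan reference for Z-values
#'
#' Computes the mean and standard deviation of the raw expression scores of
#' all control scans across all timepoints — the reference against which
#' every Z-value of the analysis is standardized.
#'
#' @param pattern A `metabolic_pattern`.
#' @param data A `feature_matrix` containing the control scans.
#' @param control_group Group label of the controls (default `"control"`).
#' @return List with `mu`, `sigma`, `n`, and the control `scores`.
#' @export
control_reference <- function(pattern, data, control_group = "control") {
  stopifnot(inherits(data, "feature_matrix"))
  ctrl <- subset_rows(data, rows = which(data$meta$group == control_group))
  if (nrow(ctrl$X) < 2L)
    stop("need at least 2 control scans for the reference", call. = FALSE)
  sc <- expression_scores(pattern, ctrl)
  sigma <- stats::sd(sc)
  if (!is.finite(sigma) || sigma <= 0)
    stop("zero variance among control scores", call. = FALSE)
  list(mu = mean(sc), sigma = sigma, n = length(sc), scores = sc,
       control_group = control_group)
}

#' Predict method for metabolic patterns
#'
#' @param object A `metabolic_pattern`.
#' @param newdata A `feature_matrix` (or N x D matrix). Defaults to the
#'   training data.
#' @param type `"raw"` (expression score, default), `"z"` (control-referenced
#'   Z-value; needs `reference`), `"decision"` (SVM decision value including
#'   the bias), `"class"` (hard label, classification only), or `"response"`
#'   (alias for `"decision"`, natural for regression).
#' @param reference Control reference for `type = "z"`, from
#'   [control_reference()] or a numeric vector of control raw scores.
#' @param centering Passed to [expression_scores()] for `"raw"`/`"z"`.
#' @param ... Unused.
#' @return Numeric vector of scores or labels.
#' @export
predict.metabolic_pattern <- function(object, newdata = NULL,
                                      type = c("raw", "z", "decision",
                                               "class", "response"),
                                      reference = NULL, centering = TRUE,
                                      ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "raw") return(object$training$raw_scores)
    if (type %in% c("decision", "response")) return(fitted(object))
    stop("`newdata` is required for type = \"", type, "\"", call. = FALSE)
  }
  if (type %in% c("raw", "z")) {
    raw <- expression_scores(object, newdata, centering = centering)
    if (type == "raw") return(raw)
    if (is.null(reference))
      stop("`reference` is required for type = \"z\"", call. = FALSE)
    return(zscore(raw, reference))
  }
  Xm <- if (inherits(newdata, "feature_matrix")) newdata$X else
    as.matrix(newdata)
  coords <- pca_transform(object$basis, Xm)
  if (type %in% c("decision", "response"))
    return(decision_values(object$model, coords))
  if (object$mode != "classification")
    stop("type = \"class\" needs a classification pattern", call. = FALSE)
  classify(object$model, coords)
}

#' @export
print.metabolic_pattern <- function(x, ...) {
  cat(sprintf("metabolic brain pattern (%s)\n",
              if (x$mode == "classification")
                "group-discriminative, soft-margin SVC" else
                "motor-score regression, epsilon-SVR"))
  cat(sprintf("  %d voxels, %d principal components (N = %d scans%s)\n",
              length(x$pattern), x$basis$K, x$basis$N,
              if (!is.null(x$timepoint))
                paste0(", timepoint ", x$timepoint) else ""))
  h <- x$hyperparameters
  cat(sprintf("  C = %.4g, kernel scale = %.4g%s%s\n", h$C, h$kernel_scale,
              if (!is.null(h$epsilon)) sprintf(", epsilon = %.4g", h$epsilon)
              else "",
              if (x$sign_flipped) " (pattern sign flipped to PD-positive)"
              else ""))
  invisible(x)
}

#' @export
summary.metabolic_pattern <- function(object, ...) {
  raw <- object$training$raw_scores
  grp <- object$training$meta$group
  out <- list(pattern = object,
              pattern_norm = sqrt(sum(object$pattern^2)),
              positive_fraction = mean(object$pattern > 0),
              group_means = tapply(raw, grp, mean),
              cv_loss = object$hyperparameters$cv$cv_loss)
  class(out) <- "summary.metabolic_pattern"
  out
}

#' @export
print.summary.metabolic_pattern <- function(x, ...) {
  print(x$pattern)
  cat(sprintf("  |p| = %.4g, %.1f%% positive voxel weights\n",
              x$pattern_norm, 100 * x$positive_fraction))
  cat("  training raw score means by group:\n")
  print(signif(x$group_means, 4))
  if (!is.null(x$cv_loss))
    cat(sprintf("  inner-CV loss at selected hyperparameters: %.4g\n",
                x$cv_loss))
  invisible(x)
}

#' @export
coef.metabolic_pattern <- function(object, as_volume = FALSE, ...) {
  if (as_volume)
    devectorize(object$pattern, object$mask_index, object$dim)
  else object$pattern
}

#' @export
fitted.metabolic_pattern <- function(object, ...) {
  # training decision values: <p_unflipped, x - m> + b
  raw <- object$training$raw_scores
  if (object$sign_flipped) raw <- -raw
  raw + object$model$b
}

#' @export
residuals.metabolic_pattern <- function(object, ...) {
  if (object$mode != "regression")
    stop("residuals are defined for regression patterns", call. = FALSE)
  object$training$response - fitted(object)
}

#' Plot mid-volume slices of a pattern
#'
#' Shows axial slices of the voxel-weight map; positive weights (relative
#' hypermetabolism) in warm colors, negative (hypometabolism) in cool colors.
#'
#' @param x A `metabolic_pattern`.
#' @param slices Slice indices along the third axis (default: 4 evenly
#'   spaced interior slices).
#' @param ... Passed to [graphics::image()].
#' @export
plot.metabolic_pattern <- function(x, slices = NULL, ...) {
  vol <- coef(x, as_volume = TRUE)
  nz <- dim(vol)[3L]
  slices <- slices %||% unique(round(seq(0.3, 0.7, length.out = 4) * nz))
  lim <- max(abs(vol))
  pal <- grDevices::colorRampPalette(
    c("#2166AC", "#F7F7F7", "#B2182B"))(65)
  op <- graphics::par(mfrow = c(1, length(slices)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (s in slices) {
    graphics::image(vol[, , s], zlim = c(-lim, lim), col = pal,
                    axes = FALSE, asp = 1, main = paste("z =", s), ...)
  }
  invisible(x)
}
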