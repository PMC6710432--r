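# Linear-kernel support vector machines solved by sequential minimal
# optimization (SMO) on the dual, for L1-soft-margin classification and
# epsilon-insensitive (L1 loss) regression.
#
# Both duals are instances of
#   min_z  1/2 z' (yy' * K) z + p' z   s.t.  0 <= z <= C,  y'z = 0
# (classification: p = -1; regression: 2n variables with duplicated kernel,
# y = (+1,..,-1,..), p = (eps - t, eps + t)).  smo_solve() is the shared
# maximal-violating-pair solver.

smo_solve <- function(K, y, p, C, tol = 1e-3, max_iter = 1e5) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n, length(p) == n, C > 0, tol > 0)
  Q <- tcrossprod(y) * K
  z <- numeric(n)
  G <- p # gradient of the objective at z = 0
  eps_b <- 1e-12 * max(1, C)
  iter <- 0L
  repeat {
    yG <- -y * G
    up <- (y > 0 & z < C - eps_b) | (y < 0 & z > eps_b)
    lo <- (y > 0 & z > eps_b) | (y < 0 & z < C - eps_b)
    if (!any(up) || !any(lo)) {
      m <- if (any(up)) max(yG[up]) else -Inf
      M <- if (any(lo)) min(yG[lo]) else Inf
      break
    }
    iu <- which(up); il <- which(lo)
    i <- iu[which.max(yG[iu])]
    j <- il[which.min(yG[il])]
    m <- yG[i]; M <- yG[j]
    if (m - M < tol) break
    iter <- iter + 1L
    if (iter > max_iter)
      stop(sprintf(
        "SMO failed to converge within %d iterations (KKT violation %.3g)",
        as.integer(max_iter), m - M), call. = FALSE)
    # feasible step along d_i = y_i, d_j = -y_j (keeps y'z constant)
    curv <- K[i, i] + K[j, j] - 2 * K[i, j]
    delta <- if (curv > 1e-12) (m - M) / curv else Inf
    bound_i <- if (y[i] > 0) C - z[i] else z[i]
    bound_j <- if (y[j] > 0) z[j] else C - z[j]
    delta <- min(delta, bound_i, bound_j)
    di <- y[i] * delta
    dj <- -y[j] * delta
    z[i] <- min(max(z[i] + di, 0), C)
    z[j] <- min(max(z[j] + dj, 0), C)
    G <- G + Q[, i] * di + Q[, j] * dj
  }
  free <- z > eps_b & z < C - eps_b
  b <- if (any(free)) mean((-y * G)[free]) else (m + M) / 2
  if (!is.finite(b)) b <- 0
  list(z = z, b = b, iterations = iter, kkt_gap = max(m - M, 0))
}

#' Train a linear-kernel soft-margin SVM classifier
#'
#' Solves the L1-norm soft-margin dual by sequential minimal optimization
#' (maximal-violating-pair working-set selection) and recovers the primal
#' weight vector and bias. The linear kernel is
#' `k(x, x') = <x/s, x'/s>` with `s = kernel_scale`, so the stored `w` lives
#' in the scaled feature space and decision values are `<w, x/s> + b`.
#'
#' @param features N x K numeric matrix of training coordinates.
#' @param labels Numeric/integer vector of class labels in {-1, +1}.
#' @param C Box constraint (soft-margin cost), > 0.
#' @param kernel_scale Positive kernel scale `s`.
#' @param tol KKT violation tolerance for SMO termination (default 1e-3).
#' @param max_iter Iteration cap; non-convergence raises an error.
#' @return Object of class `svm_fit` with elements `mode`, `w`, `b`, `alpha`
#'   (dual coefficients, `0 <= alpha <= C`), `labels`, `C`, `kernel_scale`,
#'   `support` (indices with `alpha > 0`), `iterations`, `kkt_gap`.
#' @export
train_svc <- function(features, labels, C = 1, kernel_scale = 1,
                      tol = 1e-3, max_iter = 1e5) {
  features <- as.matrix(features)
  y <- as.numeric(labels)
  if (!all(y %in% c(-1, 1)))
    stop("`labels` must be coded -1/+1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training data contain a single class", call. = FALSE)
  if (C <= 0 || kernel_scale <= 0)
    stop("`C` and `kernel_scale` must be positive", call. = FALSE)
  Xs <- features / kernel_scale
  K <- tcrossprod(Xs)
  sol <- smo_solve(K, y, rep(-1, length(y)), C, tol = tol,
                   max_iter = max_iter)
  w <- drop(crossprod(Xs, sol$z * y))
  structure(list(mode = "classification", w = w, b = sol$b,
                 alpha = sol$z, labels = y, C = C,
                 kernel_scale = kernel_scale, epsilon = NULL,
                 support = which(sol$z > 1e-8),
                 iterations = sol$iterations, kkt_gap = sol$kkt_gap,
                 tol = tol),
            class = "svm_fit")
}

#' Train a linear-kernel epsilon-insensitive SVM regressor
#'
#' Solves the epsilon-SVR dual (L1 loss outside a tube of half-width
#' `epsilon`) by the same SMO core on the doubled problem. Points strictly
#' inside the tube receive zero dual coefficient.
#'
#' @inheritParams train_svc
#' @param targets Numeric response vector.
#' @param epsilon Tube half-width, >= 0. Default `0.1 * sd(targets)`.
#' @return Object of class `svm_fit` with `alpha` the signed dual
#'   coefficients (`|alpha| <= C`) such that `w = t(Xs) %*% alpha`.
#' @export
train_svr <- function(features, targets, C = 1, epsilon = NULL,
                      kernel_scale = 1, tol = 1e-3, max_iter = 1e5) {
  features <- as.matrix(features)
  t_ <- as.numeric(targets)
  n <- length(t_)
  if (nrow(features) != n) stop("row/target mismatch", call. = FALSE)
  if (C <= 0 || kernel_scale <= 0)
    stop("`C` and `kernel_scale` must be positive", call. = FALSE)
  epsilon <- epsilon %||% (0.1 * stats::sd(t_))
  if (!is.finite(epsilon) || epsilon < 0)
    stop("`epsilon` must be >= 0", call. = FALSE)
  Xs <- features / kernel_scale
  K <- tcrossprod(Xs)
  K2 <- rbind(cbind(K, K), cbind(K, K))
  y2 <- c(rep(1, n), rep(-1, n))
  p2 <- c(epsilon - t_, epsilon + t_)
  sol <- smo_solve(K2, y2, p2, C, tol = tol, max_iter = max_iter)
  beta <- sol$z[seq_len(n)] - sol$z[n + seq_len(n)]
  w <- drop(crossprod(Xs, beta))
  structure(list(mode = "regression", w = w, b = sol$b,
                 alpha = beta, targets = t_, C = C,
                 kernel_scale = kernel_scale, epsilon = epsilon,
                 support = which(abs(beta) > 1e-8),
                 iterations = sol$iterations, kkt_gap = sol$kkt_gap,
                 tol = tol),
            class = "svm_fit")
}

#' Continuous decision values of a fitted SVM
#'
#' @param model An `svm_fit`.
#' @param coords Length-K vector or N x K matrix of feature coordinates.
#' @return Numeric score(s) `<w, coords/s> + b`.
#' @export
decision_values <- function(model, coords) {
  stopifnot(inherits(model, "svm_fit"))
  if (!is.matrix(coords)) coords <- matrix(coords, nrow = 1L)
  if (ncol(coords) != length(model$w))
    stop("coordinate dimension does not match the model", call. = FALSE)
  drop(coords %*% (model$w / model$kernel_scale)) + model$b
}

#' Hard class labels from a fitted SVM classifier
#'
#' A decision value of exactly zero (a point on the separating hyperplane)
#' maps to +1 by convention.
#'
#' @inheritParams decision_values
#' @return Vector of labels in {-1, +1}.
#' @export
classify <- function(model, coords) {
  if (model$mode != "classification")
    stop("`classify()` needs a classification model", call. = FALSE)
  ifelse(decision_values(model, coords) >= 0, 1, -1)
}

#' @export
print.svm_fit <- function(x, ...) {
  cat(sprintf("linear %s SVM: K = %d, C = %.4g, kernel scale = %.4g%s\n",
              if (x$mode == "classification") "soft-margin" else
                "epsilon-insensitive", length(x$w), x$C, x$kernel_scale,
              if (!is.null(x$epsilon))
                sprintf(", epsilon = %.4g", x$epsilon) else ""))
  cat(sprintf("  %d support vectors, %d SMO iterations, KKT gap %.2g\n",
              length(x$support), x$iterations, x$kkt_gap))
  invisible(x)
}

# dual objective value 1/2 z'Qz + p'z of a fit, used by tests and diagnostics
dual_objective <- function(model, features) {
  Xs <- as.matrix(features) / model$kernel_scale
  K <- tcrossprod(Xs)
  if (model$mode == "classification") {
    z <- model$alpha; y <- model$labels
    sum(0.5 * z * y * (K %*% (z * y))) - sum(z)
  } else {
    beta <- model$alpha
    sum(0.5 * beta * (K %*% beta)) + model$epsilon * sum(abs(beta)) -
      sum(beta * model$targets)
  }
}

#' Cross-validation fold assignment
#'
#' Stratified (per-class balanced) folds for classification, plain random
#' folds for regression; deterministic for a fixed seed.
#'
#' @param y Label or target vector.
#' @param k Number of folds, >= 2.
#' @param stratify Stratify by the levels of `y`?
#' @param seed Integer RNG seed.
#' @return Integer vector of fold ids in `1..k`, one per observation.
#' @export
make_folds <- function(y, k, stratify = FALSE, seed = 1) {
  n <- length(y)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (n < k) stop("more folds than observations", call. = FALSE)
  with_seed(seed, {
    folds <- integer(n)
    if (stratify) {
      for (lv in unique(y)) {
        idx <- which(y == lv)
        if (length(idx) < k)
          stop(sprintf(
            "fold count (%d) exceeds the size of class '%s' (%d)",
            k, as.character(lv), length(idx)), call. = FALSE)
        folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(k), n)
    }
    folds
  })
}

#' Hyperparameter grid search with inner k-fold cross-validation
#'
#' Evaluates every grid point by k-fold cross-validation (misclassification
#' rate for classification, mean absolute error for regression, pooled over
#' held-out samples) and returns the minimizer. Ties are broken toward the
#' smaller `C`, then the smaller `kernel_scale`, then the smaller `epsilon`.
#'
#' @param features N x K coordinate matrix.
#' @param y Labels in {-1, +1} (classification) or numeric targets.
#' @param C_grid,scale_grid Positive candidate values (log grids by default).
#' @param epsilon_grid Candidate tube widths for regression; `NULL` (default)
#'   fixes `epsilon = 0.1 * sd(y)`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param mode `"classification"` or `"regression"`.
#' @param tol,max_iter Passed to the SMO solver.
#' @return List with the selected `C`, `kernel_scale`, `epsilon`, `cv_loss`,
#'   the full `grid` (data frame of losses) and the fold assignment.
#' @export
grid_search_nested_cv <- function(features, y,
                                  C_grid = 10^(-3:3),
                                  scale_grid = 2^(-3:3),
                                  epsilon_grid = NULL,
                                  k = 10, seed = 1,
                                  mode = c("classification", "regression"),
                                  tol = 1e-3, max_iter = 1e5) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(y) == n)
  folds <- make_folds(y, k, stratify = (mode == "classification"),
                      seed = seed)
  if (mode == "regression" && is.null(epsilon_grid))
    epsilon_grid <- 0.1 * stats::sd(y)
  if (mode == "classification") epsilon_grid <- NA_real_
  grid <- expand.grid(epsilon = epsilon_grid, kernel_scale = scale_grid,
                      C = C_grid, KEEP.OUT.ATTRS = FALSE)
  # tie-break order: smaller C, then scale, then epsilon
  grid <- grid[order(grid$C, grid$kernel_scale, grid$epsilon), , drop = FALSE]
  grid$cv_loss <- NA_real_
  for (g in seq_len(nrow(grid))) {
    err <- numeric(0)
    ok <- TRUE
    for (f in seq_len(k)) {
      tr <- folds != f
      if (!any(!tr)) next
      fit <- tryCatch({
        if (mode == "classification")
          train_svc(features[tr, , drop = FALSE], y[tr], C = grid$C[g],
                    kernel_scale = grid$kernel_scale[g], tol = tol,
                    max_iter = max_iter)
        else
          train_svr(features[tr, , drop = FALSE], y[tr], C = grid$C[g],
                    epsilon = grid$epsilon[g],
                    kernel_scale = grid$kernel_scale[g], tol = tol,
                    max_iter = max_iter)
      }, error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      pred <- decision_values(fit, features[!tr, , drop = FALSE])
      err <- c(err, if (mode == "classification")
        as.numeric(ifelse(pred >= 0, 1, -1) != y[!tr]) else
          abs(pred - y[!tr]))
    }
    grid$cv_loss[g] <- if (ok) mean(err) else Inf
  }
  best <- which(grid$cv_loss < min(grid$cv_loss) + 1e-12)[1L]
  list(C = grid$C[best], kernel_scale = grid$kernel_scale[best],
       epsilon = if (mode == "regression") grid$epsilon[best] else NULL,
       cv_loss = grid$cv_loss[best], grid = grid, folds = folds, mode = mode)
}
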