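#' Wilcoxon rank-sum test between two score groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. The exact null
#' distribution (full enumeration over assignments) is used for tie-free
#' samples with `n_a + n_b <= 25`; otherwise the normal approximation with
#' midrank tie correction and continuity correction is used. The two-sided
#' p-value doubles the smaller tail, capped at 1.
#'
#' @param a,b Numeric score vectors (both nonempty).
#' @return List with `statistic` (rank sum of `a`, midranks for ties), `u`
#'   (Mann-Whitney U of `a`), `p.value`, and `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b))
    stop("both groups must be nonempty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && (length(a) + length(b)) <= 25L
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  u <- unname(ht$statistic)
  list(statistic = u + length(a) * (length(a) + 1) / 2, u = u,
       p.value = ht$p.value, exact = exact)
}

#' Leave-one-out cross-validation at the pattern-derivation timepoint
#'
#' Each subject's scan is held out in turn and the entire model — PCA basis
#' (including the training mean) and SVM — is refitted on the remaining
#' scans, so the held-out scan influences no part of the fold's model. The
#' held-out scan is then classified (classification mode) and scored on the
#' fold's pattern. Hyperparameters are fixed across folds (pass the values
#' selected on the full training set or by an inner search).
#'
#' @param data A `feature_matrix` restricted to (or subset by `timepoint`
#'   to) the derivation timepoint, one scan per subject.
#' @param timepoint Optional timepoint label to subset `data`.
#' @param mode `"classification"` or `"regression"`.
#' @param C,kernel_scale,epsilon SVM hyperparameters applied in every fold.
#' @param positive_group Group coded `+1` (default `"PD"`).
#' @param tol,max_iter SMO controls.
#' @return Object of class `loocv_report`: list with `scores` (data frame:
#'   `subject_id`, `group`, `truth`, `predicted`, `decision`, `raw` — the
#'   held-out raw expression score on the fold's pattern), `accuracy_pd`,
#'   `accuracy_control` (classification mode; `NA` otherwise), `mode`,
#'   `hyperparameters`.
#' @export
loocv_pattern <- function(data, timepoint = NULL,
                          mode = c("classification", "regression"),
                          C = 1, kernel_scale = 1, epsilon = NULL,
                          positive_group = "PD", tol = 1e-3,
                          max_iter = 1e5) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "feature_matrix"))
  fm <- subset_rows(data, timepoint = timepoint)
  n <- nrow(fm$X)
  grp <- fm$meta$group
  tab <- table(grp)
  if (mode == "classification" && (length(tab) < 2L || min(tab) < 2L))
    stop("LOOCV needs at least 2 subjects per group", call. = FALSE)
  res <- data.frame(subject_id = fm$meta$subject_id, group = grp,
                    truth = ifelse(grp == positive_group, 1, -1),
                    predicted = NA_real_, decision = NA_real_,
                    raw = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (mode == "classification" &&
        length(unique(grp[tr])) < 2L)
      stop("a LOOCV fold contains a single class", call. = FALSE)
    fold <- metabolic_pattern(subset_rows(fm, rows = tr), mode = mode,
                              positive_group = positive_group, C = C,
                              kernel_scale = kernel_scale,
                              epsilon = epsilon, tol = tol,
                              max_iter = max_iter)
    x_held <- fm$X[i, , drop = FALSE]
    res$decision[i] <- predict(fold, x_held, type = "decision")
    if (mode == "classification")
      res$predicted[i] <- predict(fold, x_held, type = "class")
    res$raw[i] <- expression_scores(fold, x_held)
  }
  acc_pd <- acc_ctrl <- NA_real_
  if (mode == "classification") {
    acc_pd <- mean(res$predicted[res$truth == 1] == 1)
    acc_ctrl <- mean(res$predicted[res$truth == -1] == -1)
  }
  structure(list(scores = res, accuracy_pd = acc_pd,
                 accuracy_control = acc_ctrl, mode = mode,
                 hyperparameters = list(C = C, kernel_scale = kernel_scale,
                                        epsilon = epsilon)),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("leave-one-out cross-validation (%s)\n", x$mode))
  if (x$mode == "classification") {
    n_pd <- sum(x$scores$truth == 1); n_hc <- sum(x$scores$truth == -1)
    cat(sprintf("  accuracy: PD %.0f%% (%d/%d), control %.0f%% (%d/%d)\n",
                100 * x$accuracy_pd, round(x$accuracy_pd * n_pd), n_pd,
                100 * x$accuracy_control,
                round(x$accuracy_control * n_hc), n_hc))
  }
  invisible(x)
}

#' Longitudinal projection of a week-9 pattern with per-timepoint tests
#'
#' Scores every scan at every timepoint on the pattern derived at the final
#' timepoint: earlier timepoints by direct projection of the full pattern,
#' the derivation timepoint itself by the held-out scores of the supplied
#' LOOCV report (when given), avoiding training bias. Z-values standardize
#' all raw scores by the mean/SD of all control scans across all timepoints
#' projected on the full pattern. Groups are compared per timepoint with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param pattern The `metabolic_pattern` derived at the final timepoint.
#' @param data A `feature_matrix` with all timepoints.
#' @param loocv Optional `loocv_report` for the derivation timepoint.
#' @param reference Optional control reference (defaults to
#'   [control_reference()] on `data`).
#' @param alpha Significance level (default 0.05).
#' @param positive_group,control_group Group labels.
#' @return Object of class `longitudinal_result`: list with `scores` (data
#'   frame: `subject_id`, `group`, `timepoint`, `raw`, `z`), `tests` (data
#'   frame: `timepoint`, `n_pd`, `n_control`, `statistic`, `p`,
#'   `significant`), `reference`, `alpha`.
#' @export
longitudinal_projection <- function(pattern, data, loocv = NULL,
                                    reference = NULL, alpha = 0.05,
                                    positive_group = "PD",
                                    control_group = "control") {
  stopifnot(inherits(pattern, "metabolic_pattern"),
            inherits(data, "feature_matrix"))
  reference <- reference %||%
    control_reference(pattern, data, control_group = control_group)
  tps <- unique(data$meta$timepoint)
  train_tp <- pattern$timepoint
  scores <- NULL
  tests <- NULL
  for (tp in tps) {
    fm_tp <- subset_rows(data, timepoint = tp)
    raw <- expression_scores(pattern, fm_tp)
    if (!is.null(loocv) && !is.null(train_tp) && tp %in% train_tp) {
      m <- match(fm_tp$meta$subject_id, loocv$scores$subject_id)
      if (any(is.na(m)))
        stop("LOOCV report does not cover all derivation-timepoint subjects",
             call. = FALSE)
      raw <- loocv$scores$raw[m]
    }
    z <- as.numeric(zscore(raw, reference))
    scores <- rbind(scores, data.frame(
      subject_id = fm_tp$meta$subject_id, group = fm_tp$meta$group,
      timepoint = tp, raw = raw, z = z, stringsAsFactors = FALSE))
    grp <- fm_tp$meta$group
    if (any(grp == positive_group) && any(grp == control_group)) {
      wt <- wilcoxon_rank_sum(z[grp == positive_group],
                              z[grp == control_group])
      tests <- rbind(tests, data.frame(
        timepoint = tp, n_pd = sum(grp == positive_group),
        n_control = sum(grp == control_group), statistic = wt$statistic,
        p = wt$p.value, significant = wt$p.value < alpha,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(scores = scores, tests = tests, reference = reference,
                 alpha = alpha),
            class = "longitudinal_result")
}

#' @export
print.longitudinal_result <- function(x, ...) {
  cat("longitudinal pattern expression (Wilcoxon rank-sum, alpha =",
      x$alpha, ")\n")
  tt <- x$tests
  tt$p <- signif(tt$p, 3)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Box plot of longitudinal expression Z-values by group
#'
#' @param x A `longitudinal_result`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.longitudinal_result <- function(x, ...) {
  s <- x$scores
  s$timepoint <- factor(s$timepoint, levels = unique(s$timepoint))
  graphics::boxplot(z ~ group + timepoint, data = s,
                    col = c("grey85", "indianred"),
                    las = 2, ylab = "pattern expression (Z)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
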