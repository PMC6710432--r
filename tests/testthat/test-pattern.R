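test_that("the voxel pattern is t(A) w / s and an isometric image of w", {
  fm <- small_features()
  pat <- metabolic_pattern(fm, timepoint = "w9", mode = "classification",
                           C = 0.1, kernel_scale = 0.125)
  s <- pat$model$kernel_scale
  expected <- drop(crossprod(pat$basis$A, pat$model$w / s))
  if (pat$sign_flipped) expected <- -expected
  expect_equal(pat$pattern, expected, tolerance = 1e-8)
  # orthonormal rows of A make the map an isometry
  expect_equal(sqrt(sum(pat$pattern^2)), sqrt(sum((pat$model$w / s)^2)),
               tolerance = 1e-8)
})

test_that("pattern scores reproduce SVM decision values minus the bias", {
  fm <- subset_rows(small_features(), timepoint = "w9")
  pat <- metabolic_pattern(fm, mode = "classification", C = 0.1,
                           kernel_scale = 0.125)
  raw <- expression_scores(pat, fm)
  dec <- predict(pat, fm, type = "decision")
  flip <- if (pat$sign_flipped) -1 else 1
  expect_equal(flip * raw, dec - pat$model$b, tolerance = 1e-8)
  # classification by sign of <p, x - m> + b equals classify()
  expect_equal(ifelse(flip * raw + pat$model$b >= 0, 1, -1),
               predict(pat, fm, type = "class"))
})

test_that("an identity transform passes the weight vector through", {
  # K = D case: A orthonormal square, pattern = t(A) (w/s); project a
  # point constructed along the pattern to get a unit score
  set.seed(15)
  X <- matrix(rnorm(6 * 5), 6, 5)
  X <- t(apply(X, 1, normalize_feature))
  meta <- data.frame(subject_id = sprintf("S%d", 1:6),
                     group = rep(c("PD", "control"), each = 3),
                     timepoint = "w9",
                     image = sprintf("S%d", 1:6),
                     stringsAsFactors = FALSE)
  fm <- structure(list(X = X, meta = meta, mask_index = 1:5,
                       dim = c(5L, 1L, 1L), voxel_size = c(1, 1, 1),
                       fwhm = 0), class = "feature_matrix")
  pat <- metabolic_pattern(fm, mode = "classification", C = 10,
                           kernel_scale = 1)
  p_unit <- pat$pattern / sqrt(sum(pat$pattern^2))
  x <- pat$basis$mean + p_unit
  expect_equal(expression_scores(pat, matrix(x, 1)),
               sqrt(sum(pat$pattern^2)), tolerance = 1e-8)
  # orthogonal complement scores zero
  v <- rnorm(5)
  v <- v - sum(v * p_unit) * p_unit
  expect_equal(expression_scores(pat, matrix(pat$basis$mean + v, 1)),
               0, tolerance = 1e-8)
})

test_that("the sign convention puts the PD group on positive scores", {
  fm <- small_features()
  for (mode in c("classification", "regression")) {
    pat <- metabolic_pattern(fm, timepoint = "w9", mode = mode,
                             C = 10, kernel_scale = 0.25)
    raw <- pat$training$raw_scores
    grp <- pat$training$meta$group
    expect_gt(mean(raw[grp == "PD"]), mean(raw[grp == "control"]))
    expect_gt(mean(raw[grp == "PD"]), 0)
    expect_lt(mean(raw[grp == "control"]), 0)
  }
})

test_that("z-scores standardize against the control reference", {
  expect_equal(as.numeric(zscore(3, c(0, 1, 2))), 2)   # sd with N-1 = 1
  expect_equal(as.numeric(zscore(1, c(0, 1, 2))), 0)
  ref <- c(0.2, 0.5, 0.9, 1.4)
  z <- as.numeric(zscore(ref, ref))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(zscore(1, c(2, 2, 2)), "zero standard deviation")
  expect_error(zscore(1, 5), "at least 2")
})

test_that("pattern rescaling cancels in z-values derived from one object", {
  fm <- small_features()
  pat <- metabolic_pattern(fm, timepoint = "w9", mode = "classification",
                           C = 0.1, kernel_scale = 0.125)
  ref <- control_reference(pat, fm)
  z1 <- zscore(expression_scores(pat, fm), ref)
  scaled <- pat
  scaled$pattern <- 3 * pat$pattern
  ref2 <- control_reference(scaled, fm)
  z2 <- zscore(expression_scores(scaled, fm), ref2)
  expect_equal(as.numeric(z1), as.numeric(z2), tolerance = 1e-10)
})

test_that("model methods expose coefficients, fits and residuals", {
  fm <- small_features()
  pat <- metabolic_pattern(fm, timepoint = "w9", mode = "regression",
                           C = 100, kernel_scale = 0.5)
  expect_length(coef(pat), ncol(fm$X))
  vol <- coef(pat, as_volume = TRUE)
  expect_equal(dim(vol), fm$dim)
  expect_equal(vol[fm$mask_index], pat$pattern)
  fit9 <- fitted(pat)
  r <- residuals(pat)
  expect_equal(r, pat$training$response - fit9)
  expect_output(print(pat), "motor-score regression")
  expect_output(print(summary(pat)), "raw score means")
  cls <- metabolic_pattern(fm, timepoint = "w9", mode = "classification",
                           C = 0.1, kernel_scale = 0.125)
  expect_error(residuals(cls), "regression")
})

test_that("mask bookkeeping is enforced end to end", {
  fm <- small_features()
  pat <- metabolic_pattern(fm, timepoint = "w9", mode = "classification",
                           C = 0.1, kernel_scale = 0.125)
  other <- fm
  other$mask_index <- fm$mask_index[-1]
  other$X <- fm$X[, -1]
  expect_error(expression_scores(pat, other), "mask")
})
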