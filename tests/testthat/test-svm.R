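test_that("the symmetric separable pair gives the maximum-margin line", {
  fit <- train_svc(matrix(c(-1, 1), 2, 1), c(-1, 1), C = 100)
  expect_equal(unname(fit$w), 1, tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_equal(classify(fit, matrix(c(-3, 0.5), 2, 1)), c(-1, 1))
})

test_that("classifier duals are feasible and consistent with the primal", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(6:20, 1); k <- sample(2:5, 1)
    X <- matrix(rnorm(n * k), n, k)
    y <- sample(c(-1, 1), n, replace = TRUE)
    while (length(unique(y)) < 2) y <- sample(c(-1, 1), n, replace = TRUE)
    C <- sample(c(0.3, 1, 5), 1); s <- sample(c(0.5, 1, 2), 1)
    fit <- train_svc(X, y, C = C, kernel_scale = s, tol = 1e-6)
    expect_true(all(fit$alpha >= -1e-10 & fit$alpha <= C + 1e-10))
    expect_lt(abs(sum(fit$alpha * y)), 1e-8)
    expect_equal(fit$w, drop(crossprod(X / s, fit$alpha * y)),
                 tolerance = 1e-8)
  }
})

test_that("single-class input and bad hyperparameters fail loudly", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(train_svc(X, rep(1, 5), C = 1), "single class")
  expect_error(train_svc(X, c(1, 1, -1, -1, 0), C = 1), "-1/\\+1")
  expect_error(train_svc(X, c(1, 1, 1, -1, -1), C = -1), "positive")
  expect_error(train_svr(X, rnorm(5), C = 1, epsilon = -0.5), ">= 0")
})

test_that("SVR recovers a realizable line up to the tube slack", {
  set.seed(3)
  x <- matrix(runif(25, -5, 5), 25, 1)
  t <- 2 * drop(x)
  fit <- train_svr(x, t, C = 100, epsilon = 0.1, tol = 1e-6)
  expect_equal(unname(fit$w), 2, tolerance = 0.05)
  resid <- t - decision_values(fit, x)
  expect_true(all(abs(resid) <= 0.1 + 1e-6))
})

test_that("a tube wider than the target spread gives the trivial model", {
  set.seed(8)
  x <- matrix(rnorm(15), 15, 1)
  t <- 5 + rnorm(15, 0, 0.05)
  fit <- train_svr(x, t, C = 10, epsilon = 1)
  expect_equal(unname(fit$w), 0, tolerance = 1e-10)
  expect_length(fit$support, 0)
  expect_true(all(abs(t - fit$b) <= 1))   # bias inside the tube
})

test_that("decision values are linear with the documented tie-break", {
  fit <- structure(list(mode = "classification", w = c(1, 0), b = 0,
                        kernel_scale = 1), class = "svm_fit")
  expect_equal(decision_values(fit, c(3, 5)), 3)
  expect_equal(classify(fit, c(3, 5)), 1)
  expect_equal(classify(fit, c(0, 2)), 1)    # on the hyperplane -> +1
  neg <- fit; neg$w <- -fit$w; neg$b <- -fit$b
  co <- matrix(rnorm(10), 5, 2)
  expect_equal(decision_values(neg, co), -decision_values(fit, co))
})

test_that("kernel scale trades off exactly against feature scale", {
  set.seed(5)
  X <- matrix(rnorm(24), 12, 2)
  y <- rep(c(-1, 1), 6)
  f1 <- train_svc(X, y, C = 2, kernel_scale = 2, tol = 1e-8)
  f2 <- train_svc(X / 2, y, C = 2, kernel_scale = 1, tol = 1e-8)
  co <- matrix(rnorm(6), 3, 2)
  expect_equal(decision_values(f1, co), decision_values(f2, co / 2),
               tolerance = 1e-6)
  t <- drop(X %*% c(1, -1)) + rnorm(12, 0, 0.1)
  r1 <- train_svr(X, t, C = 2, epsilon = 0.2, kernel_scale = 2, tol = 1e-8)
  r2 <- train_svr(X / 2, t, C = 2, epsilon = 0.2, kernel_scale = 1,
                  tol = 1e-8)
  expect_equal(decision_values(r1, co), decision_values(r2, co / 2),
               tolerance = 1e-6)
})

test_that("row permutation leaves the solution unchanged", {
  set.seed(9)
  X <- matrix(rnorm(30), 15, 2)
  y <- c(rep(1, 7), rep(-1, 8))
  f1 <- train_svc(X, y, C = 1, tol = 1e-8)
  per <- sample(15)
  f2 <- train_svc(X[per, ], y[per], C = 1, tol = 1e-8)
  expect_equal(f1$w, f2$w, tolerance = 1e-8)
  expect_equal(f1$b, f2$b, tolerance = 1e-8)
})

test_that("objectives match libsvm on random overlapping instances", {
  skip_if_not_installed("e1071")
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(10:25, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    y <- sample(c(-1, 1), n, replace = TRUE)
    while (length(unique(y)) < 2) y <- sample(c(-1, 1), n, replace = TRUE)
    C <- sample(c(0.5, 2), 1)
    mine <- train_svc(X, y, C = C, tol = 1e-10)
    ref <- suppressWarnings(
      e1071::svm(X, factor(y), kernel = "linear", cost = C,
                 scale = FALSE, tolerance = 1e-7))
    w_ref <- drop(crossprod(as.matrix(X[ref$index, , drop = FALSE]),
                            ref$coefs))
    # e1071 orients w toward its first factor level
    if (sum(w_ref * mine$w) < 0) w_ref <- -w_ref
    expect_equal(mine$w, w_ref, tolerance = 1e-4)
  }
})

test_that("grid search is deterministic with documented tie-breaking", {
  set.seed(13)
  X <- rbind(matrix(rnorm(20, -2), 10, 2), matrix(rnorm(20, 2), 10, 2))
  y <- rep(c(-1, 1), each = 10)
  g1 <- grid_search_nested_cv(X, y, C_grid = c(0.01, 1, 100),
                              scale_grid = c(0.5, 1), k = 5, seed = 2,
                              mode = "classification")
  g2 <- grid_search_nested_cv(X, y, C_grid = c(0.01, 1, 100),
                              scale_grid = c(0.5, 1), k = 5, seed = 2,
                              mode = "classification")
  expect_identical(g1$folds, g2$folds)
  expect_identical(g1[c("C", "kernel_scale", "cv_loss")],
                   g2[c("C", "kernel_scale", "cv_loss")])
  # well-separated data: several C attain 0 loss; smallest such C wins
  zero <- g1$grid[g1$grid$cv_loss == 0, ]
  expect_equal(g1$cv_loss, 0)
  expect_equal(g1$C, min(zero$C))
  sel <- zero[zero$C == min(zero$C), ]
  expect_equal(g1$kernel_scale, min(sel$kernel_scale))
  # single grid point passes through
  g3 <- grid_search_nested_cv(X, y, C_grid = 1, scale_grid = 1, k = 5,
                              seed = 2, mode = "classification")
  expect_equal(g3$C, 1)
  expect_equal(g3$kernel_scale, 1)
  expect_true(is.finite(g3$cv_loss))
})

test_that("stratified folds refuse more folds than the smallest class", {
  y <- c(rep(1, 10), rep(-1, 8))
  expect_error(make_folds(y, 10, stratify = TRUE, seed = 1),
               "exceeds the size of class")
  f <- make_folds(y, 8, stratify = TRUE, seed = 1)
  expect_equal(sort(unique(f)), 1:8)
  # each fold holds at least one member of the larger class
  expect_true(all(table(f[y == 1]) >= 1))
})
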