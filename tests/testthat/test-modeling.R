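# Splitting, metrics, univariate baseline, LASSO, PLSR and VIP.

test_that("the 2:1 split reproduces the canonical sample counts", {
  sp <- split_dataset(204, seed = 1)
  expect_length(sp$calibration, 136)
  expect_length(sp$validation, 68)
  expect_length(intersect(sp$calibration, sp$validation), 0)
  expect_setequal(c(sp$calibration, sp$validation), 1:204)
  tiny <- split_dataset(3, seed = 9)
  expect_length(tiny$calibration, 2)
  expect_length(tiny$validation, 1)
  expect_identical(split_dataset(204, seed = 5), split_dataset(204, seed = 5))
  expect_false(identical(split_dataset(204, seed = 5)$calibration,
                         split_dataset(204, seed = 6)$calibration))
  expect_error(split_dataset(204, ratio = 1.2), "between 0 and 1")
  expect_error(split_dataset(2), "at least 3")
  df <- data.frame(x = 1:12)
  spd <- split_dataset(df, seed = 2)
  expect_identical(nrow(spd$calibration), 8L)
})

test_that("evaluation metrics match hand arithmetic and are translation-consistent", {
  perfect <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$bias, 0)
  shifted <- evaluate_predictions(c(3, 4, 5), c(1, 2, 3))
  expect_equal(shifted$bias, 2)
  expect_equal(shifted$rmse, 2)
  hand <- evaluate_predictions(c(1, 2, 5), c(1, 2, 3))
  expect_equal(hand$rmse, sqrt(4 / 3))
  expect_equal(hand$bias, 2 / 3)
  expect_equal(hand$rrmse_percent, 100 * sqrt(4 / 3) / 2)
  expect_equal(hand$r2, 1 - 4 / 2)
  # adding a constant to both vectors changes nothing but the context
  set.seed(1)
  o <- rnorm(50, 10)
  p <- o + rnorm(50, 0, 0.3)
  a <- evaluate_predictions(p, o)
  b <- evaluate_predictions(p + 7, o + 7)
  expect_equal(a$rmse, b$rmse)
  expect_equal(a$r2, b$r2)
  expect_equal(a$bias, b$bias)
  flat <- evaluate_predictions(c(1, 2), c(5, 5))
  expect_true(is.na(flat$r2))
})

test_that("univariate regression recovers exact lines and rejects junk", {
  m <- univariate_fit(c(0, 1, 2, 3), 2 * c(0, 1, 2, 3) + 1)
  expect_equal(m$slope, 2)
  expect_equal(m$intercept, 1)
  expect_equal(m$report$r2, 1)
  tri <- univariate_fit(c(0, 1, 2), c(0, 1, 2))
  expect_equal(tri$slope, 1)
  expect_equal(tri$report$rmse, 0)
  set.seed(2)
  noise <- univariate_fit(rnorm(1e4), rnorm(1e4))
  expect_lt(noise$report$r2, 0.01)
  expect_error(univariate_fit(rep(1, 5), 1:5), "zero-variance")
})

test_that("LASSO equals soft-thresholded OLS on an orthonormal design", {
  set.seed(7)
  n <- 64
  p <- 8
  Q <- qr.Q(qr(scale(matrix(rnorm(n * p), n, p), scale = FALSE)))
  X <- sqrt(n) * Q                      # columns: mean 0, n-variance 1
  beta <- c(3, -2, 1.5, 0, 0, 0.8, 0, 0)
  y <- drop(X %*% beta)
  y <- y - mean(y)
  z <- drop(crossprod(X, y)) / n        # OLS coefficients here
  lam <- 0.93
  path <- sort(unique(c(max(abs(z)) * 1.01, seq(2, 0.05, length.out = 40),
                        lam)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, lambda = path, standardize = FALSE,
                        thresh = 1e-14)
  got <- as.numeric(stats::coef(fit, s = lam, exact = TRUE, x = X, y = y))[-1]
  soft <- sign(z) * pmax(abs(z) - lam, 0)
  expect_equal(got, soft, tolerance = 1e-6)
  # a penalty above lambda_max shrinks every coefficient to zero
  lmax <- max(glmnet::glmnet(X, y, standardize = FALSE)$lambda)
  all0 <- as.numeric(stats::coef(fit, s = lmax * 1.01, exact = TRUE,
                                 x = X, y = y))[-1]
  expect_true(all(all0 == 0))
})

test_that("LASSO keeps the truly informative indices almost surely", {
  hits <- 0L
  for (r in 1:100) {
    X <- local({
      set.seed(1000 + r)
      matrix(rnorm(120 * 30), 120, 30,
             dimnames = list(NULL, paste0("idx", 1:30)))
    })
    y <- drop(X[, 1] + X[, 2] + X[, 3]) + local({
      set.seed(2000 + r)
      rnorm(120, 0, 0.5)
    })
    sel <- lasso_select(X, y, folds = 10, seed = r)
    if (all(c("idx1", "idx2", "idx3") %in% sel$selected)) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("lasso_select validates input and reports its path", {
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(lasso_select(X, rep(1, 20)), "constant")
  X[1, 1] <- NA
  expect_error(lasso_select(X, rnorm(20)), "finite")
  X[1, 1] <- 0
  y <- drop(X %*% c(2, 0, 0)) + rnorm(20, 0, 0.1)
  sel <- lasso_select(X, y, folds = 5, seed = 3)
  expect_true("a" %in% sel$selected)
  expect_true(all(c("lambda", "cvm", "nzero") %in% names(sel$cv)))
  # deterministic given the seed
  sel2 <- lasso_select(X, y, folds = 5, seed = 3)
  expect_identical(sel$lambda, sel2$lambda)
  expect_identical(sel$selected, sel2$selected)
})

test_that("rank-1 PLSR equals simple linear regression", {
  set.seed(5)
  x <- rnorm(30)
  y <- 2 + 1.5 * x + rnorm(30, 0, 0.2)
  m <- fit_plsr(matrix(x, dimnames = list(NULL, "x")), y, ncomp = 1)
  lmfit <- lm(y ~ x)
  expect_equal(unname(fitted(m)), unname(fitted(lmfit)), tolerance = 1e-10)
  expect_equal(unname(predict(m, matrix(c(-1, 0, 2), dimnames = list(NULL, "x")))),
               unname(predict(lmfit, data.frame(x = c(-1, 0, 2)))),
               tolerance = 1e-10)
})

test_that("full-component PLSR reproduces OLS predictions", {
  set.seed(6)
  X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, letters[1:5]))
  y <- drop(X %*% c(1, -2, 0.5, 0, 3)) + rnorm(40, 0, 0.5)
  m <- fit_plsr(X, y, ncomp = 5)
  ols <- lm(y ~ X)
  expect_equal(unname(fitted(m)), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("PLSR is invariant to sample order at fixed components", {
  set.seed(8)
  X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, letters[1:4]))
  y <- drop(X %*% c(1, 2, -1, 0.5)) + rnorm(50, 0, 0.3)
  perm <- sample(50)
  m1 <- fit_plsr(X, y, ncomp = 2)
  m2 <- fit_plsr(X[perm, ], y[perm], ncomp = 2)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-10)
})

test_that("cross-validated component choice is seeded and bounded", {
  set.seed(9)
  X <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, letters[1:6]))
  y <- drop(X %*% c(2, 1, 0, 0, 0, 0)) + rnorm(60, 0, 0.4)
  m1 <- fit_plsr(X, y, folds = 10, seed = 4)
  m2 <- fit_plsr(X, y, folds = 10, seed = 4)
  expect_identical(m1$ncomp, m2$ncomp)
  expect_equal(m1$cv_rmse, m2$cv_rmse)
  expect_lte(m1$ncomp, min(ncol(X), nrow(X) - 1))
  expect_error(fit_plsr(X, y, ncomp = 10), "exceeds")
})

test_that("PLSR predictions agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(12)
  X <- matrix(rnorm(45 * 6), 45, 6, dimnames = list(NULL, letters[1:6]))
  y <- drop(X %*% c(1, 0.5, -1, 0, 2, 0)) + rnorm(45, 0, 0.4)
  Xn <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(NULL, letters[1:6]))
  mine <- fit_plsr(X, y, ncomp = 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression")
  ref_pred <- drop(predict(ref, Xn)$predict[, 1, 3])
  expect_equal(unname(predict(mine, Xn)), unname(ref_pred),
               tolerance = 1e-6)
})

test_that("VIP scores satisfy the normalisation identity and flag signal", {
  set.seed(11)
  X <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, letters[1:5]))
  y <- 3 * X[, 2] + rnorm(100, 0, 0.05)
  m <- fit_plsr(X, y, ncomp = 3)
  vip <- vip_scores(m)
  expect_equal(mean(vip^2), 1, tolerance = 1e-12)
  expect_identical(names(which.max(vip)), "b")
  expect_gt(vip[["b"]], 1)
  expect_true("b" %in% attr(vip, "influential"))
  # a single-predictor model has VIP exactly 1
  m1 <- fit_plsr(matrix(X[, 1], dimnames = list(NULL, "a")), y, ncomp = 1)
  expect_equal(unname(m1$vip), 1, ignore_attr = TRUE)
  expect_error(vip_scores(lm(y ~ X)), "plsr_trait_model")
})

test_that("the two-stage trait model selects, fits and predicts", {
  set.seed(13)
  n <- 80
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("i", 1:12)))
  y <- drop(X %*% c(2, -1.5, rep(0, 10))) + rnorm(n, 0, 0.4)
  tm <- fit_trait_model(X, y, folds = 10, seed = 2, trait = "vcmax25")
  expect_s3_class(tm, "trait_model")
  expect_true(all(c("i1", "i2") %in% tm$plsr$x_names))
  expect_gte(length(tm$plsr$x_names), 2)
  pred <- predict(tm, X)
  expect_gt(evaluate_predictions(pred, y)$r2, 0.8)
  expect_identical(model_indices(tm), tm$plsr$x_names)
})
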