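# NIPALS PLS1, leave-one-out cross-validation and model metrics.

test_that("a single exactly-linear column is fit perfectly with one latent variable", {
  f <- fit_pls(cbind(x = c(1, 2, 3)), c(2, 4, 6), n_lv = 1)
  expect_equal(f$fitted, c(2, 4, 6), tolerance = 1e-12)
  expect_equal(regression_metrics(c(2, 4, 6), f$fitted)$rmse, 0, tolerance = 1e-10)
})

test_that("full-rank PLS reproduces ordinary least squares", {
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(8:15, 1); p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    y <- rnorm(n)
    f <- fit_pls(X, y, n_lv = p)
    expect_equal(f$fitted, unname(fitted(lm(y ~ X))), tolerance = 1e-8)
  }
})

test_that("latent-route and coefficient-route predictions coincide", {
  set.seed(7)
  X <- matrix(rpois(60, 3), 12, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- rnorm(12, 20, 4)
  f <- fit_pls(X, y, n_lv = 3)
  via_latent <- f$y_center + as.numeric(f$scores %*% f$y_loadings)
  expect_equal(f$fitted, via_latent, tolerance = 1e-8)
  # b_weighted and b_raw agree through the autoscaling
  expect_equal(unname(f$b_raw), unname(f$b_weighted / f$x_scale), tolerance = 1e-12)
})

test_that("constant columns are dropped without changing the model", {
  set.seed(11)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(10)
  f1 <- fit_pls(X, y, 2)
  X2 <- cbind(X, konst = 5)
  f2 <- fit_pls(X2, y, 2)
  expect_equal(f1$b_raw, f2$b_raw, tolerance = 1e-12)
  expect_equal(f2$dropped_columns, "konst")
  p1 <- predict(f1, X)
  p2 <- predict(f2, X2)
  expect_equal(unname(p1), unname(p2), tolerance = 1e-12)
})

test_that("rank and size preconditions are enforced", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))  # rank 1 after scaling
  expect_error(fit_pls(X, c(1, 2, 3, 5), n_lv = 2), "rank")
  expect_error(fit_pls(cbind(a = 1:2), 1:2, 1), "3 training rows")
  expect_error(fit_pls(cbind(a = rep(1, 5)), rnorm(5), 1), "constant")
})

test_that("prediction demands conforming columns and names the missing ones", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  f <- fit_pls(X, rnorm(10), 2)
  expect_error(predict(f, X[, c("a", "b"), drop = FALSE]), "c")
  # permuted and extended column order predicts identically
  Xp <- X[, c("d", "b", "a", "c")]
  expect_equal(predict(f, Xp), predict(f, X), tolerance = 1e-12)
})

test_that("autoscaling absorbs positive column rescaling", {
  set.seed(3)
  X <- matrix(rpois(50, 4) + 0.0, 10, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- rnorm(10, 15, 2)
  f1 <- fit_pls(X, y, 3)
  X2 <- sweep(X, 2, c(10, 0.5, 3, 1, 100), `*`)
  f2 <- fit_pls(X2, y, 3)
  expect_equal(predict(f1, X), predict(f2, X2), tolerance = 1e-8)
})

test_that("leave-one-out CV runs one fold per sample and matches an explicit refit oracle", {
  set.seed(4)
  n <- 12
  X <- matrix(rpois(n * 6, 2), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- rnorm(n, 10, 3)
  cv <- loo_cv(X, y, max_lv = 4)
  expect_equal(cv$n_folds, n)
  expect_equal(nrow(cv$predictions), n)
  expect_equal(cv$predictions, oracle_loo(X, y, 4), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_true(all(cv$rmsecv >= 0))
})

test_that("noiseless univariate response selects one latent variable with near-zero RMSECV", {
  X <- cbind(x = c(1, 3, 2, 5, 4, 7, 6, 9))
  y <- 2 * X[, "x"] + 1
  cv <- loo_cv(X, y, max_lv = 1)
  expect_lt(cv$rmsecv[1], 1e-8)
  expect_equal(cv$selected_lv, 1L)
  # with a second pure-noise column the signal column still wins by A = 2
  X2 <- cbind(X, junk = c(0, 1, 0, 1, 0, 1, 0, 1))
  cv2 <- loo_cv(X2, y, max_lv = 2)
  expect_lt(min(cv2$rmsecv), 1e-8)
  expect_equal(cv2$selected_lv, unname(which.min(cv2$rmsecv)))
})

test_that("calibration RMSE never increases with more latent variables", {
  set.seed(5)
  X <- matrix(rpois(15 * 8, 3), 15, 8, dimnames = list(NULL, paste0("v", 1:8)))
  y <- rnorm(15, 20, 5)
  rank <- qr(scale(X))$rank
  rmse <- vapply(seq_len(min(rank, 6)), function(A) {
    f <- fit_pls(X, y, A)
    sqrt(mean((y - f$fitted)^2))
  }, 0)
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("PLS predictions agree with mixOmics as an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(6)
  X <- matrix(rpois(20 * 10, 3) + 0.0, 20, 10,
              dimnames = list(paste0("m", 1:20), paste0("v", 1:10)))
  y <- rnorm(20, 25, 5)
  f <- fit_pls(X, y, n_lv = 4)
  mo <- mixOmics::pls(X, y, ncomp = 4, mode = "regression", scale = TRUE)
  pm <- predict(mo, X)$predict[, 1, 4]
  expect_equal(unname(f$fitted), unname(pm), tolerance = 1e-8)
})

test_that("regression metrics follow their closed forms", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$rmse, 0)
  expect_equal(m$r2, 1)
  expect_equal(m$slope, 1)

  m2 <- regression_metrics(c(0, 0, 1), c(3, 4, 1))
  expect_equal(m2$rmse, sqrt(mean(c(9, 16, 0))))

  # constant shift: rmse = |c|, correlation and slope untouched
  y <- c(1, 4, 2, 8)
  m3 <- regression_metrics(y, y + 2.5)
  expect_equal(m3$rmse, 2.5)
  expect_equal(m3$r2, 1)
  expect_equal(m3$slope, 1)

  expect_error(regression_metrics(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(regression_metrics(1, 1), "length")
})
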