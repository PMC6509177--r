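# MAS encoding, linear/multilinear calibration, SVR, MSE.

test_that("MAS grades encode to the published numeric scores", {
  expect_equal(encode_mas("1+"), 1.5)
  expect_equal(encode_mas("0"), 0)
  expect_equal(encode_mas(c("0", "1", "1+", "2", "3")),
               c(0, 1, 1.5, 2, 3))
  expect_error(encode_mas("4"), class = "spastr_grade_error")
  expect_error(encode_mas("moderate"), class = "spastr_grade_error")
})

test_that("single-variable calibration is exact OLS", {
  x <- c(1, 2, 3, 4)
  fit <- fit_linear(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  # mean-centred antisymmetric data: intercept = mean(y)
  x2 <- c(-2, -1, 1, 2)
  y2 <- c(-4, -2, 2, 4) + 3
  expect_equal(fit_linear(x2, y2)$intercept, 3)
  # random set matches the closed-form normal equations
  set.seed(5)
  xr <- rnorm(10); yr <- rnorm(10)
  b <- solve(crossprod(cbind(1, xr)), crossprod(cbind(1, xr), yr))
  fr <- fit_linear(xr, yr)
  expect_equal(fr$intercept, b[1], tolerance = 1e-10)
  expect_equal(fr$slope, b[2], tolerance = 1e-10)
  expect_equal(predict(fr, 2.5), b[1] + b[2] * 2.5, tolerance = 1e-10)
  expect_error(fit_linear(rep(1, 5), rnorm(5)),
               class = "spastr_calibrate_error")
})

test_that("multivariate calibration matches the pseudo-inverse oracle", {
  set.seed(6)
  X <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- X %*% c(1, 0, -2, 0.5) + rnorm(10, 0, 0.1)
  fit <- fit_multilinear(X, y)
  oracle <- qr.solve(cbind(1, X), y)
  expect_equal(fit$intercept, oracle[1], tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), unname(oracle[-1]),
               tolerance = 1e-10)
  expect_equal(predict(fit, X), as.numeric(cbind(1, X) %*% oracle),
               tolerance = 1e-10)
  # y depending on one column only: other coefficients vanish
  y1 <- 3 * X[, 2]
  f1 <- fit_multilinear(X, y1)
  expect_lt(max(abs(f1$coefficients[c("a", "c", "d")])), 1e-10)
  expect_equal(unname(f1$coefficients["b"]), 3, tolerance = 1e-10)
  # rank deficiency names the collinear column
  Xc <- cbind(X, e = X[, 1] + X[, 2])
  expect_error(fit_multilinear(Xc[1:8, ], rnorm(8)), "collinear",
               class = "spastr_calibrate_error")
  expect_error(fit_multilinear(X[1:3, ], rnorm(3)),
               class = "spastr_calibrate_error")
})

test_that("MSE is the mean of squared differences", {
  expect_equal(mse_score(c(1, 1), c(1, 1)), 0)
  expect_equal(mse_score(c(0, 2), c(1, 1)), 1)
  set.seed(8)
  s <- rnorm(24); l <- rnorm(24)
  expect_equal(mse_score(s, l), sum((l - s)^2) / 24, tolerance = 1e-12)
  expect_error(mse_score(1:3, 1:4), class = "spastr_calibrate_error")
})

test_that("SVR with constant labels predicts the constant", {
  set.seed(9)
  X <- matrix(rnorm(15), 5, 3)
  m <- fit_svr(X, rep(1.5, 5), svr_config())
  expect_equal(predict(m, matrix(rnorm(9), 3, 3)), rep(1.5, 3))
  expect_equal(m$dual_coeffs, rep(0, 5))
})

test_that("SVR dual at the published constants matches an independent QP oracle", {
  # 5 training points, C = 30, epsilon = 0.09, sigma = 0.007 (raw features);
  # oracle = libsvm's SMO solver at tight tolerance, an independent
  # implementation of the same dense QP
  skip_if_not_installed("e1071")
  set.seed(10)
  X <- matrix(runif(25, 0, 0.02), 5, 5)
  y <- c(0, 1, 1.5, 2, 3)
  cfg <- svr_config()
  expect_equal(cfg$penalty_c, 30)
  m <- fit_svr(X, y, cfg)
  o <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                  gamma = 1 / (2 * cfg$sigma^2), cost = cfg$penalty_c,
                  epsilon = cfg$epsilon, scale = FALSE, tolerance = 1e-8)
  beta_o <- rep(0, 5)
  beta_o[o$index] <- o$coefs
  expect_equal(m$dual_coeffs, beta_o, tolerance = 1e-4)
  expect_equal(m$bias, -o$rho, tolerance = 1e-4)
  expect_true(all(abs(m$dual_coeffs) <= cfg$penalty_c + 1e-8))
})

test_that("SVR solution matches libsvm on generic standardized problems", {
  skip_if_not_installed("e1071")
  set.seed(12)
  X <- matrix(rnorm(5 * 23), 23, 5)
  y <- as.numeric(scale(X %*% rnorm(5))) + rnorm(23, 0, 0.3)
  cfg <- svr_config(sigma = sqrt(2.5))
  m <- fit_svr(X, y, cfg)
  o <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                  gamma = 1 / (2 * cfg$sigma^2), cost = 30, epsilon = 0.09,
                  scale = FALSE, tolerance = 1e-8)
  Xn <- matrix(rnorm(20), 4, 5)
  expect_equal(predict(m, Xn), as.numeric(predict(o, Xn)),
               tolerance = 1e-5)
})

test_that("duplicating a training point leaves predictions unchanged", {
  set.seed(13)
  X <- matrix(rnorm(12), 4, 3)
  y <- c(0, 1, 2, 3)
  cfg <- svr_config(sigma = 1.5)
  m1 <- fit_svr(X, y, cfg)
  m2 <- fit_svr(X[c(1, 1:4), ], y[c(1, 1:4)], cfg)
  Xn <- matrix(rnorm(15), 5, 3)
  expect_equal(predict(m1, Xn), predict(m2, Xn), tolerance = 1e-6)
})

test_that("SVR prediction is invariant to the training order", {
  set.seed(14)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  cfg <- svr_config(sigma = 1.2)
  per <- sample(10)
  m1 <- fit_svr(X, y, cfg)
  m2 <- fit_svr(X[per, ], y[per], cfg)
  Xn <- matrix(rnorm(9), 3, 3)
  expect_equal(predict(m1, Xn), predict(m2, Xn), tolerance = 1e-6)
})

test_that("standardization statistics come from the training data only", {
  set.seed(15)
  X <- matrix(rnorm(40, mean = 7, sd = 3), 10, 4)
  y <- rnorm(10)
  m <- fit_svr(X, y, svr_config(sigma = 1.5, standardize_features = TRUE))
  expect_equal(m$center, colMeans(X))
  expect_equal(m$scale, apply(X, 2, sd))
  # prediction on a far-away point decays to the bias, proving the stored
  # statistics (not the new data) define the kernel scale
  far <- matrix(100, 1, 4)
  expect_equal(predict(m, far), m$bias, tolerance = 1e-6)
})
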