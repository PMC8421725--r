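make_split <- function(train_rows, val_rows) {
  structure(list(train_rows = train_rows, val_rows = val_rows,
                 seed = 0L, fraction = length(train_rows) /
                   (length(train_rows) + length(val_rows))),
            class = "split_index")
}

test_that("a two-point line is fit exactly", {
  b <- activation_bundle(list(x = matrix(c(0, 1, 2, 3), 4, 1)),
                         c("a", "b", "c", "d"))
  rec <- recording_set(matrix(c(1, 3, 5, 7), 4, 1), "IT",
                       c("a", "b", "c", "d"))
  fit <- fit_linear(b, rec, make_split(1:2, 3:4), ridge_lambda = 0)
  expect_equal(as.numeric(fit$coefficients), 2, tolerance = 1e-12)
  expect_equal(fit$intercepts, 1, tolerance = 1e-12)
})

test_that("an exactly linear target is recovered on held-out rows", {
  b <- tiny_bundle(n = 50, dims = c(a = 4, b = 3), seed = 1)
  X <- cbind(b$matrices$a, b$matrices$b)
  beta <- matrix(seq(-1, 1, length.out = 7 * 2), 7, 2)
  y <- X %*% beta + matrix(c(0.5, -0.25), 50, 2, byrow = TRUE)
  rec <- recording_set(y, c("V4", "IT"), b$stimulus_ids)
  sp <- split_rows(50, 0.8, seed = 2)
  fit <- fit_linear(b, rec, sp, ridge_lambda = 0)
  pred <- predict_linear(fit, b)
  expect_lt(mae(pred[sp$val_rows, ], y[sp$val_rows, ]), 1e-8)
})

test_that("closed-form fit matches an independent normal-equation oracle", {
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- 40; d <- 5; s <- 3
      X <- matrix(rnorm(n * d), n, d)
      Y <- matrix(rnorm(n * s), n, s)
      b <- activation_bundle(list(f = X), sprintf("s%02d", 1:n))
      rec <- recording_set(Y, c("V4", "IT", "IT"), b$stimulus_ids)
      sp <- split_rows(n, 0.75, seed = i)
      fit <- fit_linear(b, rec, sp, ridge_lambda = 0)
      # oracle: append an intercept column, solve the stacked normal
      # equations directly on the training rows
      Xa <- cbind(1, X[sp$train_rows, ])
      beta_o <- solve(crossprod(Xa), crossprod(Xa, Y[sp$train_rows, ]))
      expect_equal(fit$intercepts, as.numeric(beta_o[1, ]),
                   tolerance = 1e-8)
      expect_equal(unname(fit$coefficients), unname(beta_o[-1, ]),
                   tolerance = 1e-8)
    }
  })
})

test_that("closed-form fit agrees with gradient descent on the same objective", {
  withr::with_seed(9, {
    n <- 30; d <- 3
    X <- matrix(rnorm(n * d), n, d)
    y <- matrix(X %*% c(1, -2, 0.5) + 0.3 + rnorm(n, sd = 0.1), n, 1)
  })
  b <- activation_bundle(list(f = X), sprintf("s%02d", 1:n))
  rec <- recording_set(y, "IT", b$stimulus_ids)
  sp <- make_split(1:n %% 5 != 0, which(1:n %% 5 == 0))
  sp$train_rows <- which(1:n %% 5 != 0)
  lam <- 0.5
  fit <- fit_linear(b, rec, sp, ridge_lambda = lam)
  # plain gradient descent on sum((y - Xb - b0)^2) + lam * sum(b^2)
  Xtr <- X[sp$train_rows, ]; ytr <- y[sp$train_rows, ]
  beta <- numeric(d); b0 <- 0
  for (it in 1:20000) {
    r <- as.numeric(Xtr %*% beta) + b0 - ytr
    gb <- 2 * as.numeric(crossprod(Xtr, r)) + 2 * lam * beta
    g0 <- 2 * sum(r)
    beta <- beta - 1e-3 * gb / length(ytr)
    b0 <- b0 - 1e-3 * g0 / length(ytr)
  }
  expect_equal(as.numeric(fit$coefficients), beta, tolerance = 1e-4)
  expect_equal(fit$intercepts, b0, tolerance = 1e-4)
})

test_that("the underdetermined case demands a ridge penalty", {
  b <- tiny_bundle(n = 10, dims = c(wide = 30), seed = 4)
  rec <- tiny_recordings(b, n_sites = 2, regions = c("V4", "IT"))
  sp <- split_rows(10, 0.8, seed = 1)
  expect_error(fit_linear(b, rec, sp, ridge_lambda = 0), "ridge_lambda")
  expect_s3_class(fit_linear(b, rec, sp, ridge_lambda = 1),
                  "linear_map_model")
})

test_that("prediction is affine: intercept passthrough and additivity", {
  b <- tiny_bundle(n = 6, dims = c(a = 3), seed = 5)
  fit <- structure(list(coefficients = matrix(c(1, 2, 3, -1, 0, 1), 3, 2),
                        intercepts = c(0.5, -0.5), ridge_lambda = 0,
                        source_layers = "a"),
                   class = "linear_map_model")
  zero <- activation_bundle(list(a = matrix(0, 2, 3)), c("p", "q"))
  p0 <- predict_linear(fit, zero)
  expect_equal(p0, matrix(c(0.5, 0.5, -0.5, -0.5), 2, 2))
  # f(x1 + x2) - f(x2) = f(x1) - f(0)
  x1 <- matrix(rnorm(3), 1, 3); x2 <- matrix(rnorm(3), 1, 3)
  f <- function(x) predict_linear(fit,
    activation_bundle(list(a = x), "s"))
  expect_equal(f(x1 + x2) - f(x2), f(x1) - f(matrix(0, 1, 3)),
               tolerance = 1e-12)
})

test_that("r_squared is 1 for perfect fits and 0 for the mean predictor", {
  b <- tiny_bundle(n = 40, dims = c(a = 3), seed = 6)
  y <- b$matrices$a %*% matrix(rnorm(6), 3, 2) + 1
  rec <- recording_set(y, c("V4", "IT"), b$stimulus_ids)
  sp <- split_rows(40, 0.8, seed = 3)
  fit <- fit_linear(b, rec, sp, ridge_lambda = 0)
  r2 <- r_squared(fit, b, rec, rows = sp$val_rows)
  expect_equal(unname(r2$per_site), c(1, 1), tolerance = 1e-8)

  # a model predicting each site's mean response scores exactly 0
  rows <- sp$val_rows
  mean_model <- structure(list(
    coefficients = matrix(0, 3, 2),
    intercepts = colMeans(y[rows, , drop = FALSE]),
    ridge_lambda = 0, source_layers = "a"), class = "linear_map_model")
  r2m <- r_squared(mean_model, b, rec, rows = rows)
  expect_equal(unname(r2m$per_site), c(0, 0), tolerance = 1e-12)
})

test_that("zero-variance sites are excluded from mean R-squared with a warning", {
  b <- tiny_bundle(n = 20, dims = c(a = 2), seed = 7)
  y <- cbind(b$matrices$a %*% c(1, 1), rep(2, 20))
  rec <- recording_set(y, c("IT", "IT"), b$stimulus_ids)
  sp <- split_rows(20, 0.8, seed = 2)
  fit <- fit_linear(b, rec, sp, ridge_lambda = 1e-8)
  expect_warning(r2 <- r_squared(fit, b, rec, rows = sp$val_rows),
                 "zero-variance")
  expect_true(is.na(r2$per_site[2]))
  expect_false(is.na(r2$mean))
})

test_that("the ridge path collapses to the intercept-only model", {
  b <- tiny_bundle(n = 60, dims = c(a = 4), seed = 8)
  y <- b$matrices$a %*% rnorm(4) + 0.2
  rec <- recording_set(matrix(y, 60, 1), "IT", b$stimulus_ids)
  sp <- split_rows(60, 0.8, seed = 4)
  fit_huge <- fit_linear(b, rec, sp, ridge_lambda = 1e12)
  pred <- predict_linear(fit_huge, b)[sp$val_rows, , drop = FALSE]
  intercept_only <- matrix(mean(y[sp$train_rows]), length(sp$val_rows), 1)
  expect_equal(pred, intercept_only, tolerance = 1e-6)
})

test_that("held-out MAE approaches the analytic Gaussian noise floor", {
  n <- 2500; d <- 50; sigma <- 0.05
  b <- gen_activations(n, d, seed = 91)
  gt <- make_ground_truth("linear", d, n_sites = 20, seed = 92)
  rec <- gen_recordings(b, gt, noise_model(sd = sigma, seed = 93))
  sp <- split_rows(n, 0.8, seed = 94)   # 2000 training rows
  fit <- fit_linear(b, rec, sp)
  pred <- predict_linear(fit, b)
  err <- mae(pred[sp$val_rows, ], rec$responses[sp$val_rows, ])
  floor_ <- sigma * sqrt(2 / pi)
  expect_lt(abs(err - floor_) / floor_, 0.10)
})
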