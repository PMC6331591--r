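make_net <- function(W1, b1, w2, b2, xc, xs, yc, ys) {
  mucosim:::mlp_net(W1, b1, w2, b2, xc, xs, yc, ys,
                    mlp_config(n_hidden = length(b1)), init_seed = 0)
}

test_that("forward pass: zero-weight net returns the inverse-scaled bias", {
  net <- make_net(matrix(0, 3, 2), rep(0, 3), rep(0, 3), b2 = 1.5,
                  xc = c(0, 0), xs = c(1, 1), yc = 10, ys = 4)
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(nn_forward(net, X), rep(10 + 4 * 1.5, 10))
  # determinism
  expect_identical(nn_forward(net, X), nn_forward(net, X))
})

test_that("forward pass: hand-set net realizes y = x1 via the linear regime", {
  # sigma(eps*x) ~ 0.5 + eps*x/4 near 0; one hidden unit with weight eps,
  # output weight 4/eps and bias -2/eps yields y ~ x1 with O(eps^2) error
  eps <- 1e-5
  net <- make_net(matrix(c(eps, 0, 0, 0, 0, 0), 2, 3), c(0, 0),
                  c(4 / eps, 0), b2 = -2 / eps,
                  xc = rep(0, 3), xs = rep(1, 3), yc = 0, ys = 1)
  X <- cbind(seq(-2, 2, length.out = 9), rnorm(9), rnorm(9))
  expect_equal(nn_forward(net, X), X[, 1], tolerance = 1e-6)
  expect_error(nn_forward(net, X[, 1:2]), "feature count")
})

test_that("LM training is exact on linear targets (OLS oracle)", {
  x <- seq(-1, 1, length.out = 50)
  y <- 2 * x + 1
  net <- lm_train(matrix(x), y, mlp_config(n_hidden = 10), init_seed = 3)
  pred <- nn_forward(net, matrix(x))
  expect_lt(mean((pred - y)^2), 1e-8)
  # OLS oracle: the best linear map, fit independently
  ols <- stats::lm.fit(cbind(1, x), y)
  expect_equal(pred, ols$fitted.values, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("constant targets take the exact shortcut", {
  net <- lm_train(matrix(rnorm(20)), rep(3.25, 20))
  expect_equal(net$stop_reason, "constant_y")
  expect_equal(nn_forward(net, matrix(rnorm(7))), rep(3.25, 7))
})

test_that("LM fits sin(pi x); attainability cross-checked with BFGS", {
  set.seed(99)
  x <- matrix(seq(-1, 1, length.out = 100))
  y <- sin(pi * x[, 1])
  cfg <- mlp_config(n_hidden = 10, n_restarts = 10, seed = 1)
  mses <- vapply(seq_len(cfg$n_restarts), function(r) {
    net <- lm_train(x, y, cfg, init_seed = cfg$seed + r - 1)
    mean((nn_forward(net, x) - y)^2)
  }, numeric(1))
  expect_lt(min(mses), 1e-4)

  # independent optimizer on the same architecture confirms the target is
  # representable: BFGS with the analytic MSE gradient
  ys <- (y - mean(y)) / stats::sd(y)
  nh <- 10
  obj <- function(th) {
    w <- mucosim:::nn_unpack(th, 1, nh)
    mean((mucosim:::nn_forward_std(w, x)$yhat - ys)^2)
  }
  grad <- function(th) {
    w <- mucosim:::nn_unpack(th, 1, nh)
    f <- mucosim:::nn_forward_std(w, x)
    J <- mucosim:::nn_jacobian(w, x, f$H)
    as.vector(2 * crossprod(J, f$yhat - ys) / length(ys))
  }
  set.seed(11)
  best <- min(vapply(1:5, function(i) {
    th0 <- stats::runif(3 * nh + 1, -0.5, 0.5)
    stats::optim(th0, obj, grad, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))$value
  }, numeric(1)))
  expect_lt(best * stats::var(y), 1e-4)  # back on the original scale
})

test_that("accepted-step training MSE is monotone non-increasing", {
  set.seed(4)
  x <- matrix(rnorm(120), 60, 2)
  y <- tanh(x[, 1]) + 0.5 * x[, 2]^2
  net <- lm_train(x, y, mlp_config(n_hidden = 6, max_iter = 150),
                  init_seed = 5)
  mse <- net$trace$mse[net$trace$accepted]
  expect_true(all(diff(mse) <= 0))
  expect_gt(nrow(net$trace), 5)
})

test_that("LM limits: large mu ~ gradient descent, small mu ~ Gauss-Newton", {
  n <- 200
  Xs <- matrix(seq(-2, 2, length.out = n), n, 1)
  ys <- sin(Xs[, 1])
  # fixed, well-separated two-unit net so J'J is invertible
  w <- list(W1 = matrix(c(1.3, -0.7), 2, 1), b1 = c(0.4, -0.9),
            w2 = c(0.8, -0.5), b2 = 0.1)
  f <- mucosim:::nn_forward_std(w, Xs)
  J <- mucosim:::nn_jacobian(w, Xs, f$H)
  r <- f$yhat - ys
  g <- crossprod(J, r)
  p <- 7L
  step <- function(mu) solve(crossprod(J) + mu * diag(p), -g)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cosine(step(1e10), -g), 1 - 1e-6)
  gn <- solve(crossprod(J), -g)
  expect_gt(cosine(step(1e-9), gn), 1 - 1e-6)
})

test_that("training is affine-invariant in the target for fixed seeds", {
  set.seed(21)
  x <- matrix(rnorm(80), 40, 2)
  y <- sin(x[, 1]) * exp(-x[, 2]^2)
  cfg <- mlp_config(n_hidden = 5, max_iter = 60)
  n1 <- lm_train(x, y, cfg, init_seed = 9)
  n2 <- lm_train(x, 100 * y - 7, cfg, init_seed = 9)
  expect_equal(nn_forward(n1, x), (nn_forward(n2, x) + 7) / 100,
               tolerance = 1e-6)
})

test_that("evaluate_fit matches closed forms and the noise oracle", {
  y <- as.numeric(1:10)
  f <- evaluate_fit(y, y)
  expect_equal(c(f$slope, f$intercept, f$r_squared), c(1, 0, 1))
  f <- evaluate_fit(y, 2 * y)
  expect_equal(c(f$slope, f$intercept, f$r_squared), c(2, 0, 1))
  f <- evaluate_fit(y, 3 * y + 4)
  expect_equal(c(f$slope, f$intercept), c(3, 4))
  expect_equal(f$r_squared, 1)
  # noisy case: population R^2 = 1 / (1 + var_e/var_y)
  set.seed(31)
  n <- 4000
  yt <- rnorm(n, sd = 1)
  eps <- rnorm(n, sd = 0.2)
  f <- evaluate_fit(yt, yt + eps)
  expect_equal(f$r_squared, 1 / (1 + 0.04), tolerance = 0.01)
  expect_error(evaluate_fit(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(evaluate_fit(1:2, 1:2), "length")
})

test_that("restart selection is deterministic and picks min test MSE", {
  df <- synthetic_cohort(50)
  X <- as.matrix(df[, c("blood_Cmax", "blood_tmax", "blood_AUC",
                        "blood_C24")])
  y <- df$t_lag
  cfg <- mlp_config(n_hidden = 4, n_restarts = 4, max_iter = 40, seed = 2)
  a <- train_with_restarts(X[1:40, ], y[1:40], X[41:50, ], y[41:50], cfg)
  b <- train_with_restarts(X[1:40, ], y[1:40], X[41:50, ], y[41:50], cfg)
  expect_identical(a$net$W1, b$net$W1)
  expect_equal(a$selected, which.min(a$restart_mse))
  expect_equal(a$report$mse, min(a$restart_mse))
})

test_that("identity map trains to a near-perfect fit report", {
  set.seed(13)
  x <- matrix(runif(80, -1, 1))
  tr <- train_with_restarts(x, x[, 1], x[41:80, , drop = FALSE], x[41:80, 1],
                            mlp_config(n_hidden = 5, n_restarts = 3,
                                       max_iter = 120, seed = 1))
  expect_equal(tr$report$slope, 1, tolerance = 1e-3)
  expect_equal(tr$report$intercept, 0, tolerance = 1e-3)
  expect_gt(tr$report$r_squared, 0.9999)
})

test_that("networks round-trip through the JSON schema", {
  set.seed(17)
  x <- matrix(rnorm(60), 30, 2)
  y <- x[, 1] - 2 * x[, 2] + x[, 1] * x[, 2]
  net <- lm_train(x, y, mlp_config(n_hidden = 3, max_iter = 50),
                  init_seed = 4)
  tf <- withr::local_tempfile(fileext = ".json")
  write_net_json(net, tf)
  back <- read_net_json(tf)
  expect_equal(nn_forward(back, x), nn_forward(net, x), tolerance = 1e-12)
  expect_equal(back$init_seed, net$init_seed)
  expect_error(read_net_json(write_config(withr::local_tempfile(
    fileext = ".json"), foo = 1)), "not a serialized")
})
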