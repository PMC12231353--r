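test_that("initialization is seed-reproducible with the right parameter count", {
  m1 <- mlp_fit(matrix(runif(28), 2), c(0, 1), hidden = 25,
                role = "classifier", control = mlp_control(max_epochs = 0),
                seed = 5)
  expect_length(coef(m1), 14 * 25 + 25 + 25 * 1 + 1)   # 401 for [14, 25, 1]
  m2 <- mlp_fit(matrix(runif(28), 2), c(0, 1), hidden = 25,
                role = "classifier", control = mlp_control(max_epochs = 0),
                seed = 5)
  expect_identical(coef(m1), coef(m2))
  m3 <- mlp_fit(matrix(runif(28), 2), c(0, 1), hidden = 25,
                role = "classifier", control = mlp_control(max_epochs = 0),
                seed = 6)
  expect_false(identical(coef(m1), coef(m3)))
})

test_that("the forward pass matches a hand computation and is batch-invariant", {
  # hand-built 2-2-1 net evaluated on the normalized scale
  x <- rbind(c(-1, 1), c(0.5, -0.25), c(1, -1))
  m <- mlp_fit(x, c(0, 1, 0), hidden = 2, role = "classifier",
               control = mlp_control(max_epochs = 0), seed = 1)
  m$W <- list(matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2), matrix(c(1.5, -0.7), 2, 1))
  m$b <- list(c(0.1, -0.2), 0.25)
  m$input_norm <- list(min = c(-1, -1), max = c(1, 1))   # identity scaling
  xi <- c(0.5, -0.25)
  h <- tanh(c(0.5 * 0.5 + (-0.3) * (-0.25) + 0.1,
              0.2 * 0.5 + 0.8 * (-0.25) - 0.2))
  expect_equal(predict(m, matrix(xi, 1)),
               sum(h * c(1.5, -0.7)) + 0.25, tolerance = 1e-12)
  # one row inside a big batch gives the same answer
  X <- matrix(runif(2000, -1, 1), ncol = 2)
  X[617, ] <- xi
  expect_equal(predict(m, X)[617], predict(m, matrix(xi, 1)), tolerance = 1e-12)
})

test_that("a zero-weight network outputs its bias everywhere", {
  m <- mlp_fit(matrix(runif(20, -1, 1), 10), runif(10), hidden = 3,
               control = mlp_control(max_epochs = 0), seed = 1)
  m$W <- lapply(m$W, function(w) w * 0)
  m$b <- list(c(0, 0, 0), 0.42)
  m$output_norm <- list(min = -1, max = 1)   # identity on [-1, 1]
  expect_equal(predict(m, matrix(runif(10, -1, 1), 5)), rep(0.42, 5))
})

test_that("the analytic Jacobian matches central finite differences", {
  ls <- c(3, 4, 2, 1)
  wb <- screwscape:::init_weights(ls, 11)
  theta <- screwscape:::pack_weights(wb$W, wb$b)
  X <- matrix(runif(12, -1, 1), 4, 3)
  fw <- screwscape:::forward_norm(wb$W, wb$b, X)
  J <- screwscape:::mlp_jacobian(wb$W, wb$b, fw$A)
  eps <- 1e-6
  for (k in seq(1, length(theta), by = 3)) {
    tp <- theta; tp[k] <- tp[k] + eps
    tm <- theta; tm[k] <- tm[k] - eps
    wp <- screwscape:::unpack_weights(tp, ls)
    wm <- screwscape:::unpack_weights(tm, ls)
    fd <- (screwscape:::forward_norm(wp$W, wp$b, X)$out -
             screwscape:::forward_norm(wm$W, wm$b, X)$out) / (2 * eps)
    expect_equal(J[, k], fd, tolerance = 1e-6)
  }
})

test_that("Levenberg-Marquardt solves a linear least-squares problem exactly", {
  set.seed(8)
  X <- cbind(runif(60, -1, 1), runif(60, -1, 1))
  y <- 2 * X[, 1] - 3 * X[, 2] + 0.5
  fit <- mlp_fit(X, y, hidden = integer(0), algorithm = "lm",
                 control = mlp_control(max_epochs = 30), seed = 1)
  expect_lt(sum((predict(fit, X) - y)^2), 1e-8)
})

test_that("max_epochs = 0 leaves the initial weights untouched", {
  X <- matrix(runif(40, -1, 1), 20)
  y <- runif(20)
  f0 <- mlp_fit(X, y, hidden = 4, control = mlp_control(max_epochs = 0), seed = 3)
  wb <- screwscape:::init_weights(c(2, 4, 1), 3)
  expect_identical(f0$W, wb$W)
  expect_equal(f0$epochs_run, 0)
})

test_that("Levenberg-Marquardt learns the AND gate on most seeds", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0, 0, 0, 1)
  wins <- 0
  for (s in 1:20) {
    fit <- mlp_fit(X, y, hidden = 4, role = "classifier", algorithm = "lm",
                   control = mlp_control(max_epochs = 100), seed = s)
    if (all(predict(fit, X, type = "class") == y)) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("Bayesian regularization fits a noiseless quadratic to R2 > 0.999", {
  set.seed(4)
  x <- matrix(seq(-1, 1, length.out = 50), ncol = 1)
  y <- 2 * x[, 1]^2 - x[, 1] + 0.3
  fit <- mlp_fit(x, y, hidden = c(10, 5), algorithm = "bayes",
                 control = mlp_control(max_epochs = 150), seed = 2)
  xt <- matrix(seq(-0.97, 0.97, length.out = 101), ncol = 1)
  yt <- 2 * xt[, 1]^2 - xt[, 1] + 0.3
  m <- regression_metrics(yt, predict(fit, xt))
  expect_gt(m$r2, 0.999)
})

test_that("Bayesian regularization shrinks weights to nothing on a constant target", {
  set.seed(5)
  x <- matrix(runif(30, -1, 1), ncol = 1)
  fit <- mlp_fit(x, rep(2.5, 30), hidden = 3, algorithm = "bayes",
                 role = "classifier",   # no output scaling: target stays 2.5
                 control = mlp_control(max_epochs = 100), seed = 3)
  w_nonbias <- unlist(fit$W)
  expect_lt(max(abs(w_nonbias)), 1e-2)
  expect_equal(predict(fit, x), rep(2.5, 30), tolerance = 1e-3)
})

test_that("the effective parameter count stays inside (0, P)", {
  set.seed(6)
  x <- matrix(runif(80, -1, 1), ncol = 2)
  y <- x[, 1] * x[, 2] + 0.1 * rnorm(40)
  fit <- mlp_fit(x, y, hidden = 4, algorithm = "bayes",
                 control = mlp_control(max_epochs = 80), seed = 4)
  P <- length(coef(fit))
  expect_gt(fit$gamma, 0)
  expect_lt(fit$gamma, P)
  expect_gt(fit$alpha, 0)
  expect_gt(fit$beta, 0)
})

test_that("validation rows fold into Bayesian-regularization training", {
  set.seed(9)
  x <- matrix(runif(30, -1, 1), ncol = 1); y <- x[, 1]^2
  xv <- matrix(runif(10, -1, 1), ncol = 1); yv <- xv[, 1]^2
  f1 <- mlp_fit(x, y, hidden = 2, algorithm = "bayes",
                validation = list(x = xv, y = yv),
                control = mlp_control(max_epochs = 20), seed = 1)
  f2 <- mlp_fit(rbind(x, xv), c(y, yv), hidden = 2, algorithm = "bayes",
                control = mlp_control(max_epochs = 20), seed = 1)
  expect_identical(coef(f1), coef(f2))
})

test_that("replicate ensembles are reproducible and select the best model", {
  set.seed(10)
  x <- matrix(runif(120, -1, 1), ncol = 2)
  y <- x[, 1]^2 + x[, 2]
  xe <- matrix(runif(40, -1, 1), ncol = 2); ye <- xe[, 1]^2 + xe[, 2]
  ens <- mlp_replicates(x, y, xe, ye, hidden = 3, role = "regressor",
                        n_replicates = 4,
                        control = mlp_control(max_epochs = 30), seed = 21)
  expect_s3_class(ens, "mlp_ensemble")
  expect_length(ens$models, 4)
  expect_equal(ens$best, which.min(ens$scores))
  expect_identical(coef(select_best(ens)), coef(ens$models[[ens$best]]))
  ens2 <- mlp_replicates(x, y, xe, ye, hidden = 3, role = "regressor",
                         n_replicates = 4,
                         control = mlp_control(max_epochs = 30), seed = 21)
  expect_equal(ens$scores, ens2$scores)
  one <- mlp_replicates(x, y, xe, ye, hidden = 3, n_replicates = 1,
                        control = mlp_control(max_epochs = 10), seed = 1)
  expect_identical(coef(select_best(one)), coef(one$models[[1]]))
  rep <- ensemble_report(ens)
  expect_named(rep, c("best", "mean"))
  expect_lte(rep["best"], rep["mean"])
})

test_that("print, summary, residuals and plot methods work", {
  set.seed(11)
  x <- matrix(runif(60, -1, 1), ncol = 2); y <- x[, 1] + x[, 2]
  fit <- mlp_fit(x, y, hidden = 2, control = mlp_control(max_epochs = 20),
                 seed = 1)
  expect_output(print(fit), "Feed-forward surrogate")
  expect_output(print(summary(fit)), "training RMSE")
  expect_equal(residuals(fit), y - fitted(fit))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path); plot(fit); grDevices::dev.off()
  expect_true(file.exists(path))
})
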