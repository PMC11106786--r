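# From-scratch classifiers: L2 logistic regression (gradient correctness,
# limits, recovery, grid search), the feed-forward network, and the
# majority-class baseline.

sim_logistic_data <- function(n, w, b, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * length(w)), n,
                dimnames = list(NULL, paste0("x", seq_along(w))))
    y <- rbinom(n, 1, plogis(X %*% w + b))
    list(X = X, y = y)
  })
}

test_that("analytic gradient matches central finite differences", {
  d <- sim_logistic_data(5, c(0.5, -1, 2), 0.3, seed = 1)
  w <- c(0.2, -0.4, 0.7); b <- 0.1; C <- 2
  g <- logistic_objective(w, b, d$X, d$y, C)$gradient
  eps <- 1e-6
  num <- vapply(seq_len(4), function(i) {
    th_p <- c(w, b); th_m <- c(w, b)
    th_p[i] <- th_p[i] + eps
    th_m[i] <- th_m[i] - eps
    (logistic_objective(th_p[1:3], th_p[4], d$X, d$y, C)$value -
       logistic_objective(th_m[1:3], th_m[4], d$X, d$y, C)$value) / (2 * eps)
  }, 1)
  expect_lt(max(abs(g - num)), 1e-6)
})

test_that("penalty-dominated limit: C -> 0 shrinks weights to zero, prediction to base rate", {
  d <- sim_logistic_data(200, c(1.5, -1), 0, seed = 2)
  m <- fit_logistic(d$X, d$y, C = 1e-8)
  expect_lt(max(abs(m$coefficients)), 1e-4)
  p <- predict(m, d$X)
  expect_lt(max(abs(p - mean(d$y))), 1e-3)
})

test_that("1-D separable data: positive weight, decision threshold near zero", {
  X <- matrix(rep(c(-1, 1), each = 25), ncol = 1,
              dimnames = list(NULL, "x1"))
  y <- rep(c(0, 1), each = 25)
  m <- fit_logistic(X, y, C = 100)
  expect_gt(m$coefficients[["x1"]], 0)
  expect_lt(abs(m$intercept / m$coefficients[["x1"]]), 0.05)
})

test_that("objective decreases monotonically along the Newton path", {
  d <- sim_logistic_data(300, c(1, -2, 0.5), 0.4, seed = 3)
  m <- fit_logistic(d$X, d$y, C = 1)
  expect_true(all(diff(m$objective) <= 1e-10))
  expect_true(m$converged)
})

test_that("planted-weight recovery at n = 5,000 with weak regularization", {
  w_true <- c(1.0, -0.5)
  d <- sim_logistic_data(5000, w_true, 0.25, seed = 4)
  m <- fit_logistic(d$X, d$y, C = 1e6)
  expect_lt(max(abs(unname(m$coefficients) - w_true)), 0.1)
  expect_lt(abs(m$intercept - 0.25), 0.1)
})

test_that("fit agrees with glmnet as an independent reference", {
  skip_if_not_installed("glmnet")
  d <- sim_logistic_data(400, c(0.8, -1.2), -0.3, seed = 5)
  C <- 1
  m <- fit_logistic(d$X, d$y, C = C)
  # glmnet minimizes (1/n) loglik + lambda/2 ||w||^2 -> lambda = 1/(n C)
  g <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = 0,
                      lambda = 1 / (nrow(d$X) * C), standardize = FALSE,
                      thresh = 1e-12)
  expect_lt(max(abs(as.numeric(g$beta) - unname(m$coefficients))), 5e-3)
  expect_lt(abs(as.numeric(g$a0) - m$intercept), 5e-3)
})

test_that("invalid inputs raise errors", {
  X <- matrix(rnorm(10), 5)
  expect_error(fit_logistic(X, c(0, 1, 2, 0, 1)),
               class = "audiodx_label_error")
  X[1] <- NaN
  expect_error(fit_logistic(X, c(0, 1, 0, 1, 0)),
               class = "audiodx_label_error")
  expect_error(fit_logistic(matrix(rnorm(10), 5), c(0, 1, 0, 1, 0), C = -1),
               class = "audiodx_config_error")
})

test_that("grid search: tie goes to the smallest C, AUC table is self-consistent", {
  # perfectly separable: every C reaches AUC 1 -> tie rule returns 0.01
  X <- matrix(c(rnorm(30, -3), rnorm(30, 3)), ncol = 1,
              dimnames = list(NULL, "x1"))
  y <- rep(c(0, 1), each = 30)
  gs <- grid_search_C(X, y, seed = 8)
  expect_equal(gs$best_C, 0.01)
  expect_true(all(gs$results$mean_auc == 1))

  d <- sim_logistic_data(150, c(0.8), 0, seed = 9)
  gs2 <- grid_search_C(d$X, d$y, k = 5, seed = 8)
  expect_true(gs2$best_C %in% gs2$results$C)
  # independent recomputation over the same folds
  folds <- stratified_kfold(d$y, k = 5, seed = 8)
  for (row in seq_len(nrow(gs2$results))) {
    C <- gs2$results$C[row]
    aucs <- vapply(1:5, function(f) {
      m <- fit_logistic(d$X[folds != f, , drop = FALSE], d$y[folds != f],
                        C = C)
      roc_auc(predict(m, d$X[folds == f, , drop = FALSE]), d$y[folds == f])
    }, 1)
    expect_equal(gs2$results$mean_auc[row], mean(aucs))
  }
})

test_that("predictions match manual computation and are monotone in the margin", {
  m <- fit_logistic(matrix(c(-1, 1), ncol = 1,
                           dimnames = list(NULL, "x1")),
                    c(0, 1), C = 1)
  X2 <- matrix(c(0.5, -2), ncol = 1, dimnames = list(NULL, "x1"))
  manual <- plogis(m$coefficients[["x1"]] * X2[, 1] + m$intercept)
  expect_equal(unname(predict(m, X2)), unname(manual))

  zero <- fit_logistic(matrix(0, 4, 1, dimnames = list(NULL, "x1")),
                       c(0, 1, 0, 1), C = 1e-9)
  expect_equal(predict(zero, matrix(0, 1, 1)), 0.5, tolerance = 1e-6)

  xs <- matrix(seq(-3, 3, by = 0.5), ncol = 1,
               dimnames = list(NULL, "x1"))
  expect_true(all(diff(predict(m, xs)) > 0))
})

test_that("feature importance: sorted magnitudes, invariant to column order", {
  d <- sim_logistic_data(500, c(2, -0.5, 1), 0, seed = 10)
  m <- fit_logistic(d$X, d$y, C = 1)
  imp <- feature_importance(m)
  expect_true(all(diff(imp$magnitude) <= 0))
  perm <- d$X[, c(3, 1, 2)]
  m2 <- fit_logistic(perm, d$y, C = 1)
  imp2 <- feature_importance(m2)
  expect_equal(imp$feature, imp2$feature)
  expect_equal(imp$magnitude, imp2$magnitude, tolerance = 1e-8)
})

test_that("MLP: seeded determinism and zero-epoch no-op", {
  d <- sim_logistic_data(60, c(1, -1), 0, seed = 11)
  a <- fit_mlp(d$X, d$y, hidden_sizes = c(8), epochs = 5, seed = 3)
  b <- fit_mlp(d$X, d$y, hidden_sizes = c(8), epochs = 5, seed = 3)
  expect_identical(a$weights, b$weights)
  expect_equal(length(a$loss_trace), 5)

  init <- fit_mlp(d$X, d$y, hidden_sizes = c(8), epochs = 0, seed = 3)
  init2 <- fit_mlp(d$X, d$y, hidden_sizes = c(8), epochs = 0, seed = 3)
  p <- predict(init, d$X)
  expect_identical(p, predict(init2, d$X))
  expect_true(all(p > 0 & p < 1))
})

test_that("MLP learns XOR (nonlinear separability)", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  y <- c(0, 1, 1, 0)
  m <- fit_mlp(X, y, hidden_sizes = c(8), epochs = 3000, batch_size = 4,
               learning_rate = 0.05, seed = 2)
  pred <- predict(m, X, type = "class")
  expect_equal(unname(pred == "tinnitus"), as.logical(y))
  # training loss fell
  expect_lt(m$loss_trace[3000], m$loss_trace[1] / 10)
})

test_that("dummy baseline: majority class, constant score, AUC exactly 0.5", {
  y <- c(rep("normal", 60), rep("tinnitus", 40))
  m <- fit_dummy(y)
  expect_equal(m$majority, "normal")
  expect_equal(m$base_rate, 0.4)
  p <- predict(m, matrix(0, 100, 3))
  expect_true(all(p == 0.4))
  expect_identical(roc_auc(p, y), 0.5)
  expect_true(all(predict(m, matrix(0, 5, 3), type = "class") == "normal"))
})

test_that("model JSON serialization round-trips predictions", {
  d <- sim_logistic_data(50, c(1, -1), 0.2, seed = 12)
  for (m in list(fit_logistic(d$X, d$y),
                 fit_mlp(d$X, d$y, hidden_sizes = c(4), epochs = 3),
                 fit_dummy(d$y))) {
    path <- withr::local_tempfile(fileext = ".json")
    write_model_json(m, path)
    back <- read_model_json(path)
    expect_equal(predict(back, d$X), predict(m, d$X), tolerance = 1e-12)
  }
})
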