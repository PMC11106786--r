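# From-scratch L2-penalized logistic regression. The objective, for labels
# y in {0,1} mapped to s = 2y - 1:
#   J(w, b) = sum_i log(1 + exp(-s_i (w.x_i + b))) + ||w||^2 / (2C)
# with the intercept unpenalized. Fitted by damped Newton iterations with a
# backtracking line search, so the objective decreases monotonically.

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) {
    X <- as.matrix(X[vapply(X, is.numeric, TRUE)])
  }
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

as_binary_labels <- function(y, classes = LABEL_LEVELS) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), classes)
    if (length(bad) > 0) {
      abort(paste("unknown labels:", paste(bad, collapse = ", ")),
            class = "audiodx_label_error")
    }
    return(as.numeric(y == classes[2]))
  }
  if (!all(y %in% c(0, 1))) {
    abort("labels must be binary (0/1 or normal/tinnitus)",
          class = "audiodx_label_error")
  }
  as.numeric(y)
}

#' L2-regularized logistic objective and gradient
#'
#' Exposed for optimizer verification: returns the penalized negative
#' log-likelihood and its exact gradient at `(w, b)`.
#'
#' @param w Weight vector.
#' @param b Intercept.
#' @param X Numeric feature matrix.
#' @param y Binary labels (0/1).
#' @param C Inverse regularization strength (> 0).
#' @return List with `value` and `gradient` (length `ncol(X) + 1`; the last
#'   element is the intercept derivative).
#' @export
logistic_objective <- function(w, b, X, y, C) {
  s <- 2 * y - 1
  z <- s * (as.numeric(X %*% w) + b)
  # numerically stable log(1 + exp(-z))
  loss <- ifelse(z > 0, log1p(exp(-z)), -z + log1p(exp(z)))
  value <- sum(loss) + sum(w^2) / (2 * C)
  sig <- 1 / (1 + exp(z))          # sigmoid(-z)
  gw <- -as.numeric(t(X) %*% (s * sig)) + w / C
  gb <- -sum(s * sig)
  list(value = value, gradient = c(gw, gb))
}

#' Fit L2-regularized logistic regression
#'
#' Deterministic (zero-initialized) damped Newton solver for the penalized
#' logistic objective; the intercept is not penalized. Convergence is
#' declared when the gradient norm falls below `tol`; otherwise the model
#' is returned with `converged = FALSE`.
#'
#' @param X Feature matrix or data frame (numeric columns used).
#' @param y Binary labels: 0/1 or `"normal"`/`"tinnitus"` (tinnitus = 1).
#' @param C Inverse regularization strength (> 0); 1.0 is the value the
#'   default grid search typically settles on.
#' @param tol Gradient-norm convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `aud_logistic` with `coefficients`,
#'   `intercept`, `C`, `iterations`, `converged`, `objective` trace.
#' @export
#' @examples
#' X <- cbind(std = c(1, 2, 8, 9), mean = c(0, 1, 5, 6))
#' fit_logistic(X, c(0, 0, 1, 1), C = 1)
fit_logistic <- function(X, y, C = 1, tol = 1e-8, max_iter = 100) {
  X <- as_feature_matrix(X)
  if (any(!is.finite(X))) {
    abort("features must be finite", class = "audiodx_label_error")
  }
  y <- as_binary_labels(y)
  if (C <= 0) abort_config("C", "must be positive")
  p <- ncol(X)
  w <- rep(0, p); b <- 0
  obj <- logistic_objective(w, b, X, y, C)
  trace <- obj$value
  converged <- FALSE
  iter <- 0
  Xt <- cbind(X, 1)
  for (iter in seq_len(max_iter)) {
    if (sqrt(sum(obj$gradient^2)) <= tol) { converged <- TRUE; break }
    eta <- as.numeric(X %*% w) + b
    mu <- plogis(eta)
    wgt <- pmax(mu * (1 - mu), 1e-10)
    H <- t(Xt * wgt) %*% Xt
    diag(H)[seq_len(p)] <- diag(H)[seq_len(p)] + 1 / C
    step <- tryCatch(solve(H, obj$gradient),
                     error = function(e) obj$gradient / max(diag(H)))
    t_step <- 1
    repeat {
      w_new <- w - t_step * step[seq_len(p)]
      b_new <- b - t_step * step[p + 1]
      obj_new <- logistic_objective(w_new, b_new, X, y, C)
      if (obj_new$value <= obj$value - 1e-12 * t_step ||
          t_step < 1e-10) break
      t_step <- t_step / 2
    }
    if (obj_new$value >= obj$value) { converged <- TRUE; break }
    w <- w_new; b <- b_new; obj <- obj_new
    trace <- c(trace, obj$value)
  }
  if (!converged && sqrt(sum(obj$gradient^2)) <= tol) converged <- TRUE
  structure(list(coefficients = setNames(w, colnames(X)), intercept = b,
                 C = C, iterations = iter, converged = converged,
                 objective = trace, feature_names = colnames(X),
                 classes = LABEL_LEVELS),
            class = "aud_logistic")
}

#' Predicted probabilities or labels from a fitted classifier
#'
#' `predict_proba()` returns the probability of the positive (tinnitus)
#' class; `predict()` with `type = "class"` applies `threshold`.
#'
#' @param object A fitted `aud_logistic`, `aud_mlp` or `aud_dummy` model.
#' @param newdata Feature matrix or data frame.
#' @param type `"prob"` or `"class"`.
#' @param threshold Classification threshold on the positive-class
#'   probability.
#' @param ... Unused.
#' @return Numeric probabilities or a character label vector.
#' @export
predict.aud_logistic <- function(object, newdata, type = c("prob", "class"),
                                 threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  if (ncol(X) != length(object$coefficients)) {
    abort("newdata has the wrong number of feature columns",
          class = "audiodx_shape_error")
  }
  X <- X[, object$feature_names, drop = FALSE]
  p <- plogis(as.numeric(X %*% object$coefficients) + object$intercept)
  if (type == "prob") p else
    ifelse(p >= threshold, object$classes[2], object$classes[1])
}

#' @rdname predict.aud_logistic
#' @param model A fitted model.
#' @param X Feature matrix or data frame.
#' @export
predict_proba <- function(model, X) predict(model, X, type = "prob")

#' Stratified cross-validated grid search for the regularization strength C
#'
#' Evaluates each candidate C by mean validation ROC-AUC over stratified
#' k-fold splits of the training data and returns the maximizer; exact AUC
#' ties go to the smaller C (the simpler model).
#'
#' @param X Feature matrix or data frame.
#' @param y Binary labels.
#' @param grid Candidate C values.
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @return List with `best_C` and `results` (tibble `C`, `mean_auc`).
#' @export
grid_search_C <- function(X, y, grid = c(0.01, 0.1, 1, 10, 100), k = 5,
                          seed = 1L) {
  X <- as_feature_matrix(X)
  y <- as_binary_labels(y)
  folds <- stratified_kfold(y, k = k, seed = seed)
  grid <- sort(grid)
  aucs <- vapply(grid, function(C) {
    fold_auc <- vapply(seq_len(k), function(f) {
      tr <- folds != f; te <- folds == f
      if (length(unique(y[te])) < 2) {
        abort("degenerate fold: one class absent",
              class = "audiodx_cv_error")
      }
      m <- fit_logistic(X[tr, , drop = FALSE], y[tr], C = C)
      roc_auc(predict(m, X[te, , drop = FALSE]), y[te])
    }, 1)
    mean(fold_auc)
  }, 1)
  best <- grid[which(aucs >= max(aucs) - 1e-12)[1]]
  list(best_C = best, results = tibble(C = grid, mean_auc = aucs))
}

#' Coefficient-magnitude feature importance of a logistic model
#'
#' On standardized features the absolute coefficient is a direct importance
#' measure; pairs are returned in descending magnitude.
#'
#' @param model A fitted `aud_logistic`.
#' @return Tibble `feature`, `coefficient`, `magnitude`, sorted descending.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "aud_logistic"))
  tibble(feature = names(model$coefficients),
         coefficient = unname(model$coefficients),
         magnitude = abs(unname(model$coefficients))) |>
    arrange(desc(.data$magnitude), .data$feature)
}

#' @export
tidy.aud_logistic <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$coefficients)),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' @export
glance.aud_logistic <- function(x, ...) {
  tibble(C = x$C, iterations = x$iterations, converged = x$converged,
         objective = x$objective[length(x$objective)])
}

#' @export
print.aud_logistic <- function(x, ...) {
  cat(sprintf("L2 logistic regression (C = %g, %s in %d iterations)\n",
              x$C, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(c(`(Intercept)` = x$intercept, x$coefficients))
  invisible(x)
}

#' Serialize a fitted classifier to JSON and back
#'
#' @param model A fitted `aud_logistic`, `aud_mlp` or `aud_dummy`.
#' @param path File path.
#' @return `read_model_json()` returns the model; `write_model_json()` the
#'   path, invisibly.
#' @export
write_model_json <- function(model, path) {
  kind <- class(model)[1]
  ser <- switch(kind,
    aud_logistic = list(kind = kind,
                        coefficients = as.list(model$coefficients),
                        intercept = model$intercept, C = model$C,
                        iterations = model$iterations,
                        converged = model$converged),
    aud_mlp = list(kind = kind, layer_sizes = model$layer_sizes,
                   weights = lapply(model$weights, unclass),
                   biases = model$biases, config = model$config),
    aud_dummy = list(kind = kind, majority = model$majority,
                     base_rate = model$base_rate),
    abort("unknown model class"))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(j$kind,
    aud_logistic = structure(
      list(coefficients = unlist(j$coefficients), intercept = j$intercept,
           C = j$C, iterations = j$iterations, converged = j$converged,
           feature_names = names(j$coefficients), classes = LABEL_LEVELS),
      class = "aud_logistic"),
    aud_mlp = structure(
      list(layer_sizes = j$layer_sizes,
           weights = lapply(j$weights, as.matrix),
           biases = lapply(j$biases, as.numeric), config = as.list(j$config),
           classes = LABEL_LEVELS),
      class = "aud_mlp"),
    aud_dummy = structure(
      list(majority = j$majority, base_rate = j$base_rate,
           classes = LABEL_LEVELS),
      class = "aud_dummy"),
    abort("unknown serialized model kind"))
}
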