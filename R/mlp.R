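# Small from-scratch feed-forward network for binary classification:
# ReLU hidden layers, a sigmoid output unit, binary cross-entropy loss,
# mini-batch Adam with seeded shuffling.

#' Fit a small feed-forward neural network
#'
#' Architecture: `length(hidden_sizes)` ReLU hidden layers followed by a
#' single sigmoid output unit, trained with binary cross-entropy and the
#' Adam optimizer on shuffled mini-batches. Fully deterministic given
#' `seed` (Glorot-uniform initialization and per-epoch shuffles both come
#' from the seeded stream). Features should be standardized first.
#'
#' @param X Feature matrix or data frame.
#' @param y Binary labels (0/1 or normal/tinnitus).
#' @param hidden_sizes Hidden-layer widths.
#' @param epochs Training epochs (0 returns the initialized network).
#' @param batch_size Mini-batch size.
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param seed Integer seed.
#' @return An `aud_mlp` object with `weights`, `biases`, `layer_sizes`,
#'   `config` and the per-epoch `loss_trace`.
#' @export
fit_mlp <- function(X, y, hidden_sizes = c(32, 16), epochs = 100,
                    batch_size = 32, learning_rate = 1e-3, beta1 = 0.9,
                    beta2 = 0.999, epsilon = 1e-8, seed = 1L) {
  X <- as_feature_matrix(X)
  y <- as_binary_labels(y)
  n <- nrow(X)
  sizes <- c(ncol(X), hidden_sizes, 1)
  L <- length(sizes) - 1

  with_seed(derive_seed(seed, "mlp"), {
    W <- lapply(seq_len(L), function(l) {
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      matrix(runif(sizes[l] * sizes[l + 1], -lim, lim),
             nrow = sizes[l], ncol = sizes[l + 1])
    })
    B <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mB <- lapply(B, function(b) b * 0); vB <- mB
    step <- 0
    loss_trace <- numeric(0)

    if (epochs > 0) {
      for (ep in seq_len(epochs)) {
        idx <- sample.int(n)
        batches <- split(idx, ceiling(seq_along(idx) / batch_size))
        ep_loss <- 0
        for (bt in batches) {
          xb <- X[bt, , drop = FALSE]
          yb <- y[bt]
          m <- length(bt)
          # forward
          acts <- vector("list", L + 1)
          acts[[1]] <- xb
          for (l in seq_len(L)) {
            z <- sweep(acts[[l]] %*% W[[l]], 2, B[[l]], "+")
            acts[[l + 1]] <- if (l < L) pmax(z, 0) else plogis(z)
          }
          p <- pmin(pmax(as.numeric(acts[[L + 1]]), 1e-12), 1 - 1e-12)
          loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
          if (!is.finite(loss)) {
            abort(sprintf("training diverged (NaN loss) at epoch %d", ep),
                  class = "audiodx_divergence_error", epoch = ep)
          }
          ep_loss <- ep_loss + loss * m / n
          # backward: delta at output for sigmoid + BCE is (p - y)/m
          delta <- matrix((p - yb) / m, ncol = 1)
          step <- step + 1
          for (l in rev(seq_len(L))) {
            gW <- t(acts[[l]]) %*% delta
            gB <- colSums(delta)
            if (l > 1) {
              delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
            }
            mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
            vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
            mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB
            vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB^2
            mhW <- mW[[l]] / (1 - beta1^step)
            vhW <- vW[[l]] / (1 - beta2^step)
            mhB <- mB[[l]] / (1 - beta1^step)
            vhB <- vB[[l]] / (1 - beta2^step)
            W[[l]] <- W[[l]] - learning_rate * mhW / (sqrt(vhW) + epsilon)
            B[[l]] <- B[[l]] - learning_rate * mhB / (sqrt(vhB) + epsilon)
          }
        }
        loss_trace[ep] <- ep_loss
      }
    }
    structure(list(weights = W, biases = B, layer_sizes = sizes,
                   loss_trace = loss_trace,
                   config = list(hidden_sizes = hidden_sizes,
                                 epochs = epochs, batch_size = batch_size,
                                 learning_rate = learning_rate,
                                 beta1 = beta1, beta2 = beta2,
                                 epsilon = epsilon, seed = seed),
                   feature_names = colnames(X), classes = LABEL_LEVELS),
              class = "aud_mlp")
  })
}

mlp_forward <- function(model, X) {
  a <- X
  L <- length(model$weights)
  for (l in seq_len(L)) {
    z <- sweep(a %*% model$weights[[l]], 2, model$biases[[l]], "+")
    a <- if (l < L) pmax(z, 0) else plogis(z)
  }
  as.numeric(a)
}

#' @rdname predict.aud_logistic
#' @export
predict.aud_mlp <- function(object, newdata, type = c("prob", "class"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  if (ncol(X) != model_input_dim(object)) {
    abort("newdata has the wrong number of feature columns",
          class = "audiodx_shape_error")
  }
  p <- mlp_forward(object, X)
  if (type == "prob") p else
    ifelse(p >= threshold, object$classes[2], object$classes[1])
}

model_input_dim <- function(model) nrow(model$weights[[1]])

#' @export
glance.aud_mlp <- function(x, ...) {
  tibble(layers = paste(x$layer_sizes, collapse = "-"),
         epochs = x$config$epochs,
         final_loss = if (length(x$loss_trace)) x$loss_trace[length(x$loss_trace)] else NA_real_)
}

#' @export
print.aud_mlp <- function(x, ...) {
  cat(sprintf("feed-forward network %s (ReLU hidden, sigmoid output), %d epochs\n",
              paste(x$layer_sizes, collapse = "-"), x$config$epochs))
  invisible(x)
}

#' Majority-class baseline classifier
#'
#' Predicts the training majority class for every input and a constant
#' positive-class probability equal to the training base rate; its tie-aware
#' ROC-AUC is exactly 0.5 by construction.
#'
#' @param y Binary labels.
#' @return An `aud_dummy` object.
#' @export
fit_dummy <- function(y) {
  yb <- as_binary_labels(y)
  base_rate <- mean(yb)
  majority <- if (mean(yb) > 0.5) LABEL_LEVELS[2] else LABEL_LEVELS[1]
  structure(list(majority = majority, base_rate = base_rate,
                 classes = LABEL_LEVELS),
            class = "aud_dummy")
}

#' @rdname predict.aud_logistic
#' @export
predict.aud_dummy <- function(object, newdata, type = c("prob", "class"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  n <- if (is.null(dim(newdata))) length(newdata) else nrow(newdata)
  if (type == "prob") rep(object$base_rate, n) else rep(object$majority, n)
}
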