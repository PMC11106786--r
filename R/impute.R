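#' Configuration for chained-equations imputation
#'
#' @param n_iterations Chained-equation sweeps per imputation chain.
#' @param n_imputations Independent chains; results are pooled per cell
#'   (mean for continuous, majority for binary).
#' @param pmm_donor_count Number of nearest donors predictive mean matching
#'   draws from.
#' @param seed Integer seed.
#' @return An `imputation_config` list.
#' @export
imputation_config <- function(n_iterations = 10, n_imputations = 5,
                              pmm_donor_count = 5, seed = 1L) {
  for (f in c("n_iterations", "n_imputations", "pmm_donor_count")) {
    assert_scalar_num(get(f), f, min = 1)
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 n_imputations = as.integer(n_imputations),
                 pmm_donor_count = as.integer(pmm_donor_count),
                 seed = as.integer(seed)),
            class = "imputation_config")
}

is_binary_col <- function(x) {
  u <- unique(x[!is.na(x)])
  is.logical(x) || (is.numeric(x) && length(u) <= 2 && all(u %in% c(0, 1)))
}

# Least-squares fit tolerant of collinear predictors: rank-deficient
# coefficients are zeroed rather than propagated as NA.
safe_lm_predict <- function(X_obs, y_obs, X_all) {
  fit <- lm.fit(cbind(1, X_obs), y_obs)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  as.numeric(cbind(1, X_all) %*% beta)
}

# One PMM draw per missing cell: rank observed donors by distance between
# predicted means, draw uniformly among the k nearest. Consumes exactly one
# sample.int() call per missing cell, in ascending row order.
pmm_column <- function(y, X, miss, k) {
  obs <- which(!miss)
  pred <- safe_lm_predict(X[obs, , drop = FALSE], y[obs], X)
  out <- y
  for (i in which(miss)) {
    d <- abs(pred[obs] - pred[i])
    donors <- obs[order(d, obs)][seq_len(min(k, length(obs)))]
    out[i] <- y[donors[sample.int(length(donors), 1)]]
  }
  out
}

# Logistic imputation for a binary column: one runif() per missing cell.
logistic_column <- function(y, X, miss) {
  obs <- which(!miss)
  fit <- suppressWarnings(
    glm.fit(cbind(1, X[obs, , drop = FALSE]), y[obs], family = binomial()))
  beta <- fit$coefficients
  beta[!is.finite(beta)] <- 0
  p <- plogis(as.numeric(cbind(1, X) %*% beta))
  p[!is.finite(p)] <- mean(y[obs])
  out <- y
  for (i in which(miss)) out[i] <- as.numeric(runif(1) < p[i])
  out
}

#' Impute missing cells by chained equations (MICE)
#'
#' Iterative per-column conditional imputation: continuous columns by
#' predictive mean matching (an imputed value is always one of the column's
#' observed values), binary columns by logistic-regression draws. Several
#' independent chains are run and pooled into a single completed table
#' (per-cell mean for continuous, per-cell majority for binary).
#'
#' Column visit order is left to right; the initial fill is the observed
#' column mean (continuous) or majority value (binary). Non-numeric columns
#' must be complete and are passed through untouched.
#'
#' @param table A data frame/tibble whose numeric columns may contain `NA`.
#' @param config An [imputation_config()].
#' @return The completed tibble, with an `"imputation_log"` attribute
#'   recording per-cell provenance (row, column, per-chain values, pooled
#'   value).
#' @export
#' @examples
#' df <- tibble::tibble(x = 1:10, y = c(2.1, NA, 3.9, 6.2, NA, 5, 4, 3, 2, 1))
#' mice_impute(df, imputation_config(n_iterations = 2, n_imputations = 2))
mice_impute <- function(table, config = imputation_config()) {
  stopifnot(is.data.frame(table))
  tbl <- as_tibble(table)
  num_cols <- names(tbl)[vapply(tbl, is.numeric, TRUE) |
                           vapply(tbl, is.logical, TRUE)]
  other <- setdiff(names(tbl), num_cols)
  if (any(vapply(tbl[other], anyNA, TRUE))) {
    abort("non-numeric columns must be complete",
          class = "audiodx_impute_error")
  }
  for (cn in num_cols) {
    n_obs <- sum(!is.na(tbl[[cn]]))
    if (n_obs == 0) {
      abort(sprintf("column `%s` is entirely missing", cn),
            class = "audiodx_impute_error", column = cn)
    }
    if (n_obs < 2) {
      abort(sprintf("column `%s` has fewer than 2 observed values", cn),
            class = "audiodx_impute_error", column = cn)
    }
  }
  M <- as.matrix(tbl[num_cols])
  storage.mode(M) <- "double"
  miss <- is.na(M)
  if (!any(miss)) {
    attr(tbl, "imputation_log") <- tibble(row = integer(), column = character())
    return(tbl)
  }
  binary <- vapply(num_cols, function(cn) is_binary_col(tbl[[cn]]), TRUE)

  chains <- lapply(seq_len(config$n_imputations), function(m) {
    with_seed(derive_seed(config$seed, paste0("mice", m)), {
      cur <- M
      for (j in seq_along(num_cols)) {           # initial fill
        mj <- miss[, j]
        if (!any(mj)) next
        obs <- cur[!mj, j]
        cur[mj, j] <- if (binary[j]) as.numeric(mean(obs) >= 0.5) else mean(obs)
      }
      for (it in seq_len(config$n_iterations)) {
        for (j in seq_along(num_cols)) {
          mj <- miss[, j]
          if (!any(mj)) next
          X <- cur[, -j, drop = FALSE]
          cur[, j] <- if (binary[j]) {
            logistic_column(ifelse(mj, NA, M[, j]), X, mj)
          } else {
            pmm_column(ifelse(mj, NA, M[, j]), X, mj,
                       config$pmm_donor_count)
          }
        }
      }
      cur
    })
  })

  pooled <- M
  log_rows <- list()
  for (j in seq_along(num_cols)) {
    mj <- which(miss[, j])
    if (length(mj) == 0) next
    vals <- vapply(chains, function(ch) ch[mj, j], numeric(length(mj)))
    vals <- matrix(vals, nrow = length(mj))
    pooled[mj, j] <- if (binary[j]) {
      as.numeric(rowMeans(vals) >= 0.5)
    } else {
      rowMeans(vals)
    }
    log_rows[[j]] <- tibble(row = mj, column = num_cols[j],
                            chain_values = lapply(seq_along(mj),
                                                  function(i) vals[i, ]),
                            pooled = pooled[mj, j])
  }
  for (j in seq_along(num_cols)) tbl[[num_cols[j]]] <- pooled[, j]
  attr(tbl, "imputation_log") <- bind_rows(log_rows)
  tbl
}

#' Z-score standardization with reusable training statistics
#'
#' Standardizes numeric columns to mean 0, sd 1 using statistics computed on
#' the data itself (training mode) or previously stored statistics (applied
#' to test data). Constant columns are passed through unchanged and flagged.
#'
#' @param features Data frame of features.
#' @param stats Optional statistics tibble from a previous call (training
#'   stats applied to new data).
#' @param columns Columns to scale; default all numeric ones.
#' @return List with `data` (scaled tibble) and `stats` (tibble `column`,
#'   `mean`, `sd`, `constant`).
#' @export
standardize <- function(features, stats = NULL, columns = NULL) {
  tbl <- as_tibble(features)
  if (is.null(columns)) {
    columns <- names(tbl)[vapply(tbl, is.numeric, TRUE)]
  }
  if (is.null(stats)) {
    stats <- tibble(
      column = columns,
      mean = vapply(columns, function(cn) mean(tbl[[cn]]), 1),
      sd = vapply(columns, function(cn) sd(tbl[[cn]]), 1))
    stats$constant <- !is.finite(stats$sd) | stats$sd == 0
    if (any(stats$constant)) {
      warn(paste("constant columns passed through unscaled:",
                 paste(stats$column[stats$constant], collapse = ", ")))
    }
  }
  for (i in seq_len(nrow(stats))) {
    cn <- stats$column[i]
    if (!cn %in% names(tbl) || stats$constant[i]) next
    tbl[[cn]] <- (tbl[[cn]] - stats$mean[i]) / stats$sd[i]
  }
  list(data = tbl, stats = stats)
}

#' Invert a standardization
#'
#' @param scaled Tibble produced by [standardize()].
#' @param stats The `stats` tibble from the same call.
#' @return Tibble on the original scale.
#' @export
unstandardize <- function(scaled, stats) {
  tbl <- as_tibble(scaled)
  for (i in seq_len(nrow(stats))) {
    cn <- stats$column[i]
    if (!cn %in% names(tbl) || stats$constant[i]) next
    tbl[[cn]] <- tbl[[cn]] * stats$sd[i] + stats$mean[i]
  }
  tbl
}
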