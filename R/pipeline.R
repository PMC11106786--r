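# End-to-end orchestration. Two entry points mirror the study design:
# run_tabular() goes cohort -> missingness -> MICE -> features -> models ->
# test metrics; run_imaging() inserts the chart renderer, per-ear symbol
# detectors and calibration between the cohort and the feature stage. A
# single run seed is expanded into independent per-stage streams.

profiles_to_wide <- function(profiles) {
  profiles |>
    filter(.data$conduction == "air") |>
    select("subject_id", "ear", "label", "frequency_hz", "threshold_db") |>
    tidyr::pivot_wider(names_from = "frequency_hz",
                       values_from = "threshold_db",
                       names_prefix = "f") |>
    arrange(.data$subject_id, .data$ear)
}

wide_to_profiles <- function(wide) {
  wide |>
    tidyr::pivot_longer(cols = dplyr::starts_with("f"),
                        names_to = "frequency_hz",
                        values_to = "threshold_db") |>
    mutate(frequency_hz = as.numeric(sub("^f", "", .data$frequency_hz)),
           conduction = "air") |>
    select("subject_id", "ear", "conduction", "frequency_hz",
           "threshold_db", "label")
}

evaluate_model <- function(model, X_test, y_test) {
  scores <- predict(model, X_test, type = "prob")
  preds <- predict(model, X_test, type = "class", threshold = 0.5)
  metrics_report(y_test, preds, scores)
}

feature_columns <- c("std", "mean", "has_above_30")

#' Run the tabular diagnosis pipeline end to end
#'
#' Simulates a labeled cohort, blanks entries at the configured missing
#' rate, completes the table by chained-equations imputation, extracts the
#' per-ear high-frequency features, splits 70/30 stratified, standardizes
#' on training statistics, tunes the logistic regression's C by stratified
#' k-fold AUC, fits the requested models and evaluates them on the held-out
#' test ears. Fully deterministic given `seed`.
#'
#' @param cohort A [cohort_config()].
#' @param imputation An [imputation_config()].
#' @param band_low_hz,band_high_hz Feature band (Hz).
#' @param test_fraction Held-out fraction.
#' @param k Cross-validation folds for the C grid search.
#' @param C_grid Candidate inverse regularization strengths.
#' @param models Subset of `c("lr", "mlp", "dummy")`.
#' @param mlp_hidden,mlp_epochs,mlp_batch_size Network architecture and
#'   training length.
#' @param seed Master run seed.
#' @param out_dir Optional directory for artifacts (feature table, models,
#'   metrics, manifest, run log).
#' @return An `aud_run` list: `features`, `split`, `models`, `grid`,
#'   `reports`, `importance`, `manifest`.
#' @export
run_tabular <- function(cohort = cohort_config(),
                        imputation = imputation_config(),
                        band_low_hz = 8000, band_high_hz = 16000,
                        test_fraction = 0.30, k = 5,
                        C_grid = c(0.01, 0.1, 1, 10, 100),
                        models = c("lr", "mlp", "dummy"),
                        mlp_hidden = c(32, 16), mlp_epochs = 100,
                        mlp_batch_size = 32, seed = 1L, out_dir = NULL) {
  if (!inherits(cohort, "cohort_config")) {
    abort_config("cohort", "must be created by cohort_config()")
  }
  log_lines <- character()
  log_step <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  log_step("simulate: %d tinnitus + %d control subjects",
           cohort$n_tinnitus, cohort$n_control)
  profiles <- sample_cohort(cohort, seed = derive_seed(seed, "cohort"))
  profiles <- inject_missingness(profiles, cohort$missing_rate,
                                 seed = derive_seed(seed, "missing"))

  wide <- profiles_to_wide(profiles)
  wide$label_bin <- as.numeric(wide$label == "tinnitus")
  imp <- imputation
  imp$seed <- derive_seed(seed, "impute")
  completed <- mice_impute(wide, imp)
  n_imputed <- nrow(attr(completed, "imputation_log") %||% tibble())
  log_step("impute: %d cells completed", n_imputed)
  completed$label_bin <- NULL
  profiles_full <- wide_to_profiles(completed)

  features <- build_design_matrix(profiles_full, band_low_hz, band_high_hz)
  log_step("features: %d ear rows", nrow(features))

  split <- split_train_test(features$label, test_fraction,
                            seed = derive_seed(seed, "split"))
  train <- features[split$train, ]
  test <- features[split$test, ]
  std <- standardize(train, columns = c("std", "mean"))
  X_train <- std$data[feature_columns]
  X_test <- standardize(test, stats = std$stats)$data[feature_columns]

  out_models <- list(); reports <- list(); grid <- NULL; importance <- NULL
  if ("lr" %in% models) {
    grid <- grid_search_C(X_train, train$label, grid = C_grid, k = k,
                          seed = derive_seed(seed, "grid"))
    log_step("grid search: best C = %g", grid$best_C)
    lr <- fit_logistic(X_train, train$label, C = grid$best_C)
    out_models$lr <- lr
    reports$lr <- evaluate_model(lr, X_test, test$label)
    importance <- feature_importance(lr)
  }
  if ("mlp" %in% models) {
    mlp <- fit_mlp(X_train, train$label, hidden_sizes = mlp_hidden,
                   epochs = mlp_epochs, batch_size = mlp_batch_size,
                   seed = derive_seed(seed, "mlp"))
    out_models$mlp <- mlp
    reports$mlp <- evaluate_model(mlp, X_test, test$label)
  }
  if ("dummy" %in% models) {
    dummy <- fit_dummy(train$label)
    out_models$dummy <- dummy
    reports$dummy <- evaluate_model(dummy, X_test, test$label)
  }
  for (nm in names(reports)) {
    log_step("evaluate %s: accuracy %.4f%s", nm, reports[[nm]]$report$accuracy,
             if (!is.null(reports[[nm]]$auc))
               sprintf(", AUC %.4f", reports[[nm]]$auc) else "")
  }

  config <- list(cohort = unclass(cohort), imputation = unclass(imputation),
                 band = c(band_low_hz, band_high_hz),
                 test_fraction = test_fraction, k = k, C_grid = C_grid,
                 models = models, mlp_hidden = mlp_hidden,
                 mlp_epochs = mlp_epochs, mlp_batch_size = mlp_batch_size,
                 seed = seed)
  manifest <- list(pipeline = "tabular", seed = seed,
                   config_hash = rlang::hash(config),
                   package_version = as.character(utils::packageVersion("audiodx")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   n_ears = nrow(features), test_size = length(split$test))

  run <- structure(list(profiles = profiles_full, features = features,
                        split = split, scaler = std$stats,
                        models = out_models, grid = grid, reports = reports,
                        importance = importance, manifest = manifest,
                        log = log_lines),
                   class = "aud_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(run$features, file.path(out_dir, "features.csv"))
  for (nm in names(run$models)) {
    if (inherits(run$models[[nm]], c("aud_logistic", "aud_mlp", "aud_dummy"))) {
      write_model_json(run$models[[nm]],
                       file.path(out_dir, paste0("model_", nm, ".json")))
    }
  }
  for (nm in names(run$reports)) {
    write_metrics_json(run$reports[[nm]],
                       file.path(out_dir, paste0("metrics_", nm, ".json")))
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.aud_run <- function(x, ...) {
  cat(sprintf("audiodx %s run: %d ear rows, test size %d\n",
              x$manifest$pipeline, x$manifest$n_ears, x$manifest$test_size))
  for (nm in names(x$reports)) {
    g <- glance(x$reports[[nm]])
    cat(sprintf("  %-6s accuracy %.3f%s\n", nm, g$accuracy,
                if (!is.na(g$auc)) sprintf("  AUC %.3f", g$auc) else ""))
  }
  invisible(x)
}

#' Run the imaging (chart digitization) pipeline end to end
#'
#' Simulates a small cohort, renders one chart per subject (both ears),
#' harvests positive/negative patch sets, trains per-ear air-conduction
#' symbol detectors, digitizes every chart back into threshold profiles via
#' the stored calibration, and finally runs the tabular feature/model/
#' evaluation stages on the digitized thresholds. The returned object also
#' carries a digitization-accuracy report and, for reference, the same
#' logistic model fitted on the ground-truth features.
#'
#' @param cohort A [cohort_config()] (keep it modest: one chart per
#'   subject is rendered and scanned).
#' @param style A [chart_style()]; the default widens the dB axis to
#'   -10 dB so every generatable threshold is renderable.
#' @param detector A [detector_params()].
#' @param patch_size Detector window size in pixels.
#' @param band_low_hz,band_high_hz,test_fraction,seed,out_dir As in
#'   [run_tabular()].
#' @param score_threshold Detection score threshold.
#' @return An `aud_imaging_run` list: `packages` count, `detectors`,
#'   `digitized`, `digitization` accuracy tibble, `reports` (lr on
#'   digitized and on truth features), `manifest`.
#' @export
run_imaging <- function(cohort = cohort_config(n_tinnitus = 30,
                                               n_control = 30,
                                               missing_rate = 0),
                        style = chart_style(db_axis_top = -10),
                        detector = detector_params(),
                        patch_size = 16, band_low_hz = 8000,
                        band_high_hz = 16000, test_fraction = 0.30,
                        score_threshold = 0.5, seed = 1L, out_dir = NULL) {
  profiles <- sample_cohort(cohort, seed = derive_seed(seed, "cohort"))
  subjects <- unique(profiles$subject_id)

  packages <- purrr::map(seq_along(subjects), function(i) {
    sub <- profiles[profiles$subject_id == subjects[i], ]
    render_chart(left_profile = sub[sub$ear == "left", ],
                 right_profile = sub[sub$ear == "right", ],
                 style = style, seed = derive_seed(seed, paste0("chart", i)))
  })

  patches <- export_patch_sets(packages, patch_size = patch_size,
                               classes = c("left_air", "right_air"),
                               seed = derive_seed(seed, "patches"))
  det_par <- detector
  det_par$seed <- derive_seed(seed, "detector")
  mine_idx <- seq_len(min(6, length(packages)))
  detectors <- purrr::imap(patches, function(p, cls) {
    train_detector(p$positives, p$negatives, det_par, class_label = cls,
                   mining_images = purrr::map(packages[mine_idx], "image"),
                   mining_exclude = purrr::map(packages[mine_idx], function(pk) {
                     pk$truth[pk$truth$class == cls, c("x", "y")]
                   }),
                   template_positives = p$centered)
  })

  digitized <- purrr::map(seq_along(packages), function(i) {
    d <- digitize_chart(packages[[i]], detectors,
                        score_threshold = score_threshold)
    if (nrow(d) > 0) d$subject_id <- subjects[i]
    d
  })

  # digitization accuracy vs the truth sidecars
  acc <- purrr::map(seq_along(packages), function(i) {
    truth <- packages[[i]]$truth |>
      filter(.data$class %in% names(detectors))
    dig <- digitized[[i]]
    hit <- purrr::map_lgl(seq_len(nrow(truth)), function(j) {
      any(dig$class == truth$class[j] &
            dig$frequency_hz == truth$frequency_hz[j] &
            abs(dig$threshold_db - truth$level_db[j]) <= 2.5)
    })
    err <- purrr::map_dbl(seq_len(nrow(dig)), function(j) {
      tr <- truth[truth$class == dig$class[j] &
                    truth$frequency_hz == dig$frequency_hz[j], ]
      if (nrow(tr) == 0) NA_real_ else min(abs(tr$level_db - dig$threshold_db[j]))
    })
    tibble(chart = i, n_truth = nrow(truth), n_detected = nrow(dig),
           n_recovered = sum(hit),
           level_mae = mean(err, na.rm = TRUE))
  })
  acc <- bind_rows(acc)

  labels <- profiles |> distinct(.data$subject_id, .data$ear, .data$label)
  dig_long <- bind_rows(digitized) |>
    left_join(labels, by = c("subject_id", "ear")) |>
    select("subject_id", "ear", "conduction", "frequency_hz",
           "threshold_db", "label")

  feats_dig <- build_design_matrix(dig_long, band_low_hz, band_high_hz)
  feats_truth <- build_design_matrix(profiles, band_low_hz, band_high_hz)

  fit_eval <- function(features) {
    split <- split_train_test(features$label, test_fraction,
                              seed = derive_seed(seed, "split"))
    train <- features[split$train, ]; test <- features[split$test, ]
    std <- standardize(train, columns = c("std", "mean"))
    Xtr <- std$data[feature_columns]
    Xte <- standardize(test, stats = std$stats)$data[feature_columns]
    lr <- fit_logistic(Xtr, train$label, C = 1)
    evaluate_model(lr, Xte, test$label)
  }
  reports <- list(lr_digitized = fit_eval(feats_dig),
                  lr_truth = fit_eval(feats_truth))

  manifest <- list(pipeline = "imaging", seed = seed,
                   config_hash = rlang::hash(list(unclass(cohort),
                                                  unclass(style),
                                                  detector, patch_size)),
                   package_version = as.character(utils::packageVersion("audiodx")),
                   n_charts = length(packages),
                   recovery_rate = sum(acc$n_recovered) / sum(acc$n_truth),
                   level_mae = mean(acc$level_mae, na.rm = TRUE))

  run <- structure(list(n_charts = length(packages), detectors = detectors,
                        digitized = dig_long, digitization = acc,
                        features_digitized = feats_dig,
                        features_truth = feats_truth,
                        reports = reports, manifest = manifest),
                   class = "aud_imaging_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_threshold_table(dig_long, file.path(out_dir, "digitized.csv"))
    for (nm in names(detectors)) {
      write_detector_json(detectors[[nm]],
                          file.path(out_dir, paste0("detector_", nm, ".json")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.aud_imaging_run <- function(x, ...) {
  cat(sprintf("audiodx imaging run: %d charts, symbol recovery %.1f%%, level MAE %.2f dB\n",
              x$n_charts, 100 * x$manifest$recovery_rate,
              x$manifest$level_mae))
  for (nm in names(x$reports)) {
    g <- glance(x$reports[[nm]])
    cat(sprintf("  %-13s accuracy %.3f  AUC %.3f\n", nm, g$accuracy, g$auc))
  }
  invisible(x)
}
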