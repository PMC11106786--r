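#' Extract the three high-frequency features for one ear
#'
#' From the air-conduction thresholds in the high-frequency band (default
#' 8-16 kHz, endpoints inclusive) computes the per-ear feature vector used
#' for classification: the band mean, the sample (n-1 denominator) standard
#' deviation, and a strict indicator that any band threshold exceeds 30 dB
#' HL.
#'
#' @param profile Long threshold tibble for a single (subject, ear); only
#'   air-conduction rows are used.
#' @param band_low_hz,band_high_hz Feature band limits in Hz (inclusive).
#' @return One-row tibble: `subject_id`, `ear`, `std`, `mean`,
#'   `has_above_30`, `label`.
#' @export
#' @examples
#' p <- tibble::tibble(subject_id = "S1", ear = "left", conduction = "air",
#'                     frequency_hz = c(8000, 10000, 12500, 16000),
#'                     threshold_db = c(20, 25, 45, 50), label = "tinnitus")
#' extract_features(p)
extract_features <- function(profile, band_low_hz = 8000,
                             band_high_hz = 16000) {
  rows <- filter(profile, .data$conduction == "air",
                 .data$frequency_hz >= band_low_hz,
                 .data$frequency_hz <= band_high_hz,
                 !is.na(.data$threshold_db))
  if (nrow(rows) < 2) {
    abort(sprintf(
      "fewer than 2 usable air-conduction thresholds in [%g, %g] Hz",
      band_low_hz, band_high_hz),
      class = "audiodx_feature_error")
  }
  t_db <- rows$threshold_db
  tibble(subject_id = rows$subject_id[1] %||% NA_character_,
         ear = rows$ear[1],
         std = sd(t_db),
         mean = mean(t_db),
         has_above_30 = as.numeric(any(t_db > 30)),
         label = if ("label" %in% names(rows)) rows$label[1] else NA_character_)
}

#' Build the per-ear design matrix
#'
#' One feature row per (subject, ear) in canonical order (subject id, then
#' ear), so the output is invariant to the input row order. Ears with fewer
#' than two usable band thresholds are skipped and recorded in the
#' `"skipped"` attribute.
#'
#' @param profiles Long threshold tibble covering many ears.
#' @param band_low_hz,band_high_hz Feature band limits in Hz.
#' @return Tibble `subject_id`, `ear`, `std`, `mean`, `has_above_30`,
#'   `label`.
#' @export
build_design_matrix <- function(profiles, band_low_hz = 8000,
                                band_high_hz = 16000) {
  if (nrow(profiles) == 0) {
    return(tibble(subject_id = character(), ear = character(),
                  std = numeric(), mean = numeric(),
                  has_above_30 = numeric(), label = character()))
  }
  groups <- profiles |>
    distinct(.data$subject_id, .data$ear) |>
    arrange(.data$subject_id, .data$ear)
  skipped <- list()
  rows <- purrr::pmap(groups, function(subject_id, ear) {
    sub <- profiles[profiles$subject_id == subject_id &
                      profiles$ear == ear, ]
    tryCatch(extract_features(sub, band_low_hz, band_high_hz),
             audiodx_feature_error = function(e) {
               skipped[[length(skipped) + 1]] <<-
                 tibble(subject_id = subject_id, ear = ear,
                        reason = conditionMessage(e))
               NULL
             })
  })
  out <- bind_rows(rows)
  attr(out, "skipped") <- bind_rows(skipped)
  out
}

#' Write or read a feature table as delimited text
#'
#' Columns: `subject_id`, `ear`, `std`, `mean`, `has_above_30`, `label`.
#'
#' @param features Feature tibble from [build_design_matrix()].
#' @param path File path (CSV).
#' @return `read_feature_table()` returns the tibble;
#'   `write_feature_table()` the path, invisibly.
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
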