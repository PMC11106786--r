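#' Configure a synthetic extended high-frequency audiometry cohort
#'
#' Describes the simulated clinical population the rest of the pipeline is
#' exercised on: a control group whose thresholds sit in the normal range and
#' a tinnitus group with elevated, more dispersed thresholds at and above
#' 8 kHz, often with a single deeper "notch" point. Defaults mirror the
#' cohort composition the analysis assumes (242 tinnitus + 267 control
#' audiograms, two ears each) and a conventional extended high-frequency test
#' grid up to 16 kHz.
#'
#' The tinnitus contrast is parameterized by an effect size
#' `tinnitus_hf_shift_db`: the expected elevation of the per-ear mean
#' threshold over the high-frequency band relative to controls. Internally
#' the elevation applied to individual points is reduced by the expected
#' notch contribution so that the realized group effect equals
#' `tinnitus_hf_shift_db` exactly, which makes the generator's own effect
#' size recoverable from simulated data.
#'
#' @param n_tinnitus,n_control Number of audiograms (subjects) per group.
#' @param frequency_grid Ordered test frequencies in Hz.
#' @param control_mean_db,control_sd_db Location and scale (dB HL) of control
#'   thresholds around the age-like baseline.
#' @param tinnitus_hf_shift_db Mean elevation (dB) of tinnitus ears at
#'   frequencies >= `hf_cutoff_hz`.
#' @param tinnitus_extra_sd_db Additional per-frequency dispersion (dB) for
#'   tinnitus ears in the high-frequency band.
#' @param tinnitus_severity_sd_db Between-ear spread (dB) of the tinnitus
#'   elevation (a per-ear random severity intercept).
#' @param notch_probability Chance a tinnitus ear carries one extra-elevated
#'   notch point in the band.
#' @param notch_depth_db Extra elevation (dB) of the notch point.
#' @param hf_cutoff_hz Lowest frequency of the high-frequency band.
#' @param age_tilt_db Gentle baseline rise from `hf_cutoff_hz` to the top of
#'   the grid shared by both groups (age-like sloping).
#' @param missing_rate Fraction of threshold entries blanked downstream by
#'   [inject_missingness()].
#' @param bilateral_tinnitus If `TRUE` (default) both ears of a tinnitus
#'   subject are tinnitus-labeled; if `FALSE` one random ear per subject.
#' @param include_bone Also generate bone-conduction thresholds (used for
#'   symbol-overlap rendering, never for features).
#' @param bone_max_hz Highest frequency with a bone-conduction measurement.
#' @param round_db_step Clinical step size thresholds are rounded to
#'   (0 disables rounding).
#' @param seed Integer seed; [sample_cohort()] is deterministic given it.
#'
#' @return A `cohort_config` list.
#' @export
#' @examples
#' cfg <- cohort_config(n_tinnitus = 5, n_control = 5)
#' sample_cohort(cfg)
cohort_config <- function(n_tinnitus = 242,
                          n_control = 267,
                          frequency_grid = c(250, 500, 1000, 2000, 4000,
                                             8000, 10000, 12500, 14000, 16000),
                          control_mean_db = 10,
                          control_sd_db = 5,
                          tinnitus_hf_shift_db = 20,
                          tinnitus_extra_sd_db = 5,
                          tinnitus_severity_sd_db = 8,
                          notch_probability = 0.3,
                          notch_depth_db = 20,
                          hf_cutoff_hz = 8000,
                          age_tilt_db = 5,
                          missing_rate = 0.05,
                          bilateral_tinnitus = TRUE,
                          include_bone = FALSE,
                          bone_max_hz = 4000,
                          round_db_step = 5,
                          seed = 1L) {
  assert_scalar_num(n_tinnitus, "n_tinnitus", min = 0)
  assert_scalar_num(n_control, "n_control", min = 0)
  if (!is.numeric(frequency_grid) || length(frequency_grid) < 2 ||
      any(diff(frequency_grid) <= 0) || any(frequency_grid <= 0)) {
    abort_config("frequency_grid", "must be strictly increasing positive frequencies")
  }
  assert_scalar_num(control_mean_db, "control_mean_db")
  assert_scalar_num(control_sd_db, "control_sd_db", min = 0)
  assert_scalar_num(tinnitus_hf_shift_db, "tinnitus_hf_shift_db", min = 0)
  assert_scalar_num(tinnitus_extra_sd_db, "tinnitus_extra_sd_db", min = 0)
  assert_scalar_num(tinnitus_severity_sd_db, "tinnitus_severity_sd_db", min = 0)
  assert_scalar_num(notch_probability, "notch_probability", min = 0, max = 1)
  assert_scalar_num(notch_depth_db, "notch_depth_db", min = 0)
  assert_scalar_num(missing_rate, "missing_rate", min = 0, max = 1)
  assert_scalar_num(seed, "seed")
  if (!hf_cutoff_hz %in% frequency_grid) {
    abort_config("hf_cutoff_hz", "must be a member of frequency_grid")
  }
  structure(
    list(n_tinnitus = as.integer(n_tinnitus), n_control = as.integer(n_control),
         frequency_grid = frequency_grid,
         control_mean_db = control_mean_db, control_sd_db = control_sd_db,
         tinnitus_hf_shift_db = tinnitus_hf_shift_db,
         tinnitus_extra_sd_db = tinnitus_extra_sd_db,
         tinnitus_severity_sd_db = tinnitus_severity_sd_db,
         notch_probability = notch_probability, notch_depth_db = notch_depth_db,
         hf_cutoff_hz = hf_cutoff_hz, age_tilt_db = age_tilt_db,
         missing_rate = missing_rate, bilateral_tinnitus = bilateral_tinnitus,
         include_bone = include_bone, bone_max_hz = bone_max_hz,
         round_db_step = round_db_step, seed = as.integer(seed)),
    class = "cohort_config")
}

# Shared age-like baseline: flat at control_mean_db, rising linearly in
# log-frequency from the HF cutoff to age_tilt_db at the top of the grid.
cohort_baseline <- function(config) {
  f <- config$frequency_grid
  hf <- f >= config$hf_cutoff_hz
  tilt <- rep(0, length(f))
  span <- log10(max(f)) - log10(config$hf_cutoff_hz)
  if (span > 0) {
    tilt[hf] <- config$age_tilt_db *
      (log10(f[hf]) - log10(config$hf_cutoff_hz)) / span
  }
  config$control_mean_db + tilt
}

clip_levels <- function(x, step) {
  if (step > 0) x <- round(x / step) * step
  pmin(pmax(x, -10), 120)
}

#' Simulate a labeled cohort of per-ear threshold profiles
#'
#' Draws air-conduction (and optionally bone-conduction) thresholds for every
#' ear of every subject. Control ears follow the shared baseline with
#' Gaussian noise; tinnitus-labeled ears additionally receive, at frequencies
#' in the high-frequency band, a per-ear severity intercept, extra
#' per-frequency dispersion, and possibly one notch point. Levels are rounded
#' to the clinical step and clipped to [-10, 120] dB HL.
#'
#' @param config A [cohort_config()].
#' @param seed Optional override of `config$seed`.
#' @return A tibble with one row per (subject, ear, conduction, frequency):
#'   columns `subject_id`, `ear`, `conduction`, `frequency_hz`,
#'   `threshold_db`, `label`.
#' @export
sample_cohort <- function(config, seed = config$seed) {
  if (!inherits(config, "cohort_config")) {
    abort_config("config", "must be created by cohort_config()")
  }
  grid <- config$frequency_grid
  hf <- grid >= config$hf_cutoff_hz
  n_hf <- sum(hf)
  baseline <- cohort_baseline(config)
  # point elevation chosen so the expected HF-band mean elevation equals
  # tinnitus_hf_shift_db after accounting for the notch contribution
  point_shift <- config$tinnitus_hf_shift_db -
    config$notch_probability * config$notch_depth_db / n_hf

  n_total <- config$n_tinnitus + config$n_control
  subjects <- tibble(
    subject_id = sprintf("S%04d", seq_len(n_total)),
    group = rep(c("tinnitus", "control"),
                c(config$n_tinnitus, config$n_control)))

  with_seed(derive_seed(seed, "cohort"), {
    ears <- tidyr::expand_grid(subjects, ear = EAR_LEVELS)
    ears$label <- ifelse(ears$group == "tinnitus", "tinnitus", "normal")
    if (!config$bilateral_tinnitus) {
      # one random tinnitus ear per affected subject, the other normal
      tin <- ears$group == "tinnitus"
      pick_left <- runif(nrow(subjects)) < 0.5
      pick <- rep(pick_left, each = 2)[tin]
      is_left <- ears$ear[tin] == "left"
      ears$label[tin] <- ifelse(is_left == pick, "tinnitus", "normal")
    }

    rows <- purrr::pmap(ears, function(subject_id, group, ear, label) {
      mu <- baseline
      sdv <- rep(config$control_sd_db, length(grid))
      if (label == "tinnitus") {
        severity <- rnorm(1, 0, config$tinnitus_severity_sd_db)
        mu[hf] <- mu[hf] + point_shift + severity
        sdv[hf] <- sdv[hf] + config$tinnitus_extra_sd_db
        if (runif(1) < config$notch_probability) {
          notch_at <- which(hf)[sample.int(n_hf, 1)]
          mu[notch_at] <- mu[notch_at] + config$notch_depth_db
        }
      }
      air <- clip_levels(rnorm(length(grid), mu, sdv), config$round_db_step)
      out <- tibble(subject_id = subject_id, ear = ear, conduction = "air",
                    frequency_hz = grid, threshold_db = air, label = label)
      if (config$include_bone) {
        bone_idx <- grid <= config$bone_max_hz
        gap <- abs(rnorm(sum(bone_idx), 0, 5))
        bone <- clip_levels(air[bone_idx] - gap, config$round_db_step)
        out <- bind_rows(out, tibble(
          subject_id = subject_id, ear = ear, conduction = "bone",
          frequency_hz = grid[bone_idx], threshold_db = bone, label = label))
      }
      out
    })
    bind_rows(rows)
  })
}

#' Blank a fraction of threshold entries completely at random
#'
#' Emulates missing entries in digitized clinical tables (missing completely
#' at random). Only `threshold_db` is ever blanked; labels and identifiers
#' are untouched.
#'
#' @param profiles Long threshold tibble from [sample_cohort()].
#' @param missing_rate Fraction of entries to blank, in \[0, 1).
#' @param seed Integer seed.
#' @return `profiles` with some `threshold_db` set to `NA`.
#' @export
inject_missingness <- function(profiles, missing_rate, seed = 1L) {
  if (!is.numeric(missing_rate) || length(missing_rate) != 1 ||
      missing_rate < 0 || missing_rate >= 1) {
    abort_config("missing_rate", "must lie in [0, 1)")
  }
  if (missing_rate == 0) return(profiles)
  with_seed(derive_seed(seed, "missing"), {
    blank <- runif(nrow(profiles)) < missing_rate
    profiles$threshold_db[blank] <- NA_real_
  })
  profiles
}

#' Read or write a threshold table as delimited text
#'
#' One row per (subject, ear, conduction, frequency) with columns
#' `subject_id`, `ear`, `conduction`, `frequency_hz`, `threshold_db`,
#' `label`.
#'
#' @param profiles Threshold tibble.
#' @param path File path (CSV).
#' @return `read_threshold_table()` returns the tibble;
#'   `write_threshold_table()` returns `path` invisibly.
#' @export
write_threshold_table <- function(profiles, path) {
  readr::write_csv(profiles, path)
  invisible(path)
}

#' @rdname write_threshold_table
#' @export
read_threshold_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject_id = readr::col_character(),
                    ear = readr::col_character(),
                    conduction = readr::col_character(),
                    frequency_hz = readr::col_double(),
                    threshold_db = readr::col_double(),
                    label = readr::col_character()))
}
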