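# Shared fixtures, built once per test run and cached. The imaging fixture
# is the expensive one (50 rendered charts + two trained detectors); all
# chart-level tests and the round-trip acceptance check reuse it.

fixture_env <- new.env(parent = emptyenv())

imaging_style <- function() chart_style(db_axis_top = -10)

imaging_fixture <- function() {
  if (!is.null(fixture_env$imaging)) return(fixture_env$imaging)
  cohort <- cohort_config(n_tinnitus = 25, n_control = 25, missing_rate = 0,
                          seed = 42)
  profiles <- sample_cohort(cohort)
  style <- imaging_style()
  subjects <- unique(profiles$subject_id)
  packages <- lapply(seq_along(subjects), function(i) {
    s <- profiles[profiles$subject_id == subjects[i], ]
    render_chart(s[s$ear == "left", ], s[s$ear == "right", ], style,
                 seed = 1000 + i)
  })
  # patches from the first 20 charts keep training affordable; detection is
  # evaluated on all 50
  patches <- export_patch_sets(packages[1:20], patch_size = 16, seed = 7)
  detectors <- lapply(names(patches), function(cls) {
    train_detector(
      patches[[cls]]$positives, patches[[cls]]$negatives,
      detector_params(seed = 7), class_label = cls,
      mining_images = lapply(packages[1:6], function(p) p$image),
      mining_exclude = lapply(packages[1:6], function(p) {
        p$truth[p$truth$class == cls, c("x", "y")]
      }),
      template_positives = patches[[cls]]$centered)
  })
  names(detectors) <- names(patches)
  fixture_env$imaging <- list(cohort = cohort, profiles = profiles,
                              style = style, packages = packages,
                              patches = patches, detectors = detectors)
  fixture_env$imaging
}

# one ear profile tibble for quick feature tests
ear_profile <- function(freqs, levels, ear = "left", label = "tinnitus",
                        conduction = "air", subject = "S1") {
  tibble::tibble(subject_id = subject, ear = ear, conduction = conduction,
                 frequency_hz = freqs, threshold_db = levels, label = label)
}

random_confusion <- function() {
  confusion_from_counts(sample.int(200, 1), sample.int(50, 1) - 1,
                        sample.int(50, 1) - 1, sample.int(200, 1))
}
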