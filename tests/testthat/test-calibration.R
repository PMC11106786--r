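# Pixel-to-audiometric calibration, grid snapping, and chart digitization.

demo_cal <- function() {
  chart_calibration(list(c(300, 1000), c(400, 2000)),
                    list(c(100, 0), c(500, 100)))
}

default_grid <- c(250, 500, 1000, 2000, 4000, 8000, 10000, 12500, 14000, 16000)

test_that("anchor identities and linear level interpolation", {
  cal <- demo_cal()
  at_anchor <- pixel_to_audiometric(cal, 300, 100)
  expect_equal(at_anchor$frequency_hz, 1000)
  expect_equal(at_anchor$level_db, 0)
  expect_false(at_anchor$extrapolated)

  mid <- pixel_to_audiometric(cal, 300, 260)
  expect_equal(mid$level_db, 40)
})

test_that("frequency interpolation is log-linear: pixel midpoint is the log midpoint", {
  cal <- demo_cal()
  got <- pixel_to_audiometric(cal, 350, 100)
  expect_equal(got$frequency_hz, 10^((log10(1000) + log10(2000)) / 2),
               tolerance = 1e-12)
  expect_equal(round(got$frequency_hz, 2), 1414.21)
})

test_that("extrapolation beyond the anchor span is flagged", {
  cal <- demo_cal()
  out <- pixel_to_audiometric(cal, c(250, 350), c(100, 600))
  expect_true(all(out$extrapolated))
})

test_that("pixel_to_audiometric is strictly monotone in each coordinate", {
  cal <- demo_cal()
  xs <- seq(250, 450, by = 10)
  fs <- pixel_to_audiometric(cal, xs, 100)$frequency_hz
  expect_true(all(diff(fs) > 0))
  ys <- seq(50, 550, by = 10)
  dbs <- pixel_to_audiometric(cal, 300, ys)$level_db
  expect_true(all(diff(dbs) > 0))
})

test_that("degenerate anchors raise calibration errors", {
  expect_error(chart_calibration(list(c(300, 1000), c(300, 2000)),
                                 list(c(100, 0), c(500, 100))),
               class = "audiodx_calibration_error")
  expect_error(chart_calibration(list(c(300, 1000), c(400, 1000)),
                                 list(c(100, 0), c(500, 100))),
               class = "audiodx_calibration_error")
  expect_error(chart_calibration(list(c(300, -5), c(400, 2000)),
                                 list(c(100, 0), c(500, 100))),
               class = "audiodx_calibration_error")
})

test_that("snap_to_grid: nearest in log distance, ties to the lower frequency", {
  expect_equal(snap_to_grid(1010, default_grid), 1000)
  # exact log midpoint of 1000/2000 snaps down by the tie rule
  expect_equal(snap_to_grid(sqrt(1000 * 2000), default_grid), 1000)
  # grid members snap to themselves
  expect_equal(snap_to_grid(default_grid, default_grid), default_grid)
  expect_error(snap_to_grid(1000, numeric(0)),
               class = "audiodx_calibration_error")
})

test_that("digitizing an empty chart returns zero rows", {
  fx <- imaging_fixture()
  blank <- matrix(1, nrow(fx$packages[[1]]$image),
                  ncol(fx$packages[[1]]$image))
  out <- digitize_chart(blank, fx$detectors,
                        calibration = fx$packages[[1]]$calibration,
                        grid = default_grid)
  expect_equal(nrow(out), 0)
  expect_named(out, c("ear", "conduction", "frequency_hz", "threshold_db",
                      "score", "class"))
})

test_that("digitized thresholds match ground truth within 2.5 dB", {
  fx <- imaging_fixture()
  errs <- numeric(0)
  for (pkg in fx$packages[1:5]) {
    dg <- digitize_chart(pkg, fx$detectors)
    # no duplicate (class, frequency) rows survive deduplication
    expect_equal(anyDuplicated(dg[c("class", "frequency_hz")]), 0)
    for (j in seq_len(nrow(pkg$truth))) {
      tr <- pkg$truth[j, ]
      hit <- dg[dg$class == tr$class & dg$frequency_hz == tr$frequency_hz, ]
      errs <- c(errs, if (nrow(hit) == 1)
        abs(hit$threshold_db - tr$level_db) else Inf)
    }
  }
  # at least 95% of points recovered at the exact grid frequency within
  # 2.5 dB, and the typical level error is well below the 5 dB step
  expect_gte(mean(errs <= 2.5), 0.95)
  expect_lt(median(errs), 1.5)
})

test_that("jitter-free rendering digitizes exactly after 5 dB quantization", {
  p_left <- ear_profile(default_grid,
                        c(10, 15, 10, 20, 25, 30, 35, 40, 45, 50))
  p_right <- ear_profile(default_grid,
                         c(5, 10, 15, 10, 20, 25, 30, 35, 40, 45),
                         ear = "right")
  style <- chart_style(db_axis_top = -10, jitter_px = 0)
  pkg <- render_chart(p_left, p_right, style, seed = 1)
  fx <- imaging_fixture()
  dg <- digitize_chart(pkg, fx$detectors, quantize_db_step = 5)
  for (j in seq_len(nrow(pkg$truth))) {
    tr <- pkg$truth[j, ]
    hit <- dg[dg$class == tr$class & dg$frequency_hz == tr$frequency_hz, ]
    expect_equal(hit$threshold_db, tr$level_db)
  }
})

test_that("calibration JSON round-trips", {
  cal <- demo_cal()
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(cal, path)
  back <- read_calibration_json(path)
  expect_equal(back$freq_anchors, cal$freq_anchors, ignore_attr = TRUE)
  expect_equal(back$level_anchors, cal$level_anchors, ignore_attr = TRUE)
})
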