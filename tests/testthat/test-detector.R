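# Symbol detection: cascade training contract, sliding-window detection,
# and non-maximum suppression (with a brute-force oracle).

make_noise_patches <- function(n, size = 16, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) matrix(runif(size * size), size, size))
  })
}

glyph_patch <- function(shape = "x", size = 16) {
  img <- matrix(1, size, size)
  audiodx:::stamp_glyph(img, size / 2, size / 2,
                        audiodx:::glyph_mask(shape, 9), 0)
}

test_that("separable case: identical positives vs noise trains to perfection", {
  pos <- replicate(40, glyph_patch("x"), simplify = FALSE)
  neg <- make_noise_patches(80)
  m <- train_detector(pos, neg, detector_params(seed = 1),
                      class_label = "left_air")
  expect_s3_class(m, "haar_detector")
  expect_equal(unname(m$holdout["hit_rate"]), 1)
  expect_equal(unname(m$holdout["false_accept"]), 0)
  expect_gte(length(m$stages), 1)
})

test_that("training is deterministic and enforces minimum patch counts", {
  pos <- replicate(40, glyph_patch("circle"), simplify = FALSE)
  neg <- make_noise_patches(80)
  a <- train_detector(pos, neg, detector_params(seed = 3))
  b <- train_detector(pos, neg, detector_params(seed = 3))
  expect_identical(a$stages, b$stages)
  expect_error(train_detector(pos[1:5], neg, detector_params()),
               class = "audiodx_training_error")
})

test_that("a left-ear detector scores left-ear patches above right-ear patches", {
  fx <- imaging_fixture()
  model <- fx$detectors$left_air
  left <- fx$patches$left_air$positives[1:40]
  right <- fx$patches$right_air$positives[1:40]
  s_left <- vapply(left, function(p) audiodx:::patch_score(model, p), 1)
  s_right <- vapply(right, function(p) audiodx:::patch_score(model, p), 1)
  expect_gt(mean(s_left), mean(s_right))
})

test_that("blank image yields no detections; boxes stay in bounds", {
  fx <- imaging_fixture()
  blank <- matrix(1, 120, 150)
  d <- detect(blank, fx$detectors$left_air)
  expect_equal(nrow(d), 0)

  img <- fx$packages[[1]]$image
  d2 <- detect(img, fx$detectors$left_air, score_threshold = 0.5)
  expect_true(all(d2$x >= 1 & d2$y >= 1))
  expect_true(all(d2$x + d2$w - 1 <= ncol(img)))
  expect_true(all(d2$y + d2$h - 1 <= nrow(img)))
  expect_true(all(d2$score >= 0.5))
})

test_that("detection sets are nested in the score threshold", {
  fx <- imaging_fixture()
  img <- fx$packages[[2]]$image
  hi <- detect(img, fx$detectors$right_air, score_threshold = 0.8)
  lo <- detect(img, fx$detectors$right_air, score_threshold = 0.4)
  key <- function(d) paste(d$x, d$y, d$w, d$h)
  expect_true(all(key(hi) %in% key(lo)))
  expect_gte(nrow(lo), nrow(hi))
})

# independent greedy-by-score suppression oracle
nms_oracle <- function(d, thr) {
  d <- d[order(-d$score, d$x, d$y), ]
  kept <- d[0, ]
  for (i in seq_len(nrow(d))) {
    cand <- d[i, ]
    same <- kept[kept$class == cand$class, ]
    ok <- TRUE
    for (j in seq_len(nrow(same))) {
      ix <- max(0, min(same$x[j] + same$w[j], cand$x + cand$w) -
                  max(same$x[j], cand$x))
      iy <- max(0, min(same$y[j] + same$h[j], cand$y + cand$h) -
                  max(same$y[j], cand$y))
      iou <- (ix * iy) /
        (same$w[j] * same$h[j] + cand$w * cand$h - ix * iy)
      if (iou >= thr) ok <- FALSE
    }
    if (ok) kept <- rbind(kept, cand)
  }
  kept[order(kept$x, kept$y), ]
}

test_that("overlap resolution follows the greedy NMS definition", {
  two <- tibble::tibble(x = c(10, 12), y = c(10, 10), w = 16, h = 16,
                        class = "left_air", score = c(0.9, 0.7))
  out <- resolve_overlaps(two, 0.3)
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 0.9)

  # different classes survive heavy overlap (air + bone on one point)
  mixed <- tibble::tibble(x = c(10, 11), y = c(10, 10), w = 16, h = 16,
                          class = c("left_air", "left_bone"),
                          score = c(0.9, 0.8))
  expect_equal(nrow(resolve_overlaps(mixed, 0.3)), 2)

  expect_error(resolve_overlaps(two, 0), class = "audiodx_nms_error")
  expect_error(resolve_overlaps(two, 1.2), class = "audiodx_nms_error")
})

test_that("NMS matches the brute-force oracle and is idempotent", {
  for (case_seed in 1:5) {
    d <- withr::with_seed(case_seed, tibble::tibble(
      x = sample.int(60, 20, replace = TRUE),
      y = sample.int(60, 20, replace = TRUE),
      w = 16L, h = 16L,
      class = sample(c("left_air", "right_air"), 20, replace = TRUE),
      score = round(runif(20), 3)))
    got <- resolve_overlaps(d, 0.3)
    want <- nms_oracle(as.data.frame(d), 0.3)
    key <- function(z) sort(paste(z$x, z$y, z$class, z$score))
    expect_equal(key(got), key(want))
    again <- resolve_overlaps(got, 0.3)
    expect_equal(key(again), key(got))
  }
})

test_that("detector JSON serialization round-trips and detects identically", {
  fx <- imaging_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_detector_json(fx$detectors$left_air, path)
  back <- read_detector_json(path)
  img <- fx$packages[[3]]$image
  a <- detect(img, fx$detectors$left_air)
  b <- detect(img, back)
  expect_equal(a, b)
})

test_that("clean single-ear chart: >= 9 of 10 symbols found, at most 1 spurious box", {
  fx <- imaging_fixture()
  p <- ear_profile(c(250, 500, 1000, 2000, 4000, 8000, 10000, 12500,
                     14000, 16000),
                   c(10, 15, 10, 20, 15, 25, 30, 35, 40, 45))
  pkg <- render_chart(left_profile = p, style = fx$style, seed = 77)
  det <- resolve_overlaps(detect(pkg$image, fx$detectors$left_air,
                                 score_threshold = 0.8), 0.3)
  cx <- det$x + (det$w - 1) / 2
  cy <- det$y + (det$h - 1) / 2
  truth <- pkg$truth
  matched <- vapply(seq_len(nrow(truth)), function(j) {
    any(sqrt((cx - truth$x[j])^2 + (cy - truth$y[j])^2) <= 5)
  }, TRUE)
  expect_gte(sum(matched), 9)
  spurious <- vapply(seq_along(cx), function(i) {
    !any(sqrt((cx[i] - truth$x)^2 + (cy[i] - truth$y)^2) <= 8)
  }, TRUE)
  expect_lte(sum(spurious), 1)
})
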