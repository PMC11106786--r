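#' Chart calibration: the audiogram's internal scale
#'
#' Two anchor points per axis define the mapping between pixel coordinates
#' and audiometric coordinates: frequency is log-linear in the horizontal
#' pixel (standard audiogram layout), hearing level is linear in the
#' vertical pixel and increases downward.
#'
#' @param freq_anchors List of two `c(pixel_x, frequency_hz)` pairs.
#' @param level_anchors List of two `c(pixel_y, level_db)` pairs.
#' @return A `chart_calibration` object.
#' @export
#' @examples
#' cal <- chart_calibration(list(c(300, 1000), c(400, 2000)),
#'                          list(c(100, 0), c(500, 100)))
#' pixel_to_audiometric(cal, 350, 260)
chart_calibration <- function(freq_anchors, level_anchors) {
  fa <- do.call(rbind, freq_anchors)
  la <- do.call(rbind, level_anchors)
  if (nrow(fa) != 2 || nrow(la) != 2) {
    abort("exactly two anchors per axis are required",
          class = "audiodx_calibration_error")
  }
  if (fa[1, 1] == fa[2, 1] || la[1, 1] == la[2, 1]) {
    abort("anchor pixels must be distinct per axis",
          class = "audiodx_calibration_error")
  }
  if (any(fa[, 2] <= 0) || fa[1, 2] == fa[2, 2] || la[1, 2] == la[2, 2]) {
    abort("anchor frequencies must be positive and distinct; anchor levels distinct",
          class = "audiodx_calibration_error")
  }
  structure(list(freq_anchors = fa, level_anchors = la),
            class = "chart_calibration")
}

#' Translate pixel coordinates to (frequency, level)
#'
#' Frequency is recovered as `10^` of the linear interpolation of `log10(f)`
#' over the two x anchors; level by linear interpolation over the two y
#' anchors. Points outside the anchor span are extrapolated and flagged.
#'
#' @param cal A [chart_calibration()].
#' @param x,y Pixel coordinates (vectorized).
#' @return Tibble with `frequency_hz`, `level_db`, `extrapolated`.
#' @export
pixel_to_audiometric <- function(cal, x, y) {
  fa <- cal$freq_anchors; la <- cal$level_anchors
  tf <- (x - fa[1, 1]) / (fa[2, 1] - fa[1, 1])
  logf <- log10(fa[1, 2]) + tf * (log10(fa[2, 2]) - log10(fa[1, 2]))
  tl <- (y - la[1, 1]) / (la[2, 1] - la[1, 1])
  db <- la[1, 2] + tl * (la[2, 2] - la[1, 2])
  tibble(frequency_hz = 10^logf, level_db = db,
         extrapolated = tf < 0 | tf > 1 | tl < 0 | tl > 1)
}

#' Inverse mapping: audiometric coordinates to pixel coordinates
#'
#' @param cal A [chart_calibration()].
#' @param frequency_hz,level_db Audiometric coordinates (vectorized).
#' @return Tibble with `x`, `y` (fractional pixels).
#' @export
audiometric_to_pixel <- function(cal, frequency_hz, level_db) {
  fa <- cal$freq_anchors; la <- cal$level_anchors
  tf <- (log10(frequency_hz) - log10(fa[1, 2])) /
    (log10(fa[2, 2]) - log10(fa[1, 2]))
  tl <- (level_db - la[1, 2]) / (la[2, 2] - la[1, 2])
  tibble(x = fa[1, 1] + tf * (fa[2, 1] - fa[1, 1]),
         y = la[1, 1] + tl * (la[2, 1] - la[1, 1]))
}

#' Snap a recovered frequency to the nearest test-grid frequency
#'
#' Nearest in log10 distance; an exact tie goes to the lower frequency.
#'
#' @param frequency Frequencies in Hz (vectorized).
#' @param grid Increasing vector of test frequencies.
#' @return Grid frequencies.
#' @export
snap_to_grid <- function(frequency, grid) {
  if (length(grid) == 0) abort("empty frequency grid",
                               class = "audiodx_calibration_error")
  stopifnot(all(diff(grid) > 0) || length(grid) == 1)
  lg <- log10(grid)
  vapply(frequency, function(f) {
    d <- abs(log10(f) - lg)
    grid[which(d <= min(d) + 1e-9)[1]]
  }, numeric(1))
}

#' Digitize a chart image into per-ear threshold profiles
#'
#' Runs each supplied detector over the image, resolves overlapping
#' detections per class, translates surviving box centers through the
#' calibration, snaps frequencies to the test grid, and keeps the
#' higher-scoring detection when several land on one (grid frequency,
#' class).
#'
#' @param x A `chart_package` (image + calibration + grid) or a plain image
#'   matrix (then `calibration` and `grid` are required).
#' @param detectors Named list of detector models; names are symbol classes
#'   like `"left_air"`.
#' @param calibration,grid Required when `x` is a bare image.
#' @param score_threshold,stride,iou_threshold Detection controls, see
#'   [detect()] and [resolve_overlaps()].
#' @param quantize_db_step If positive, round recovered levels to this step
#'   (e.g. 5 dB); default 0 leaves them continuous.
#' @return Tibble with `ear`, `conduction`, `frequency_hz`, `threshold_db`,
#'   `score`, `class`; empty (zero rows) when nothing is detected.
#' @export
digitize_chart <- function(x, detectors, calibration = NULL, grid = NULL,
                           score_threshold = 0.5, stride = 1L,
                           iou_threshold = 0.3, quantize_db_step = 0) {
  if (inherits(x, "chart_package")) {
    img <- x$image
    calibration <- calibration %||% x$calibration
    grid <- grid %||% x$frequency_grid
  } else {
    img <- x
    if (is.null(calibration) || is.null(grid)) {
      abort("calibration and grid are required for a bare image",
            class = "audiodx_calibration_error")
    }
  }
  rows <- purrr::imap(detectors, function(model, cls) {
    raw <- detect(img, model, score_threshold = score_threshold,
                  stride = stride)
    det <- resolve_overlaps(raw, iou_threshold = iou_threshold)
    if (nrow(det) == 0) return(NULL)
    cx <- det$x + (det$w - 1) / 2
    cy <- det$y + (det$h - 1) / 2
    # two-step localization: average the centers of the raw detection
    # cluster, then snap to the centroid of glyph-ink pixels nearby
    # (glyph ink is far darker than grid lines, so a 0.5 darkness cut
    # isolates the symbol)
    rx <- raw$x + (raw$w - 1) / 2
    ry <- raw$y + (raw$h - 1) / 2
    for (i in seq_along(cx)) {
      near <- abs(rx - cx[i]) <= det$w[i] / 3 & abs(ry - cy[i]) <= det$h[i] / 3
      if (any(near)) {
        cx[i] <- mean(rx[near])
        cy[i] <- mean(ry[near])
      }
      ref <- ink_centroid(img, cx[i], cy[i], radius = det$w[i] / 2 - 1)
      if (!is.null(ref)) {
        cx[i] <- ref[1]
        cy[i] <- ref[2]
      }
    }
    am <- pixel_to_audiometric(calibration, cx, cy)
    lvl <- am$level_db
    if (quantize_db_step > 0) lvl <- round(lvl / quantize_db_step) * quantize_db_step
    # arbitration margin: how much better the local glyph ink matches this
    # detector's template than any other supplied detector's template.
    # Cascade scores saturate on clean charts, so this margin is what ranks
    # competing detections (above all the opposite ear's glyph) during
    # deduplication. Overlapping symbols score near zero margin for both
    # classes and are correctly kept by both.
    others <- detectors[setdiff(names(detectors), cls)]
    margin <- vapply(seq_along(cx), function(i) {
      patch <- crop_patch(img, round(cx[i]), round(cy[i]), model$window)
      if (is.null(patch) || is.null(model$template)) return(0)
      own <- glyph_containment(patch, model$template)
      rival <- 0
      for (o in others) {
        if (is.null(o$template)) next
        rival <- max(rival, glyph_containment(patch, o$template))
      }
      own - rival
    }, 1)
    parts <- strsplit(cls, "_", fixed = TRUE)[[1]]
    tibble(ear = parts[1], conduction = parts[2],
           frequency_hz = snap_to_grid(am$frequency_hz, grid),
           threshold_db = lvl, score = det$score, margin = margin,
           class = cls)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(ear = character(), conduction = character(),
                  frequency_hz = numeric(), threshold_db = numeric(),
                  score = numeric(), class = character()))
  }
  out |>
    group_by(.data$class, .data$frequency_hz) |>
    arrange(desc(.data$margin), desc(.data$score), .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-"margin") |>
    arrange(.data$class, .data$frequency_hz)
}

# Skeleton containment: mean (shift-tolerant) patch darkness over the
# template's consistently inked pixels. The skeleton is the set of pixels
# dark in essentially every centered positive crop, which is the glyph
# itself plus the frequency ruling; shared structure cancels when two
# containments are differenced. A 3x3 darkness dilation of the patch makes
# the score tolerant of one-pixel localization error.
glyph_containment <- function(patch, template, skeleton_cut = 0.8) {
  mask <- (1 - template) >= skeleton_cut
  if (sum(mask) < 3) return(0)
  d <- 1 - patch
  h <- nrow(d); w <- ncol(d)
  dil <- d
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      dil <- pmax(dil, d[pmin(pmax(seq_len(h) + dy, 1), h),
                         pmin(pmax(seq_len(w) + dx, 1), w)])
    }
  }
  mean(dil[mask])
}

# Darkness-weighted centroid of glyph-ink pixels around (cx, cy);
# NULL when no ink is found in the neighborhood.
ink_centroid <- function(img, cx, cy, radius) {
  r <- floor(radius)
  rows <- max(1, round(cy) - r):min(nrow(img), round(cy) + r)
  cols <- max(1, round(cx) - r):min(ncol(img), round(cx) + r)
  dark <- 1 - img[rows, cols, drop = FALSE]
  dark[dark < 0.5] <- 0
  total <- sum(dark)
  if (total == 0) return(NULL)
  c(sum(rep(cols, each = length(rows)) * dark) / total,
    sum(rep(rows, times = length(cols)) * dark) / total)
}

#' Read or write calibration metadata as JSON
#'
#' Format: `{"freq_anchors": [[x, f], [x, f]], "level_anchors": [[y, db], [y, db]]}`.
#'
#' @param cal A [chart_calibration()].
#' @param path File path.
#' @return `read_calibration_json()` returns the calibration;
#'   `write_calibration_json()` the path, invisibly.
#' @export
write_calibration_json <- function(cal, path) {
  jsonlite::write_json(list(
    freq_anchors = unname(apply(cal$freq_anchors, 1, identity, simplify = FALSE)),
    level_anchors = unname(apply(cal$level_anchors, 1, identity, simplify = FALSE))),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  chart_calibration(
    freq_anchors = list(j$freq_anchors[1, ], j$freq_anchors[2, ]),
    level_anchors = list(j$level_anchors[1, ], j$level_anchors[2, ]))
}
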