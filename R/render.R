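#' Audiogram chart style
#'
#' Geometry and glyph conventions for rendering a threshold profile as a
#' chart image. Follows the audiometric plotting convention: frequency on a
#' log-spaced horizontal axis, hearing level in dB HL increasing downward.
#' Images are grayscale matrices in \[0, 1\] (1 = white background) with the
#' origin at the top-left, so detection never depends on color.
#'
#' Default glyphs: circle for right-ear air conduction, X for left-ear air
#' conduction, and chevron brackets (`<` right, `>` left) for bone
#' conduction — distinct per (ear, conduction) as required for per-ear
#' detector training.
#'
#' @param width,height Image size in pixels.
#' @param margin_left,margin_right,margin_top,margin_bottom Plot margins px.
#' @param db_axis_top,db_axis_bottom Hearing levels (dB HL) at the top and
#'   bottom of the plot area; level increases downward.
#' @param symbol_size_px Glyph diameter in pixels.
#' @param jitter_px Max absolute integer pixel jitter applied to symbol
#'   placement on each axis.
#' @param grid_gray,axis_gray,ink Gray levels of grid lines, axes and glyph
#'   ink (0 = black).
#' @param glyphs Named character vector mapping class names
#'   (`left_air`, `right_air`, `left_bone`, `right_bone`) to glyph shapes
#'   (`"x"`, `"circle"`, `"chevron_left"`, `"chevron_right"`).
#' @param dpi_scale Integer multiplier on all pixel dimensions (resolution
#'   enhancement hook for dense high-frequency layouts).
#' @return A `chart_style` list.
#' @export
chart_style <- function(width = 520, height = 400,
                        margin_left = 60, margin_right = 20,
                        margin_top = 30, margin_bottom = 50,
                        db_axis_top = 0, db_axis_bottom = 120,
                        symbol_size_px = 9, jitter_px = 1,
                        grid_gray = 0.82, axis_gray = 0.25, ink = 0,
                        glyphs = c(right_air = "circle", left_air = "x",
                                   right_bone = "chevron_left",
                                   left_bone = "chevron_right"),
                        dpi_scale = 1) {
  if (db_axis_top >= db_axis_bottom) {
    abort_config("db_axis_top", "dB axis extents must satisfy top < bottom")
  }
  if (symbol_size_px <= 0) abort_config("symbol_size_px", "must be positive")
  if (anyDuplicated(glyphs) > 0) {
    abort_config("glyphs", "glyph shapes must be distinct per (ear, conduction)")
  }
  s <- as.integer(dpi_scale)
  if (s < 1) abort_config("dpi_scale", "must be a positive integer")
  structure(list(
    width = width * s, height = height * s,
    margin_left = margin_left * s, margin_right = margin_right * s,
    margin_top = margin_top * s, margin_bottom = margin_bottom * s,
    db_axis_top = db_axis_top, db_axis_bottom = db_axis_bottom,
    symbol_size_px = symbol_size_px * s, jitter_px = jitter_px,
    grid_gray = grid_gray, axis_gray = axis_gray, ink = ink,
    glyphs = glyphs, dpi_scale = s), class = "chart_style")
}

# Calibration implied by a style and a frequency grid: anchors at the first
# and last grid frequency and at the two dB axis extremes.
style_calibration <- function(style, grid) {
  px <- freq_to_x(style, grid, grid)
  chart_calibration(
    freq_anchors = list(c(px[1], grid[1]), c(px[length(px)], grid[length(grid)])),
    level_anchors = list(c(style$margin_top, style$db_axis_top),
                         c(style$height - style$margin_bottom, style$db_axis_bottom)))
}

freq_to_x <- function(style, f, grid) {
  lo <- log10(min(grid)); hi <- log10(max(grid))
  plot_w <- style$width - style$margin_left - style$margin_right
  style$margin_left + (log10(f) - lo) / (hi - lo) * plot_w
}

db_to_y <- function(style, db) {
  plot_h <- style$height - style$margin_top - style$margin_bottom
  style$margin_top + (db - style$db_axis_top) /
    (style$db_axis_bottom - style$db_axis_top) * plot_h
}

# Glyph masks: logical matrix over a (2r+1)^2 neighborhood.
glyph_mask <- function(shape, size) {
  r <- (size - 1) / 2
  d <- seq(-floor(r), floor(r))
  dx <- outer(rep(1, length(d)), d)   # columns: x offset
  dy <- outer(d, rep(1, length(d)))   # rows: y offset
  r0 <- r - 1
  switch(shape,
    circle = abs(sqrt(dx^2 + dy^2) - r0) <= 0.85,
    x = (abs(dx - dy) <= 0.85 | abs(dx + dy) <= 0.85) &
      pmax(abs(dx), abs(dy)) <= r0,
    chevron_left = abs(dx - (2 * abs(dy) - r0)) <= 0.9 & abs(dy) <= r0,
    chevron_right = abs(dx - (r0 - 2 * abs(dy))) <= 0.9 & abs(dy) <= r0,
    abort(sprintf("unknown glyph shape '%s'", shape)))
}

stamp_glyph <- function(img, cx, cy, mask, ink) {
  r <- (nrow(mask) - 1) / 2
  rows <- (cy - r):(cy + r)
  cols <- (cx - r):(cx + r)
  ok_r <- rows >= 1 & rows <= nrow(img)
  ok_c <- cols >= 1 & cols <= ncol(img)
  sub <- img[rows[ok_r], cols[ok_c], drop = FALSE]
  m <- mask[ok_r, ok_c, drop = FALSE]
  sub[m] <- ink
  img[rows[ok_r], cols[ok_c]] <- sub
  img
}

#' Render one subject's audiogram chart with a ground-truth sidecar
#'
#' Draws the log-frequency grid, dB rulings and one glyph per non-missing
#' threshold of the supplied ear profiles into a grayscale matrix. The truth
#' sidecar records, for every glyph, its class, jittered center pixel and the
#' audiometric coordinates it encodes; the returned calibration maps between
#' the two. Air and bone glyphs at the same (frequency, level) deliberately
#' overlap, as on real charts.
#'
#' @param left_profile,right_profile Long threshold tibbles for one ear each
#'   (as produced by [sample_cohort()], filtered); either may be `NULL`.
#' @param style A [chart_style()].
#' @param seed Integer seed controlling placement jitter.
#' @return A `chart_package`: list with `image` (matrix), `truth` (tibble
#'   `class`, `x`, `y`, `frequency_hz`, `level_db`), `calibration`,
#'   `frequency_grid`, `style`.
#' @export
render_chart <- function(left_profile = NULL, right_profile = NULL,
                         style = chart_style(), seed = 1L) {
  prof <- bind_rows(
    if (!is.null(left_profile)) mutate(left_profile, ear = "left"),
    if (!is.null(right_profile)) mutate(right_profile, ear = "right"))
  if (nrow(prof) == 0) abort("at least one profile must be supplied")
  grid <- sort(unique(prof$frequency_hz))
  if (length(grid) < 2) abort("profiles must cover at least two frequencies")

  drawn <- filter(prof, !is.na(.data$threshold_db))
  bad <- filter(drawn, .data$threshold_db < style$db_axis_top |
                  .data$threshold_db > style$db_axis_bottom)
  if (nrow(bad) > 0) {
    abort(paste0("thresholds outside the dB axis extent: ",
                 paste(sprintf("(%s %s %g Hz = %g dB)", bad$ear, bad$conduction,
                               bad$frequency_hz, bad$threshold_db),
                       collapse = ", ")),
          class = "audiodx_render_error")
  }

  img <- matrix(1, nrow = style$height, ncol = style$width)
  # dB rulings every 10 dB, frequency rulings at grid lines
  y0 <- style$margin_top; y1 <- style$height - style$margin_bottom
  x0 <- style$margin_left; x1 <- style$width - style$margin_right
  for (db in seq(ceiling(style$db_axis_top / 10) * 10,
                 style$db_axis_bottom, by = 10)) {
    y <- round(db_to_y(style, db))
    img[y, x0:x1] <- style$grid_gray
  }
  for (f in grid) {
    x <- round(freq_to_x(style, f, grid))
    img[y0:y1, x] <- style$grid_gray
  }
  img[y0, x0:x1] <- style$axis_gray
  img[y1, x0:x1] <- style$axis_gray
  img[y0:y1, x0] <- style$axis_gray
  img[y0:y1, x1] <- style$axis_gray

  cal <- style_calibration(style, grid)
  masks <- lapply(style$glyphs, glyph_mask, size = style$symbol_size_px)

  with_seed(derive_seed(seed, "render"), {
    truth <- purrr::pmap(drawn, function(ear, conduction, frequency_hz,
                                         threshold_db, ...) {
      cls <- paste(ear, conduction, sep = "_")
      jx <- if (style$jitter_px > 0)
        sample.int(2 * style$jitter_px + 1, 1) - style$jitter_px - 1 else 0L
      jy <- if (style$jitter_px > 0)
        sample.int(2 * style$jitter_px + 1, 1) - style$jitter_px - 1 else 0L
      cx <- round(freq_to_x(style, frequency_hz, grid)) + jx
      cy <- round(db_to_y(style, threshold_db)) + jy
      tibble(class = cls, x = cx, y = cy,
             frequency_hz = frequency_hz, level_db = threshold_db)
    })
    truth <- bind_rows(truth)
    for (i in seq_len(nrow(truth))) {
      img <- stamp_glyph(img, truth$x[i], truth$y[i],
                         masks[[truth$class[i]]], style$ink)
    }
    structure(list(image = img, truth = truth, calibration = cal,
                   frequency_grid = grid, style = style),
              class = "chart_package")
  })
}

crop_patch <- function(img, cx, cy, size) {
  r <- floor(size / 2)
  rows <- (cy - r):(cy + size - r - 1)
  cols <- (cx - r):(cx + size - r - 1)
  if (min(rows) < 1 || max(rows) > nrow(img) ||
      min(cols) < 1 || max(cols) > ncol(img)) return(NULL)
  img[rows, cols, drop = FALSE]
}

#' Export positive/negative training patches per symbol class
#'
#' For each target class, positives are crops centered on that class's truth
#' symbols; negatives are crops centered on symbols of the other classes
#' (in particular the opposite ear's glyphs, which real charts supply as
#' natural negatives), on chart structure that detectors must learn to
#' reject (grid-line crossings and axis borders), and on random background
#' regions.
#'
#' @param packages List of `chart_package` objects.
#' @param patch_size Square patch side in pixels.
#' @param classes Character vector of target classes.
#' @param n_background_per_chart Random background crops sampled per chart
#'   (structured grid/border negatives are added on top).
#' @param augment_shift_px Also crop positives at this many one-pixel
#'   shifts around each symbol center (0 disables); makes detectors
#'   tolerant of placement jitter.
#' @param seed Integer seed for background sampling.
#' @return Named list per class: `positives`, `negatives`, `centered`
#'   (the unshifted positive crops, for template building) and `counts`.
#' @export
export_patch_sets <- function(packages, patch_size = 16,
                              classes = c("left_air", "right_air"),
                              n_background_per_chart = 8,
                              augment_shift_px = 1, seed = 1L) {
  stopifnot(length(packages) >= 1)
  img1 <- packages[[1]]$image
  if (patch_size > nrow(img1) || patch_size > ncol(img1)) {
    abort("patch_size larger than image", class = "audiodx_patch_error")
  }
  truth_all <- bind_rows(purrr::imap(packages, function(p, i) {
    mutate(p$truth, chart = i)
  }))
  with_seed(derive_seed(seed, "patches"), {
    bg <- purrr::imap(packages, function(p, i) {
      h <- nrow(p$image); w <- ncol(p$image)
      xs <- sample(seq(patch_size, w - patch_size), n_background_per_chart)
      ys <- sample(seq(patch_size, h - patch_size), n_background_per_chart)
      st <- p$style
      # structured hard negatives: grid-line crossings and axis borders
      gx <- round(freq_to_x(st, p$frequency_grid, p$frequency_grid))
      gy <- round(db_to_y(st, seq(ceiling(st$db_axis_top / 20) * 20,
                                  st$db_axis_bottom, by = 20)))
      cross <- tidyr::expand_grid(x = gx, y = gy)
      border <- bind_rows(
        tibble(x = round(seq(st$margin_left, w - st$margin_right,
                             length.out = 12)),
               y = rep(c(st$margin_top, h - st$margin_bottom), each = 6)),
        tibble(x = rep(c(st$margin_left, w - st$margin_right), each = 6),
               y = round(seq(st$margin_top, h - st$margin_bottom,
                             length.out = 12))))
      corners <- tidyr::expand_grid(x = c(st$margin_left, w - st$margin_right),
                                    y = c(st$margin_top, h - st$margin_bottom))
      ns <- max(4, ceiling(n_background_per_chart / 2))
      bind_rows(tibble(x = xs, y = ys), corners,
                cross[sample.int(nrow(cross), min(ns, nrow(cross))), ],
                border[sample.int(nrow(border), min(ns, nrow(border))), ]) |>
        mutate(chart = i)
    })
    bg <- bind_rows(bg)
    # drop background points too close to any symbol center
    near <- purrr::map_lgl(seq_len(nrow(bg)), function(i) {
      t <- truth_all[truth_all$chart == bg$chart[i], ]
      any(abs(t$x - bg$x[i]) <= patch_size / 2 &
            abs(t$y - bg$y[i]) <= patch_size / 2)
    })
    bg <- bg[!near, ]

    out <- lapply(classes, function(cls) {
      pos_rows <- truth_all[truth_all$class == cls, ]
      neg_rows <- truth_all[truth_all$class != cls, ]
      grab <- function(rows) {
        purrr::compact(purrr::map(seq_len(nrow(rows)), function(i) {
          crop_patch(packages[[rows$chart[i]]]$image,
                     rows$x[i], rows$y[i], patch_size)
        }))
      }
      pos_src <- pos_rows
      neg_src <- neg_rows
      if (augment_shift_px > 0) {
        shifts <- tidyr::expand_grid(dx = c(-augment_shift_px, 0,
                                            augment_shift_px),
                                     dy = c(-augment_shift_px, 0,
                                            augment_shift_px))
        pos_src <- bind_rows(purrr::pmap(shifts, function(dx, dy) {
          mutate(pos_rows, x = .data$x + dx, y = .data$y + dy)
        }))
        # other-class symbols (the opposite ear above all) are the hardest
        # negatives; cover them with a one-pixel plus-shaped stencil
        neg_src <- bind_rows(purrr::pmap(
          dplyr::filter(shifts, dx == 0 | dy == 0), function(dx, dy) {
            mutate(neg_rows, x = .data$x + dx, y = .data$y + dy)
          }))
      }
      positives <- grab(pos_src)
      negatives <- c(grab(neg_src), grab(bg))
      list(positives = positives, negatives = negatives,
           centered = grab(pos_rows),
           counts = c(positives = length(positives),
                      negatives = length(negatives)))
    })
    names(out) <- classes
    out
  })
}

#' Write or read a grayscale image as plain-text PGM (P2)
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param path File path.
#' @return `read_pgm()` returns the matrix; `write_pgm()` the path,
#'   invisibly.
#' @export
write_pgm <- function(image, path) {
  v <- round(pmin(pmax(image, 0), 1) * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), "255"), con)
  write(t(v), file = con, ncolumns = ncol(image))
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  stopifnot(toks[1] == "P2")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxv <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxv
}
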