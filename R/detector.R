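# Per-ear audiogram symbol detectors: boosted decision stumps over
# rectangle-contrast (Haar-like) features computed on an integral image,
# organized as a small rejection cascade, with vectorized sliding-window
# evaluation.

# Integral image with a zero-padded first row/column so that the sum of
# dark[y..y+h-1, x..x+w-1] = ii[y+h, x+w] - ii[y, x+w] - ii[y+h, x] + ii[y, x].
integral_image <- function(m) {
  cs <- apply(m, 2, cumsum)
  ii <- t(apply(cs, 1, cumsum))
  rbind(0, cbind(0, ii))
}

# A Haar-like feature is a weighted set of rectangles inside the detection
# window; rows of `rects`: dy, dx (0-based offsets), h, w, weight. The value
# is the weighted sum of mean darknesses, i.e. a rectangle contrast.
haar_rects <- function(type, y, x, h, w) {
  r <- function(dy, dx, hh, ww, wgt) c(dy, dx, hh, ww, wgt / (hh * ww))
  m <- switch(type,
    h2 = rbind(r(y, x, h, w, 1), r(y, x + w, h, w, -1)),
    v2 = rbind(r(y, x, h, w, 1), r(y + h, x, h, w, -1)),
    h3 = rbind(r(y, x, h, w, 0.5), r(y, x + w, h, w, -1),
               r(y, x + 2 * w, h, w, 0.5)),
    v3 = rbind(r(y, x, h, w, 0.5), r(y + h, x, h, w, -1),
               r(y + 2 * h, x, h, w, 0.5)),
    quad = rbind(r(y, x, h, w, 0.5), r(y + h, x + w, h, w, 0.5),
                 r(y, x + w, h, w, -0.5), r(y + h, x, h, w, -0.5)),
    center = {
      # inner rect vs its surrounding ring: mean(center) - mean(ring)
      ac <- h * w
      af <- (3 * h) * (3 * w)
      ar <- af - ac
      rbind(c(y + h, x + w, h, w, 1 / ac + 1 / ar),
            c(y, x, 3 * h, 3 * w, -1 / ar))
    })
  colnames(m) <- c("dy", "dx", "h", "w", "wgt")
  m
}

# Random pool of candidate features fitting a `window`-sized patch.
sample_haar_pool <- function(window, n_features, seed) {
  types <- c("h2", "v2", "h3", "v3", "quad", "center")
  with_seed(derive_seed(seed, "haarpool"), {
    purrr::map(seq_len(n_features), function(i) {
      type <- types[sample.int(length(types), 1)]
      reps <- c(h2 = 2, v2 = 1, h3 = 3, v3 = 1, quad = 2, center = 3)[type]
      reps_v <- c(h2 = 1, v2 = 2, h3 = 1, v3 = 3, quad = 2, center = 3)[type]
      w <- sample.int(max(1, floor(window / reps)), 1)
      h <- sample.int(max(1, floor(window / reps_v)), 1)
      x <- sample.int(window - reps * w + 1, 1) - 1
      y <- sample.int(window - reps_v * h + 1, 1) - 1
      list(type = type, rects = haar_rects(type, y, x, h, w))
    })
  })
}

# Feature values for a list of patches: returns an N x F matrix.
patch_feature_matrix <- function(patches, pool) {
  iis <- lapply(patches, function(p) integral_image(1 - p))
  n <- length(patches)
  arr <- array(unlist(iis), dim = c(dim(iis[[1]]), n))
  out <- vapply(pool, function(ft) {
    v <- numeric(n)
    for (k in seq_len(nrow(ft$rects))) {
      rc <- ft$rects[k, ]
      v <- v + rc["wgt"] *
        (arr[rc["dy"] + rc["h"] + 1, rc["dx"] + rc["w"] + 1, ] -
           arr[rc["dy"] + 1, rc["dx"] + rc["w"] + 1, ] -
           arr[rc["dy"] + rc["h"] + 1, rc["dx"] + 1, ] +
           arr[rc["dy"] + 1, rc["dx"] + 1, ])
    }
    v
  }, numeric(n))
  matrix(out, nrow = n, ncol = length(pool))
}

# Best decision stump over all features for the given example weights.
# `orders` caches the per-feature sort permutation of the value matrix V.
best_stump <- function(V, y, wts, orders) {
  n <- nrow(V)
  best <- list(err = Inf)
  wpos_tot <- sum(wts[y > 0])
  wneg_tot <- sum(wts[y < 0])
  for (j in seq_len(ncol(V))) {
    o <- orders[[j]]
    v <- V[o, j]
    wy <- wts[o]
    ispos <- y[o] > 0
    cpos <- cumsum(wy * ispos)
    cneg <- cumsum(wy * !ispos)
    # threshold after position i (h = +1 for v > thr): err for polarity +1
    cut_ok <- c(v[-n] < v[-1], TRUE)
    err_raw <- c(wneg_tot, cpos + (wneg_tot - cneg))  # i = 0..n
    ok <- c(TRUE, cut_ok)
    err_p <- err_raw
    err_p[!ok] <- Inf
    err_m <- (wpos_tot + wneg_tot) - err_raw
    err_m[!ok] <- Inf
    i_p <- which.min(err_p); i_m <- which.min(err_m)
    for (cand in list(c(err_p[i_p], i_p, 1), c(err_m[i_m], i_m, -1))) {
      if (cand[1] < best$err - 1e-12) {
        i <- cand[2]
        thr <- if (i == 1) v[1] - 1 else if (i > n) v[n] + 1
        else (v[i - 1] + v[i]) / 2
        best <- list(err = cand[1], feature = j, threshold = thr,
                     polarity = cand[3])
      }
    }
  }
  best
}

stump_predict <- function(values, thr, polarity) {
  ifelse(polarity * (values - thr) > 0, 1, -1)
}

#' Train a per-ear symbol detector (boosted Haar-feature cascade)
#'
#' Builds a rejection cascade of boosted decision stumps over
#' rectangle-contrast features. Each stage is trained by AdaBoost on the
#' positives plus the negatives that survived earlier stages; its rejection
#' threshold is set to keep at least `stage_min_hit` of training positives.
#' When mining images are supplied, false positives of the partial cascade
#' are harvested from them between stages (hard-negative mining), which is
#' what lets later stages learn to reject grid lines, axis borders and
#' other chart structure. The finished cascade is validated on a held-out
#' split and training fails (with achieved rates) if it misses the
#' configured hit/false-accept targets.
#'
#' @param positives,negatives Lists of square grayscale patch matrices
#'   (equal size, values in \[0, 1\]).
#' @param params List of tuning knobs; see `detector_params()`.
#' @param class_label Symbol class this detector targets (e.g.
#'   `"left_air"`).
#' @param mining_images Optional list of full chart images to mine hard
#'   negatives from.
#' @param mining_exclude Optional list (parallel to `mining_images`) of
#'   tibbles with `x`, `y` centers of true target symbols to exclude from
#'   mining.
#' @param template_positives Optional list of *centered, unshifted* positive
#'   patches used to build the model's mean glyph template (defaults to
#'   `positives`). The template drives cross-class arbitration during chart
#'   digitization.
#' @return A `haar_detector` model.
#' @export
train_detector <- function(positives, negatives, params = detector_params(),
                           class_label = "symbol", mining_images = NULL,
                           mining_exclude = NULL, template_positives = NULL) {
  params <- modifyList(detector_params(), params)
  if (length(positives) < params$min_positives ||
      length(negatives) < params$min_negatives) {
    abort(sprintf("need >= %d positives and >= %d negatives (got %d / %d)",
                  params$min_positives, params$min_negatives,
                  length(positives), length(negatives)),
          class = "audiodx_training_error")
  }
  window <- nrow(positives[[1]])
  stopifnot(all(vapply(c(positives, negatives), nrow, 1L) == window))
  pool <- sample_haar_pool(window, params$n_candidate_features, params$seed)

  with_seed(derive_seed(params$seed, "train"), {
    hold_p <- sample.int(length(positives),
                         max(1, round(params$holdout_fraction * length(positives))))
    hold_n <- sample.int(length(negatives),
                         max(1, round(params$holdout_fraction * length(negatives))))
  })
  tr_pos <- positives[-hold_p]; ho_pos <- positives[hold_p]
  tr_neg <- negatives[-hold_n]; ho_neg <- negatives[hold_n]

  Vpos <- patch_feature_matrix(tr_pos, pool)
  Vneg_all <- patch_feature_matrix(tr_neg, pool)
  active_neg <- seq_len(nrow(Vneg_all))

  mine_hard_negatives <- function(stages_so_far) {
    if (is.null(mining_images)) return(NULL)
    partial <- structure(list(class_label = class_label, window = window,
                              stages = stages_so_far),
                         class = "haar_detector")
    mined <- list()
    for (i in seq_along(mining_images)) {
      fp <- detect(mining_images[[i]], partial, score_threshold = 0,
                   stride = 2L)
      if (nrow(fp) == 0) next
      cx <- fp$x + (fp$w - 1) / 2
      cy <- fp$y + (fp$h - 1) / 2
      excl <- mining_exclude[[i]]
      if (!is.null(excl) && nrow(excl) > 0) {
        near <- purrr::map_lgl(seq_along(cx), function(j) {
          any(abs(excl$x - cx[j]) <= window / 2 &
                abs(excl$y - cy[j]) <= window / 2)
        })
        fp <- fp[!near, ]
      }
      if (nrow(fp) > params$max_mined_per_image) {
        fp <- fp[unique(round(seq(1, nrow(fp),
                                  length.out = params$max_mined_per_image))), ]
      }
      mined <- c(mined, purrr::compact(purrr::map(seq_len(nrow(fp)), function(j) {
        crop_patch(mining_images[[i]],
                   fp$x[j] + floor(window / 2), fp$y[j] + floor(window / 2),
                   window)
      })))
    }
    mined
  }

  stages <- list()
  for (s in seq_len(params$max_stages)) {
    Vneg <- Vneg_all[active_neg, , drop = FALSE]
    V <- rbind(Vpos, Vneg)
    y <- c(rep(1, nrow(Vpos)), rep(-1, nrow(Vneg)))
    orders <- lapply(seq_len(ncol(V)), function(j) order(V[, j]))
    wts <- rep(1 / length(y), length(y))
    stumps <- list()
    margins <- numeric(length(y))
    alpha_sum <- 0
    stage_thr <- -Inf
    for (t in seq_len(params$max_weak_per_stage)) {
      st <- best_stump(V, y, wts, orders)
      err <- min(max(st$err / sum(wts), 1e-10), 1 - 1e-10)
      alpha <- 0.5 * log((1 - err) / err)
      h <- stump_predict(V[, st$feature], st$threshold, st$polarity)
      wts <- wts * exp(-alpha * y * h)
      wts <- wts / sum(wts)
      stumps[[t]] <- list(rects = pool[[st$feature]]$rects,
                          threshold = st$threshold,
                          polarity = st$polarity, alpha = alpha,
                          feature = st$feature)
      margins <- margins + alpha * h
      alpha_sum <- alpha_sum + alpha
      # stage threshold keeping >= stage_min_hit of training positives
      mp <- sort(margins[y > 0])
      k <- floor(length(mp) * (1 - params$stage_min_hit))
      stage_thr <- mp[k + 1] - 1e-9
      fa <- mean(margins[y < 0] >= stage_thr)
      if (fa <= params$stage_max_fa) break
    }
    stages[[s]] <- list(stumps = stumps, threshold = stage_thr,
                        alpha_sum = alpha_sum)
    active_neg <- active_neg[margins[y < 0] >= stage_thr]
    if (s == params$max_stages) break
    mined <- mine_hard_negatives(stages)
    if (length(mined) > 0) {
      Vmined <- patch_feature_matrix(mined, pool)
      active_neg <- c(active_neg, nrow(Vneg_all) + seq_len(nrow(Vmined)))
      Vneg_all <- rbind(Vneg_all, Vmined)
    }
    if (length(active_neg) < 5) break
  }

  tp <- template_positives %||% tr_pos
  template <- Reduce(`+`, tp) / length(tp)
  model <- structure(list(class_label = class_label, window = window,
                          stages = stages, template = template,
                          params = params, seed = params$seed),
                     class = "haar_detector")

  acc_p <- vapply(ho_pos, function(p) cascade_accept_patch(model, p), TRUE)
  acc_n <- vapply(ho_neg, function(p) cascade_accept_patch(model, p), TRUE)
  hit <- mean(acc_p); fa <- mean(acc_n)
  if (hit < params$min_hit_rate || fa > params$max_false_accept) {
    abort(sprintf(
      "detector training missed its targets: held-out hit rate %.3f (need >= %.3f), false-accept %.3f (need <= %.3f)",
      hit, params$min_hit_rate, fa, params$max_false_accept),
      class = "audiodx_training_error", hit_rate = hit, false_accept = fa)
  }
  model$holdout <- c(hit_rate = hit, false_accept = fa)
  model
}

#' @rdname train_detector
#' @param n_candidate_features Size of the random Haar-feature pool.
#' @param max_stages,max_weak_per_stage Cascade shape limits.
#' @param stage_min_hit Per-stage minimum fraction of training positives
#'   kept.
#' @param stage_max_fa Per-stage target false-accept rate on surviving
#'   negatives.
#' @param min_hit_rate,max_false_accept Held-out acceptance gates for the
#'   finished cascade.
#' @param min_positives,min_negatives Minimum training-set sizes.
#' @param holdout_fraction Fraction of patches held out for validation.
#' @param max_mined_per_image Cap on hard negatives harvested per mining
#'   image per stage.
#' @param seed Integer seed (feature pool + holdout split).
#' @export
detector_params <- function(n_candidate_features = 250, max_stages = 6,
                            max_weak_per_stage = 20, stage_min_hit = 0.995,
                            stage_max_fa = 0.25, min_hit_rate = 0.9,
                            max_false_accept = 0.15, min_positives = 20,
                            min_negatives = 50, holdout_fraction = 0.2,
                            max_mined_per_image = 200, seed = 1L) {
  list(n_candidate_features = n_candidate_features, max_stages = max_stages,
       max_weak_per_stage = max_weak_per_stage, stage_min_hit = stage_min_hit,
       stage_max_fa = stage_max_fa, min_hit_rate = min_hit_rate,
       max_false_accept = max_false_accept, min_positives = min_positives,
       min_negatives = min_negatives, holdout_fraction = holdout_fraction,
       max_mined_per_image = max_mined_per_image, seed = seed)
}

# Evaluate one patch through the whole cascade.
cascade_accept_patch <- function(model, patch) {
  ii <- integral_image(1 - patch)
  for (stage in model$stages) {
    m <- 0
    for (st in stage$stumps) {
      v <- 0
      for (k in seq_len(nrow(st$rects))) {
        rc <- st$rects[k, ]
        v <- v + rc["wgt"] *
          (ii[rc["dy"] + rc["h"] + 1, rc["dx"] + rc["w"] + 1] -
             ii[rc["dy"] + 1, rc["dx"] + rc["w"] + 1] -
             ii[rc["dy"] + rc["h"] + 1, rc["dx"] + 1] +
             ii[rc["dy"] + 1, rc["dx"] + 1])
      }
      m <- m + st$alpha * stump_predict(v, st$threshold, st$polarity)
    }
    if (m < stage$threshold) return(FALSE)
  }
  TRUE
}

patch_score <- function(model, patch) {
  ii <- integral_image(1 - patch)
  last <- model$stages[[length(model$stages)]]
  m <- 0
  for (st in last$stumps) {
    v <- 0
    for (k in seq_len(nrow(st$rects))) {
      rc <- st$rects[k, ]
      v <- v + rc["wgt"] *
        (ii[rc["dy"] + rc["h"] + 1, rc["dx"] + rc["w"] + 1] -
           ii[rc["dy"] + 1, rc["dx"] + rc["w"] + 1] -
           ii[rc["dy"] + rc["h"] + 1, rc["dx"] + 1] +
           ii[rc["dy"] + 1, rc["dx"] + 1])
    }
    m <- m + st$alpha * stump_predict(v, st$threshold, st$polarity)
  }
  (m / last$alpha_sum + 1) / 2
}

# Feature value of one stump at every window position; ii is the padded
# integral image, rr/cc the window top-left coordinate vectors.
stump_value_map <- function(ii, st, rr, cc) {
  v <- matrix(0, length(rr), length(cc))
  for (k in seq_len(nrow(st$rects))) {
    rc <- st$rects[k, ]
    r1 <- rr + rc["dy"]; c1 <- cc + rc["dx"]
    v <- v + rc["wgt"] *
      (ii[r1 + rc["h"], c1 + rc["w"], drop = FALSE] -
         ii[r1, c1 + rc["w"], drop = FALSE] -
         ii[r1 + rc["h"], c1, drop = FALSE] +
         ii[r1, c1, drop = FALSE])
  }
  v
}

#' Locate symbols in a chart image with a trained detector
#'
#' Slides the cascade window over the image in deterministic row-major
#' order. A window is reported when it passes every stage and its final
#' normalized boosting score reaches `score_threshold`; lowering the
#' threshold only ever adds detections.
#'
#' @param image Grayscale matrix in \[0, 1\].
#' @param model A `haar_detector` from [train_detector()].
#' @param score_threshold Minimum score in \[0, 1\].
#' @param stride Window step in pixels.
#' @param scales Numeric vector of image scales (1 = native; the renderer
#'   controls symbol size so single-scale is the default).
#' @return Tibble of detections: `x`, `y` (top-left, 1-indexed), `w`, `h`,
#'   `class`, `score`.
#' @export
detect <- function(image, model, score_threshold = 0.5, stride = 1L,
                   scales = 1) {
  win <- model$window
  out <- purrr::map(scales, function(sc) {
    img <- if (sc == 1) image else resize_nn(image, sc)
    if (nrow(img) < win || ncol(img) < win) return(NULL)
    ii <- integral_image(1 - img)
    rr <- seq(1, nrow(img) - win + 1, by = stride)
    cc <- seq(1, ncol(img) - win + 1, by = stride)
    active <- matrix(TRUE, length(rr), length(cc))
    score_map <- NULL
    for (stage in model$stages) {
      m <- matrix(0, length(rr), length(cc))
      for (st in stage$stumps) {
        v <- stump_value_map(ii, st, rr, cc)
        m <- m + st$alpha * ifelse(st$polarity * (v - st$threshold) > 0, 1, -1)
      }
      active <- active & (m >= stage$threshold)
      score_map <- (m / stage$alpha_sum + 1) / 2
    }
    hit <- which(active & score_map >= score_threshold, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    tibble(x = round((cc[hit[, 2]] - 1) / sc) + 1,
           y = round((rr[hit[, 1]] - 1) / sc) + 1,
           w = round(win / sc), h = round(win / sc),
           class = model$class_label,
           score = score_map[hit])
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(x = integer(), y = integer(), w = integer(), h = integer(),
                  class = character(), score = numeric()))
  }
  arrange(out, .data$y, .data$x)
}

resize_nn <- function(img, scale) {
  h <- max(1, round(nrow(img) * scale))
  w <- max(1, round(ncol(img) * scale))
  img[pmin(nrow(img), pmax(1, round(seq_len(h) / scale))),
      pmin(ncol(img), pmax(1, round(seq_len(w) / scale))), drop = FALSE]
}

box_iou <- function(a, b) {
  ix <- pmax(0, pmin(a$x + a$w, b$x + b$w) - pmax(a$x, b$x))
  iy <- pmax(0, pmin(a$y + a$h, b$y + b$h) - pmax(a$y, b$y))
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' Resolve overlapping detections (per-class non-maximum suppression)
#'
#' Within each class, greedily keeps the higher-scoring box (ties broken by
#' smaller x, then smaller y) and removes boxes overlapping a kept box at
#' IoU >= `iou_threshold`. Boxes of *different* classes are never suppressed
#' against each other, so overlapping air and bone symbols both survive.
#'
#' @param detections Tibble from [detect()] (possibly several classes).
#' @param iou_threshold IoU threshold in (0, 1\].
#' @return Filtered detections tibble.
#' @export
resolve_overlaps <- function(detections, iou_threshold = 0.3) {
  if (!is.numeric(iou_threshold) || length(iou_threshold) != 1 ||
      iou_threshold <= 0 || iou_threshold > 1) {
    abort("iou_threshold must lie in (0, 1]", class = "audiodx_nms_error")
  }
  if (nrow(detections) == 0) return(detections)
  kept <- detections |>
    group_by(.data$class) |>
    dplyr::group_modify(function(d, key) {
      d <- arrange(d, desc(.data$score), .data$x, .data$y)
      keep <- logical(nrow(d))
      for (i in seq_len(nrow(d))) {
        if (i == 1) { keep[1] <- TRUE; next }
        prev <- d[which(keep[seq_len(i - 1)]), , drop = FALSE]
        ious <- box_iou(prev, d[i, ])
        keep[i] <- all(ious < iou_threshold)
      }
      d[keep, , drop = FALSE]
    }) |>
    ungroup()
  arrange(kept, .data$class, desc(.data$score), .data$x, .data$y)
}

#' Serialize a detector to JSON and back
#'
#' @param model A `haar_detector`.
#' @param path File path.
#' @return `read_detector_json()` returns the model;
#'   `write_detector_json()` the path, invisibly.
#' @export
write_detector_json <- function(model, path) {
  ser <- list(class_label = model$class_label, window = model$window,
              seed = model$seed, holdout = as.list(model$holdout),
              template = apply(unname(model$template), 1, as.numeric,
                               simplify = FALSE),
              stages = lapply(model$stages, function(stage) {
                list(threshold = stage$threshold, alpha_sum = stage$alpha_sum,
                     stumps = lapply(stage$stumps, function(st) {
                       list(rects = apply(unname(st$rects), 1, as.numeric,
                                          simplify = FALSE),
                            threshold = st$threshold,
                            polarity = st$polarity, alpha = st$alpha)
                     }))
              }))
  # I(17) significant digits: exact double round-trip, so a deserialized
  # cascade votes identically at threshold-boundary windows
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_detector_json
#' @export
read_detector_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  stages <- lapply(j$stages, function(stage) {
    list(threshold = stage$threshold, alpha_sum = stage$alpha_sum,
         stumps = lapply(stage$stumps, function(st) {
           rects <- do.call(rbind, lapply(st$rects, function(r)
             as.numeric(unlist(r))))
           colnames(rects) <- c("dy", "dx", "h", "w", "wgt")
           list(rects = rects, threshold = st$threshold,
                polarity = st$polarity, alpha = st$alpha)
         }))
  })
  template <- if (!is.null(j$template)) {
    do.call(rbind, lapply(j$template, function(r) as.numeric(unlist(r))))
  }
  structure(list(class_label = j$class_label, window = j$window,
                 stages = stages, template = template, seed = j$seed,
                 holdout = unlist(j$holdout)),
            class = "haar_detector")
}
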