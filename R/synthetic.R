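#' Synthetic scene specification
#'
#' A stated world for end-to-end testing: a frame containing a quadrat,
#' flower patches as coloured disks whose HSV colour lies strictly inside a
#' target colour band, a background colour outside all bands, and optional
#' bumblebee-like dark ellipses (~30 mm body length).
#'
#' @param geometry a \code{frame_geometry}.
#' @param quadrat a \code{quadrat_spec}.
#' @param flowers data frame with columns \code{cx, cy, r} (pixels) and
#'   \code{h, s, v} (0-255); may have zero rows.
#' @param background HSV triplet outside all bands (default a dull green).
#' @param bee_colour HSV triplet for bee bodies (default near-black).
#' @param bee_length_mm bee body length, default 30 mm.
#' @return object of class \code{scene_spec}.
#' @export
scene_spec <- function(geometry, quadrat,
                       flowers = data.frame(cx = numeric(), cy = numeric(),
                                            r = numeric(), h = numeric(),
                                            s = numeric(), v = numeric()),
                       background = c(60, 60, 80),
                       bee_colour = c(30, 200, 20),
                       bee_length_mm = 30) {
  stopifnot(inherits(geometry, "frame_geometry"),
            inherits(quadrat, "quadrat_spec"))
  needed <- c("cx", "cy", "r", "h", "s", "v")
  if (!all(needed %in% names(flowers)))
    stop("flowers must have columns ", paste(needed, collapse = ", "))
  structure(list(geometry = geometry, quadrat = quadrat,
                 flowers = flowers, background = background,
                 bee_colour = bee_colour, bee_length_mm = bee_length_mm),
            class = "scene_spec")
}

# pixel-centre coordinate grids (0-based pixel ix has centre ix + 0.5)
pixel_grids <- function(height, width) {
  list(x = matrix(rep(seq_len(width) - 0.5, each = height), height, width),
       y = matrix(rep(seq_len(height) - 0.5, times = width), height, width))
}

flower_pixel_mask <- function(spec) {
  g <- spec$geometry
  grids <- pixel_grids(g$height_px, g$width_px)
  m <- matrix(FALSE, g$height_px, g$width_px)
  for (i in seq_len(nrow(spec$flowers))) {
    f <- spec$flowers[i, ]
    m <- m | ((grids$x - f$cx)^2 + (grids$y - f$cy)^2 <= f$r^2)
  }
  m
}

#' Render a synthetic scene
#'
#' Paints the background, then the flower disks, then (optionally) bee
#' ellipses on top. Deterministic: all randomness lives in the spec
#' constructors. Ground truth records the exact painted in-quadrat flower
#' cover (pixel count based, i.e. the declared cover up to rasterisation)
#' and the bee bounding boxes.
#'
#' @param spec a \code{scene_spec}.
#' @param bees optional data frame of ellipses with columns \code{cx, cy}
#'   (centre px), \code{angle} (radians); body length and colour come from
#'   the spec.
#' @return list with \code{frame} (HSV array) and \code{truth}: a list with
#'   \code{cover_frac} (painted flower pixels in quadrat / quadrat pixels,
#'   counted before bees are painted), \code{n_flower_px},
#'   \code{quadrat_px}, \code{flower_mask}, and \code{bee_boxes} (a
#'   \code{detection_set}-shaped data frame).
#' @export
render_scene <- function(spec, bees = NULL) {
  g <- spec$geometry
  img <- hsv_image(g$height_px, g$width_px, spec$background)
  fmask <- flower_pixel_mask(spec)
  # paint each disk with its own colour (later disks win on overlap)
  grids <- pixel_grids(g$height_px, g$width_px)
  for (i in seq_len(nrow(spec$flowers))) {
    f <- spec$flowers[i, ]
    dmask <- (grids$x - f$cx)^2 + (grids$y - f$cy)^2 <= f$r^2
    col <- c(f$h, f$s, f$v)
    for (k in 1:3) {
      plane <- img[, , k]
      plane[dmask] <- col[k]
      img[, , k] <- plane
    }
  }
  qrect <- quadrat_rect(spec$quadrat, g)
  qidx <- rect_to_idx(qrect, dim(img))
  n_flower <- sum(fmask[qidx$rows, qidx$cols])
  quadrat_px <- length(qidx$rows) * length(qidx$cols)
  bee_boxes <- empty_bee_boxes()
  if (!is.null(bees) && nrow(bees) > 0) {
    len_px <- spec$bee_length_mm / g$mm_per_px
    for (i in seq_len(nrow(bees))) {
      img <- paint_bee(img, grids, bees$cx[i], bees$cy[i], bees$angle[i],
                       len_px, spec$bee_colour)
      bee_boxes <- rbind(bee_boxes,
                         bee_box(bees$cx[i], bees$cy[i], len_px))
    }
  }
  list(frame = img,
       truth = list(cover_frac = n_flower / quadrat_px,
                    n_flower_px = n_flower, quadrat_px = quadrat_px,
                    flower_mask = fmask, bee_boxes = bee_boxes))
}

band_species <- function(scene) {
  sp <- attr(scene, "species")
  if (is.null(sp)) NA_character_ else sp
}

empty_bee_boxes <- function() {
  data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric())
}

# axis-aligned box of side len_px centred at (cx, cy)
bee_box <- function(cx, cy, len_px) {
  h <- len_px / 2
  data.frame(x1 = cx - h, y1 = cy - h, x2 = cx + h, y2 = cy + h)
}

paint_bee <- function(img, grids, cx, cy, angle, len_px, colour) {
  a <- len_px / 2          # semi-major (body length / 2)
  b <- len_px / 5          # semi-minor (slender body)
  dx <- grids$x - cx; dy <- grids$y - cy
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  m <- (u / a)^2 + (v / b)^2 <= 1
  for (k in 1:3) {
    plane <- img[, , k]
    plane[m] <- colour[k]
    img[, , k] <- plane
  }
  img
}

#' A colour strictly inside a band
#'
#' Midpoint of each channel's pass range; for inverted channels the lower
#' arm of the complement is used (values at or below the upper bound).
#'
#' @param band a \code{colour_band}.
#' @return HSV triplet.
#' @export
band_interior_colour <- function(band) {
  sapply(1:3, function(k) {
    if (band$inverted[k]) band$upper[k] / 2
    else (band$lower[k] + band$upper[k]) / 2
  })
}

#' Random synthetic scene
#'
#' Places non-overlapping flower disks fully inside the quadrat, coloured
#' strictly inside the target band, over an out-of-band background.
#' Deterministic given the seed.
#'
#' @param geometry a \code{frame_geometry}.
#' @param quadrat a \code{quadrat_spec}.
#' @param band target \code{colour_band} for the flower colour.
#' @param n_flowers number of disks to attempt (overlapping or
#'   out-of-quadrat draws are rejected and retried a bounded number of
#'   times).
#' @param r_range disk radius range in pixels.
#' @param seed RNG seed.
#' @return a \code{scene_spec}.
#' @export
random_scene_spec <- function(geometry, quadrat, band, n_flowers = 5,
                              r_range = c(12, 30), seed = 1L) {
  qrect <- quadrat_rect(quadrat, geometry)
  col <- band_interior_colour(band)
  flowers <- with_seed(seed, {
    placed <- data.frame(cx = numeric(), cy = numeric(), r = numeric())
    tries <- 0
    while (nrow(placed) < n_flowers && tries < 200 * n_flowers) {
      tries <- tries + 1
      r <- stats::runif(1, r_range[1], r_range[2])
      cx <- stats::runif(1, qrect[["x1"]] + r, qrect[["x2"]] - r)
      cy <- stats::runif(1, qrect[["y1"]] + r, qrect[["y2"]] - r)
      if (nrow(placed) == 0 ||
          all(sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2) >
              placed$r + r + 2))
        placed <- rbind(placed, data.frame(cx = cx, cy = cy, r = r))
    }
    placed
  })
  flowers$h <- col[1]; flowers$s <- col[2]; flowers$v <- col[3]
  scene_spec(geometry, quadrat, flowers)
}

#' Synthetic detection-stream specification
#'
#' Statistical model of bee visitation: per-frame bee counts are i.i.d.
#' Poisson with mean \code{lambda} (the quantity patch attractiveness
#' estimates); each bee is on a flower with probability \code{p_on};
#' duplicate boxes are injected with probability \code{dup_rate} per bee at
#' a centroid offset below half the merge distance, emulating tile-seam
#' double detections; confidences are uniform on \code{conf_range}.
#'
#' @param n_frames number of frames.
#' @param lambda mean per-frame bee count (>= 0).
#' @param p_on on-flower probability in \[0, 1\].
#' @param dup_rate duplicate-injection probability per bee in \[0, 1\].
#' @param conf_range confidence distribution range.
#' @return object of class \code{stream_spec}.
#' @export
stream_spec <- function(n_frames, lambda, p_on = 0.5, dup_rate = 0,
                        conf_range = c(0.4, 1)) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (p_on < 0 || p_on > 1) stop("p_on must lie in [0, 1]")
  if (dup_rate < 0 || dup_rate > 1) stop("dup_rate must lie in [0, 1]")
  structure(list(n_frames = as.integer(n_frames), lambda = lambda,
                 p_on = p_on, dup_rate = dup_rate, conf_range = conf_range),
            class = "stream_spec")
}

#' Emit a synthetic detection stream with ground truth
#'
#' Draws per-frame counts and places each bee either on a flower disk (the
#' bee box fully inside the disk, so an on-flower classification with any
#' sensible threshold is unambiguous) or on the background (box clear of
#' all disks). Distinct bees in a frame are kept at least 2.5 merge
#' distances apart so only injected duplicates merge. Injected duplicates
#' are offset by less than half the merge distance.
#'
#' @param stream a \code{stream_spec}.
#' @param scene a \code{scene_spec}; its geometry, quadrat and flower disks
#'   are used for placement. Disks must be large enough to contain a bee
#'   box when \code{p_on > 0}.
#' @param seed RNG seed.
#' @return list with \code{detections} (raw \code{detection_set}, duplicates
#'   included) and \code{truth}: \code{counts} (true per-frame bee counts),
#'   \code{bees} (one row per true bee: frame_idx, box, on_flower, angle),
#'   \code{merge_dist_px}, \code{n_duplicates}.
#' @export
emit_stream <- function(stream, scene, seed = 1L) {
  g <- scene$geometry
  qrect <- quadrat_rect(scene$quadrat, g)
  len_px <- scene$bee_length_mm / g$mm_per_px
  half <- len_px / 2
  merge_px <- merge_distance_px(g$mm_per_px)
  flowers <- scene$flowers
  # disks able to contain a full bee box (half-diagonal clearance)
  clearance <- half * sqrt(2)
  host <- flowers[flowers$r > clearance + 1, , drop = FALSE]
  if (stream$p_on > 0 && nrow(host) == 0)
    stop("no flower disk is large enough to host an on-flower bee")
  with_seed(seed, {
    counts <- stats::rpois(stream$n_frames, stream$lambda)
    bees <- list(); dets <- list(); n_dup <- 0L
    for (t in which(counts > 0)) {
      placed <- matrix(numeric(), ncol = 2)
      for (b in seq_len(counts[t])) {
        on <- stats::runif(1) < stream$p_on
        for (try in 1:500) {
          if (on) {
            i <- sample.int(nrow(host), 1)
            rmax <- host$r[i] - clearance - 0.5
            rr <- sqrt(stats::runif(1)) * max(rmax, 0)
            th <- stats::runif(1, 0, 2 * pi)
            cx <- host$cx[i] + rr * cos(th); cy <- host$cy[i] + rr * sin(th)
          } else {
            cx <- stats::runif(1, qrect[["x1"]] + half, qrect[["x2"]] - half)
            cy <- stats::runif(1, qrect[["y1"]] + half, qrect[["y2"]] - half)
            if (nrow(flowers) > 0 &&
                any(sqrt((flowers$cx - cx)^2 + (flowers$cy - cy)^2) <
                    flowers$r + clearance + 1)) next
          }
          if (nrow(placed) == 0 ||
              all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                  2.5 * merge_px)) break
          if (try == 500) stop("could not place bees with required separation")
        }
        placed <- rbind(placed, c(cx, cy))
        bb <- bee_box(cx, cy, len_px)
        bees[[length(bees) + 1]] <-
          cbind(frame_idx = t - 1L, bb, on_flower = on,
                angle = stats::runif(1, 0, pi))
        conf <- stats::runif(1, stream$conf_range[1], stream$conf_range[2])
        dets[[length(dets) + 1]] <- cbind(frame_idx = t - 1L, bb,
                                          confidence = conf)
        if (stats::runif(1) < stream$dup_rate) {
          n_dup <- n_dup + 1L
          th <- stats::runif(1, 0, 2 * pi)
          off <- stats::runif(1, 0, 0.45 * merge_px)
          bb2 <- bb
          bb2$x1 <- bb$x1 + off * cos(th); bb2$x2 <- bb$x2 + off * cos(th)
          bb2$y1 <- bb$y1 + off * sin(th); bb2$y2 <- bb$y2 + off * sin(th)
          conf2 <- stats::runif(1, stream$conf_range[1], stream$conf_range[2])
          dets[[length(dets) + 1]] <- cbind(frame_idx = t - 1L, bb2,
                                            confidence = conf2)
        }
      }
    }
    bees_df <- if (length(bees) > 0) do.call(rbind, bees) else
      cbind(frame_idx = integer(), empty_bee_boxes(), on_flower = logical(),
            angle = numeric())
    dets_df <- if (length(dets) > 0) do.call(rbind, dets) else
      cbind(frame_idx = integer(), empty_bee_boxes(), confidence = numeric())
    list(detections = detection_set(dets_df$frame_idx, dets_df$x1,
                                    dets_df$y1, dets_df$x2, dets_df$y2,
                                    dets_df$confidence,
                                    video_id = "synthetic",
                                    species = band_species(scene)),
         truth = list(counts = counts, bees = bees_df,
                      merge_dist_px = merge_px, n_duplicates = n_dup))
  })
}

#' Frame accessor for a synthetic video
#'
#' Returns a function rendering frame \code{i} (1-based) of the scene with
#' the true bees of that frame painted in, suitable as the \code{frames}
#' argument of [compute_ofc()], [build_heatmap()] and
#' [classify_on_flower()] (pass \code{n_available = n_frames}).
#'
#' @param scene a \code{scene_spec}.
#' @param stream_result result of [emit_stream()].
#' @return function \code{f(i)} returning an HSV array.
#' @export
synthetic_video <- function(scene, stream_result) {
  bees <- stream_result$truth$bees
  g <- scene$geometry
  grids <- pixel_grids(g$height_px, g$width_px)
  base <- render_scene(scene)$frame
  len_px <- scene$bee_length_mm / g$mm_per_px
  function(i) {
    fb <- bees[bees$frame_idx == (i - 1L), , drop = FALSE]
    img <- base
    for (r in seq_len(nrow(fb)))
      img <- paint_bee(img, grids, (fb$x1[r] + fb$x2[r]) / 2,
                       (fb$y1[r] + fb$y2[r]) / 2, fb$angle[r], len_px,
                       scene$bee_colour)
    img
  }
}
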