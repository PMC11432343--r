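#' Species colour bands
#'
#' A colour band is a pair of lower/upper HSV triplets on the internal
#' 0-255 scale (hue period 256, matching the ImageJ HSB convention in which
#' the thresholds were determined). A channel whose lower bound exceeds its
#' upper bound is an inverted (pass-band-complement) channel: a value passes
#' iff it is \code{>= lower} OR \code{<= upper}. This mirrors ImageJ's
#' threshold inversion and is what the shipped knotweed and clover
#' saturation ranges use.
#'
#' @param lower,upper numeric length-3 HSV triplets in \[0, 255\].
#' @param species optional species tag.
#' @param inverted optional logical length-3 flag per channel; by default a
#'   channel is inverted iff \code{lower > upper}.
#' @return object of class \code{colour_band}.
#' @export
colour_band <- function(lower, upper, species = NA_character_,
                        inverted = NULL) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3 || length(upper) != 3)
    stop("lower and upper must be HSV triplets")
  if (any(lower < 0 | lower > 255) || any(upper < 0 | upper > 255))
    stop("channel bounds must lie in [0, 255]")
  if (is.null(inverted)) inverted <- lower > upper
  inverted <- as.logical(rep_len(inverted, 3))
  if (any(lower > upper & !inverted))
    stop("lower > upper on a non-inverted channel")
  structure(list(lower = lower, upper = upper, inverted = inverted,
                 species = species),
            class = "colour_band")
}

#' @export
print.colour_band <- function(x, ...) {
  ch <- c("H", "S", "V")
  cat(sprintf("<colour_band> %s\n",
              if (is.na(x$species)) "(untagged)" else x$species))
  for (i in 1:3)
    cat(sprintf("  %s: %g..%g%s\n", ch[i], x$lower[i], x$upper[i],
                if (x$inverted[i]) " (inverted)" else ""))
  invisible(x)
}

#' Shipped flower colour thresholds
#'
#' Manually determined HSB thresholds for the three study species
#' (0-255 scale): Cretan bird's-foot trefoil (\emph{Lotus creticus}),
#' pink-headed knotweed (\emph{Persicaria capitata}) and red clover
#' (\emph{Trifolium pratense}). The knotweed and clover saturation channels
#' are inverted bands.
#'
#' @return named list of \code{colour_band} objects
#'   (\code{lotus}, \code{persicaria}, \code{trifolium}).
#' @export
species_colour_bands <- function() {
  list(
    lotus = colour_band(c(11, 42, 120), c(255, 160, 255), "lotus"),
    persicaria = colour_band(c(140, 255, 0), c(140, 40, 255), "persicaria"),
    trifolium = colour_band(c(85, 255, 0), c(247, 186, 255), "trifolium")
  )
}

#' HSV image constructor
#'
#' Images are arrays of dimension (height, width, 3) holding H, S, V planes
#' on the 0-255 scale.
#'
#' @param height,width dimensions in pixels.
#' @param hsv background triplet, default black.
#' @return numeric array \code{c(height, width, 3)}.
#' @export
hsv_image <- function(height, width, hsv = c(0, 0, 0)) {
  img <- array(0, dim = c(height, width, 3))
  for (k in 1:3) img[, , k] <- hsv[k]
  img
}

check_hsv_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("expected an HSV array of dimension (height, width, 3)")
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 255)
    stop("channel values outside the internal 0-255 scale")
  invisible(img)
}

channel_pass <- function(v, lower, upper, inverted) {
  if (inverted) v >= lower | v <= upper else v >= lower & v <= upper
}

#' Binary colour mask for a band
#'
#' A pixel passes iff every channel passes its band test (inclusive bounds;
#' inverted channels pass outside the \code{(upper, lower)} gap).
#'
#' @param image_hsv HSV array (height, width, 3) on the 0-255 scale.
#' @param band a \code{colour_band}.
#' @return logical matrix (height, width).
#' @export
band_mask <- function(image_hsv, band) {
  check_hsv_image(image_hsv)
  m <- channel_pass(image_hsv[, , 1], band$lower[1], band$upper[1],
                    band$inverted[1])
  for (k in 2:3)
    m <- m & channel_pass(image_hsv[, , k], band$lower[k], band$upper[k],
                          band$inverted[k])
  m
}

rect_to_idx <- function(rect, dim_hw) {
  xs <- seq.int(floor(rect[["x1"]]), ceiling(rect[["x2"]]) - 1L)
  ys <- seq.int(floor(rect[["y1"]]), ceiling(rect[["y2"]]) - 1L)
  xs <- xs[xs >= 0 & xs < dim_hw[2]]
  ys <- ys[ys >= 0 & ys < dim_hw[1]]
  list(rows = ys + 1L, cols = xs + 1L)
}

#' Flower cover inside a quadrat
#'
#' Fraction of quadrat pixels passing the species colour band in one frame:
#' masked pixel count divided by the quadrat pixel count.
#'
#' @param frame HSV array.
#' @param band a \code{colour_band}.
#' @param rect quadrat rectangle in pixel coordinates (half-open).
#' @return fraction in \[0, 1\].
#' @export
flower_cover <- function(frame, band, rect) {
  check_hsv_image(frame)
  idx <- rect_to_idx(rect, dim(frame))
  if (length(idx$rows) == 0 || length(idx$cols) == 0)
    stop("quadrat rectangle is empty within the frame")
  m <- band_mask(frame[idx$rows, idx$cols, , drop = FALSE], band)
  mean(m)
}

#' Optimal flower colour (OFC)
#'
#' The per-species reference colour: sample \code{n_frames} frames from the
#' video, pool every in-band pixel over the sample, and take the
#' channel-wise median of the pooled H, S, V values. Deterministic given the
#' seed.
#'
#' @param frames list of HSV arrays, or a function \code{f(i)} returning
#'   frame \code{i} (1-based) paired with \code{n_available}.
#' @param band a \code{colour_band}.
#' @param n_frames number of frames to sample (default 10).
#' @param seed RNG seed for the frame sample.
#' @param n_available number of frames accessible through a function
#'   accessor; ignored when \code{frames} is a list.
#' @return HSV triplet of class \code{ofc} with attributes recording the
#'   sampled frames and seed.
#' @export
compute_ofc <- function(frames, band, n_frames = 10, seed = 1L,
                        n_available = NULL) {
  acc <- frame_accessor(frames, n_available)
  take <- min(n_frames, acc$n)
  idx <- with_seed(seed, sample.int(acc$n, take))
  pooled <- matrix(numeric(), ncol = 3)
  for (i in idx) {
    img <- acc$get(i)
    m <- band_mask(img, band)
    if (any(m))
      pooled <- rbind(pooled, cbind(img[, , 1][m], img[, , 2][m],
                                    img[, , 3][m]))
  }
  if (nrow(pooled) == 0)
    stop("no in-band pixels in the sampled frames; cannot compute OFC")
  ofc <- apply(pooled, 2, stats::median)
  names(ofc) <- c("h", "s", "v")
  structure(ofc, class = "ofc", frames_sampled = idx, seed = seed,
            species = band$species)
}

# normalise list-of-frames / accessor-function input
frame_accessor <- function(frames, n_available = NULL) {
  if (is.function(frames)) {
    if (is.null(n_available))
      stop("n_available is required with a function frame accessor")
    list(get = frames, n = as.integer(n_available))
  } else {
    list(get = function(i) frames[[i]], n = length(frames))
  }
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Circular colour distance to a reference colour
#'
#' Euclidean distance in HSV accounting for the circular hue channel:
#' \deqn{d = \sqrt{dh^2 + \Delta s^2 + \Delta v^2}, \quad
#'       dh = \min(|\Delta h|, P - |\Delta h|)}
#' with hue period \code{P} (256 on the internal scale).
#'
#' @param pixel_hsv an HSV triplet, an n x 3 matrix of triplets, or an HSV
#'   array (height, width, 3).
#' @param ofc reference HSV triplet (e.g. from [compute_ofc()]).
#' @param h_period hue period, default 256.
#' @return distances with the shape of the input (scalar, vector, or
#'   height x width matrix).
#' @export
circular_colour_distance <- function(pixel_hsv, ofc, h_period = 256) {
  if (is.array(pixel_hsv) && length(dim(pixel_hsv)) == 3) {
    dh <- abs(pixel_hsv[, , 1] - ofc[[1]])
    dh <- pmin(dh, h_period - dh)
    return(sqrt(dh^2 + (pixel_hsv[, , 2] - ofc[[2]])^2 +
                  (pixel_hsv[, , 3] - ofc[[3]])^2))
  }
  m <- if (is.matrix(pixel_hsv)) pixel_hsv else matrix(pixel_hsv, ncol = 3)
  dh <- abs(m[, 1] - ofc[[1]])
  dh <- pmin(dh, h_period - dh)
  d <- sqrt(dh^2 + (m[, 2] - ofc[[2]])^2 + (m[, 3] - ofc[[3]])^2)
  if (!is.matrix(pixel_hsv)) d[1] else d
}

#' Colour-distance heatmap
#'
#' Per-pixel mean circular colour distance to the OFC over a sample of
#' frames, excluding at each frame the pixels lying under that frame's
#' bumblebee bounding boxes (so the map shows the vegetation, not the
#' bees). Pixels with no contributing frame are \code{NA} (undefined).
#'
#' @param frames list of HSV arrays or accessor function (see
#'   [compute_ofc()]).
#' @param dets a \code{detection_set} giving the boxes to exclude.
#' @param ofc reference colour.
#' @param n_frames frames to sample (default 3000); when more than are
#'   available, all frames are used and a notice is emitted.
#' @param seed RNG seed for the frame sample.
#' @param n_available frame count for function accessors.
#' @param h_period hue period, default 256.
#' @return object of class \code{bee_heatmap}: list with \code{mean}
#'   (height x width, NA where undefined), \code{count} (contributing
#'   frames per pixel), \code{box_count} (times each pixel fell under a
#'   box), \code{frames_sampled}, \code{seed}.
#' @export
build_heatmap <- function(frames, dets, ofc, n_frames = 3000, seed = 1L,
                          n_available = NULL, h_period = 256) {
  acc <- frame_accessor(frames, n_available)
  if (n_frames > acc$n) {
    message(sprintf("requested %d frames but only %d available; using all",
                    n_frames, acc$n))
    n_frames <- acc$n
  }
  idx <- with_seed(seed, sample.int(acc$n, n_frames))
  sum_map <- NULL
  for (i in idx) {
    img <- acc$get(i)
    if (is.null(sum_map)) {
      hw <- dim(img)[1:2]
      sum_map <- matrix(0, hw[1], hw[2])
      cnt_map <- matrix(0L, hw[1], hw[2])
      box_map <- matrix(0L, hw[1], hw[2])
    }
    d <- circular_colour_distance(img, ofc, h_period)
    contrib <- matrix(TRUE, hw[1], hw[2])
    fd <- dets[dets$frame_idx == (i - 1L), , drop = FALSE]
    if (nrow(fd) > 0) {
      for (r in seq_len(nrow(fd))) {
        ii <- rect_to_idx(c(x1 = fd$x1[r], y1 = fd$y1[r],
                            x2 = fd$x2[r], y2 = fd$y2[r]), hw)
        contrib[ii$rows, ii$cols] <- FALSE
        box_map[ii$rows, ii$cols] <- box_map[ii$rows, ii$cols] + 1L
      }
    }
    sum_map[contrib] <- sum_map[contrib] + d[contrib]
    cnt_map <- cnt_map + contrib
  }
  mean_map <- sum_map / cnt_map
  mean_map[cnt_map == 0] <- NA_real_
  structure(list(mean = mean_map, count = cnt_map, box_count = box_map,
                 frames_sampled = idx, seed = seed),
            class = "bee_heatmap")
}

#' @export
print.bee_heatmap <- function(x, ...) {
  cat(sprintf(
    "<bee_heatmap> %d x %d px, %d frames, %d undefined px, mean dist %.3f\n",
    nrow(x$mean), ncol(x$mean), length(x$frames_sampled),
    sum(is.na(x$mean)), mean(x$mean, na.rm = TRUE)))
  invisible(x)
}

#' Sample colour-deviation values from a heatmap
#'
#' Random sample, without replacement, of per-pixel mean distances, either
#' from the whole (defined) map or restricted to pixels that ever lay under
#' a bounding box — the two populations contrasted in the deviation
#' histograms. When fewer than \code{n_points} pixels are available, every
#' available pixel is returned exactly once.
#'
#' @param heatmap a \code{bee_heatmap}.
#' @param region \code{"all"} or \code{"boxes"}.
#' @param n_points sample size cap (default 100000).
#' @param seed RNG seed.
#' @return numeric vector of sampled distances.
#' @export
deviation_histogram <- function(heatmap, region = c("all", "boxes"),
                                n_points = 100000, seed = 1L) {
  region <- match.arg(region)
  ok <- !is.na(heatmap$mean)
  if (region == "boxes") ok <- ok & heatmap$box_count > 0
  vals <- heatmap$mean[ok]
  if (length(vals) == 0) stop("empty region: no defined pixels to sample")
  take <- min(n_points, length(vals))
  keep <- with_seed(seed, sample.int(length(vals), take))
  vals[keep]
}
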