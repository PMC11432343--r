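#' Frame geometry
#'
#' Describes the pixel geometry of a recorded video frame together with the
#' physical calibration: the millimetres-per-pixel scale obtained from a
#' ruler placed in the scene, and the frame rate.
#'
#' Pixel coordinates throughout the package are 0-based and rectangles are
#' half-open, \code{[x1, x2) x [y1, y2)}, so that widths, areas and
#' membership tests are exact integer arithmetic. The scale is assumed
#' isotropic (a single pixel length is calibrated).
#'
#' @param width_px,height_px frame dimensions in pixels (positive integers).
#' @param mm_per_px physical length of one pixel in millimetres (positive).
#' @param fps frames per second (default 30).
#' @return An object of class \code{frame_geometry}.
#' @examples
#' g <- frame_geometry(5120, 2880, mm_per_px = 0.5)
#' @export
frame_geometry <- function(width_px, height_px, mm_per_px, fps = 30) {
  stopifnot(length(width_px) == 1, length(height_px) == 1,
            length(mm_per_px) == 1, length(fps) == 1)
  if (width_px <= 0 || height_px <= 0)
    stop("frame dimensions must be positive")
  if (!is.finite(mm_per_px) || mm_per_px <= 0)
    stop("mm_per_px must be a positive real")
  if (fps <= 0) stop("fps must be positive")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 mm_per_px = as.numeric(mm_per_px),
                 fps = as.numeric(fps)),
            class = "frame_geometry")
}

#' @export
print.frame_geometry <- function(x, ...) {
  cat(sprintf("<frame_geometry> %d x %d px, %.6g mm/px, %g fps\n",
              x$width_px, x$height_px, x$mm_per_px, x$fps))
  invisible(x)
}

#' Calibrate the pixel scale from a reference scale bar
#'
#' A millimetre-precision scale photographed in the scene gives the physical
#' length of one pixel as \code{scalebar_length_mm / scalebar_length_px}.
#'
#' @param scalebar_length_px measured length of the scale bar in pixels.
#' @param scalebar_length_mm physical length of the scale bar in millimetres.
#' @return mm-per-pixel scale (positive numeric scalar).
#' @examples
#' calibrate_scale(200, 100) # 0.5 mm/px
#' @export
calibrate_scale <- function(scalebar_length_px, scalebar_length_mm) {
  if (!is.numeric(scalebar_length_px) || !is.numeric(scalebar_length_mm) ||
      length(scalebar_length_px) != 1 || length(scalebar_length_mm) != 1 ||
      !is.finite(scalebar_length_px) || !is.finite(scalebar_length_mm) ||
      scalebar_length_px <= 0 || scalebar_length_mm <= 0)
    stop("invalid calibration: scale-bar lengths must be positive finite scalars")
  scalebar_length_mm / scalebar_length_px
}

#' Number of frames in a time slice
#'
#' @param geometry a \code{frame_geometry} (its \code{fps} is used).
#' @param seconds duration in seconds.
#' @return integer frame count \code{round(seconds * fps)}.
#' @examples
#' frames_for_duration(frame_geometry(640, 640, 1), 3) # 90 at 30 fps
#' @export
frames_for_duration <- function(geometry, seconds) {
  stopifnot(inherits(geometry, "frame_geometry"), seconds >= 0)
  as.integer(round(seconds * geometry$fps))
}

#' Tile grid for sliced inference
#'
#' Detectors for small objects in large frames run on square tiles. The frame
#' is padded (right/bottom only, conceptually with black) to the smallest
#' multiple of the tile side, then cut into non-overlapping tiles.
#'
#' @param geometry a \code{frame_geometry}.
#' @param tile_px tile side in pixels (default 640).
#' @return An object of class \code{tile_grid} with fields \code{tile_px},
#'   \code{padded_width_px}, \code{padded_height_px}, \code{n_cols},
#'   \code{n_rows}.
#' @examples
#' make_tile_grid(frame_geometry(5120, 2880, 1)) # 8 x 5 = 40 tiles
#' @export
make_tile_grid <- function(geometry, tile_px = 640L) {
  stopifnot(inherits(geometry, "frame_geometry"))
  if (tile_px <= 0) stop("tile_px must be positive")
  tile_px <- as.integer(tile_px)
  pw <- as.integer(ceiling(geometry$width_px / tile_px) * tile_px)
  ph <- as.integer(ceiling(geometry$height_px / tile_px) * tile_px)
  structure(list(tile_px = tile_px,
                 padded_width_px = pw, padded_height_px = ph,
                 n_cols = pw %/% tile_px, n_rows = ph %/% tile_px),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d px tiles, padded %d x %d, %d cols x %d rows\n",
              x$tile_px, x$padded_width_px, x$padded_height_px,
              x$n_cols, x$n_rows))
  invisible(x)
}

#' Pixel rectangle constructor
#'
#' Half-open axis-aligned rectangle \code{[x1, x2) x [y1, y2)} in 0-based
#' pixel coordinates.
#'
#' @param x1,y1 top-left corner.
#' @param x2,y2 exclusive bottom-right corner.
#' @return named numeric vector \code{c(x1, y1, x2, y2)}.
#' @export
px_rect <- function(x1, y1, x2, y2) {
  if (x2 <= x1 || y2 <= y1) stop("rectangle must have positive area")
  c(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

#' Centroid of a pixel rectangle
#' @param box rectangle as from [px_rect()].
#' @return numeric \code{c(x, y)}.
#' @export
box_centroid <- function(box) {
  c(x = (box[["x1"]] + box[["x2"]]) / 2, y = (box[["y1"]] + box[["y2"]]) / 2)
}

#' Map a tile-local box to frame coordinates
#'
#' Inverse of the tiling: a detection reported inside tile (row, col) is
#' offset by the tile origin. Tile indices are 0-based.
#'
#' @param box rectangle in tile-local coordinates.
#' @param tile_row,tile_col 0-based tile indices.
#' @param grid a \code{tile_grid}.
#' @return rectangle in (padded) frame coordinates.
#' @export
tile_box_to_frame <- function(box, tile_row, tile_col, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  if (tile_row < 0 || tile_row >= grid$n_rows ||
      tile_col < 0 || tile_col >= grid$n_cols)
    stop(sprintf("tile index (%d, %d) outside %d x %d grid",
                 tile_row, tile_col, grid$n_rows, grid$n_cols))
  t <- grid$tile_px
  if (box[["x1"]] < 0 || box[["y1"]] < 0 || box[["x2"]] > t || box[["y2"]] > t)
    stop("box lies outside tile bounds")
  px_rect(box[["x1"]] + tile_col * t, box[["y1"]] + tile_row * t,
          box[["x2"]] + tile_col * t, box[["y2"]] + tile_row * t)
}

#' Map a frame box fully inside one tile to tile-local coordinates
#'
#' @param box rectangle in frame coordinates, fully contained in one tile.
#' @param grid a \code{tile_grid}.
#' @return list with \code{box} (tile-local), \code{tile_row}, \code{tile_col}.
#' @export
frame_box_to_tile <- function(box, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  t <- grid$tile_px
  col <- floor(box[["x1"]] / t)
  row <- floor(box[["y1"]] / t)
  if (box[["x2"]] > (col + 1) * t || box[["y2"]] > (row + 1) * t)
    stop("box spans more than one tile")
  if (col >= grid$n_cols || row >= grid$n_rows)
    stop("box lies outside the padded frame")
  list(box = px_rect(box[["x1"]] - col * t, box[["y1"]] - row * t,
                     box[["x2"]] - col * t, box[["y2"]] - row * t),
       tile_row = as.integer(row), tile_col = as.integer(col))
}

#' Quadrat placement
#'
#' The physical analysis square (60 x 60 cm by default) is delimited
#' digitally: its upper-left corner is identified in the frame and the side
#' length in pixels follows from the mm/px calibration.
#'
#' @param corner_x_px,corner_y_px pixel coordinates of the upper-left corner.
#' @param side_mm physical side length in millimetres (default 600).
#' @return An object of class \code{quadrat_spec}.
#' @export
quadrat_spec <- function(corner_x_px, corner_y_px, side_mm = 600) {
  if (side_mm <= 0) stop("side_mm must be positive")
  structure(list(corner_x_px = corner_x_px, corner_y_px = corner_y_px,
                 side_mm = side_mm),
            class = "quadrat_spec")
}

#' Quadrat rectangle in pixel coordinates
#'
#' @param q a \code{quadrat_spec}.
#' @param g a \code{frame_geometry} supplying \code{mm_per_px} and frame
#'   bounds. Pass a geometry with padded dimensions to allow the quadrat to
#'   extend into padding.
#' @return half-open pixel rectangle with side \code{round(side_mm / mm_per_px)}.
#' @export
quadrat_rect <- function(q, g) {
  stopifnot(inherits(q, "quadrat_spec"), inherits(g, "frame_geometry"))
  side_px <- round(q$side_mm / g$mm_per_px)
  r <- px_rect(q$corner_x_px, q$corner_y_px,
               q$corner_x_px + side_px, q$corner_y_px + side_px)
  over_x <- r[["x2"]] - g$width_px
  over_y <- r[["y2"]] - g$height_px
  if (r[["x1"]] < 0 || r[["y1"]] < 0 || over_x > 0 || over_y > 0)
    stop(sprintf(
      "quadrat exceeds frame bounds (overflow right %g px, bottom %g px)",
      max(over_x, 0), max(over_y, 0)))
  r
}

#' Is a box centroid inside a rectangle?
#'
#' Membership uses the half-open convention: the near (top/left) edges are
#' included, the far (bottom/right) edges excluded.
#'
#' @param box detection rectangle.
#' @param rect reference rectangle (e.g. from [quadrat_rect()]).
#' @return logical scalar.
#' @export
centroid_in_quadrat <- function(box, rect) {
  ctr <- box_centroid(box)
  ctr[["x"]] >= rect[["x1"]] && ctr[["x"]] < rect[["x2"]] &&
    ctr[["y"]] >= rect[["y1"]] && ctr[["y"]] < rect[["y2"]]
}
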