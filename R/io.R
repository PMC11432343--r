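#' Read and write detection CSV
#'
#' The CSV dialect has a header \code{frame_idx,x1,y1,x2,y2,confidence,label}
#' (an optional \code{source} column is preserved). Writing then reading a
#' detection set reproduces it exactly.
#'
#' @param path file path.
#' @param video_id,species provenance attached to the result.
#' @return a \code{detection_set}.
#' @export
read_detections_csv <- function(path, video_id = NA_character_,
                                species = NA_character_) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_detection_set(d, video_id = video_id, species = species)
}

#' @rdname read_detections_csv
#' @param dets a \code{detection_set}.
#' @export
write_detections_csv <- function(dets, path) {
  utils::write.csv(as.data.frame(dets), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read YOLO-style detection text files
#'
#' One whitespace-delimited file per frame with rows
#' \code{class cx cy w h confidence}, coordinates normalised to the image
#' size. The frame index is parsed from the trailing digits of the file
#' name (e.g. \code{frame_000017.txt} is frame 17).
#'
#' @param paths character vector of per-frame files.
#' @param width_px,height_px image dimensions used to de-normalise.
#' @param label class label to assign.
#' @return a \code{detection_set} with half-open pixel boxes.
#' @export
read_yolo_detections <- function(paths, width_px, height_px,
                                 label = "bumblebee") {
  rows <- lapply(paths, function(p) {
    idx <- frame_index_from_name(p)
    tab <- tryCatch(utils::read.table(p), error = function(e) NULL)
    if (is.null(tab) || nrow(tab) == 0) return(NULL)
    if (ncol(tab) < 6)
      stop("expected 6 columns (class cx cy w h conf) in ", p)
    data.frame(frame_idx = idx,
               x1 = (tab[[2]] - tab[[4]] / 2) * width_px,
               y1 = (tab[[3]] - tab[[5]] / 2) * height_px,
               x2 = (tab[[2]] + tab[[4]] / 2) * width_px,
               y2 = (tab[[3]] + tab[[5]] / 2) * height_px,
               confidence = tab[[6]])
  })
  d <- do.call(rbind, rows)
  if (is.null(d))
    return(detection_set())
  detection_set(d$frame_idx, d$x1, d$y1, d$x2, d$y2, d$confidence,
                label = label)
}

#' Parse a frame index from a file name
#'
#' The last run of digits in the base name (extension stripped) is the
#' 0-based frame index.
#'
#' @param path file path or name.
#' @return integer frame index.
#' @export
frame_index_from_name <- function(path) {
  base <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  m <- regmatches(base, gregexpr("[0-9]+", base))[[1]]
  if (length(m) == 0) stop("no frame index found in name: ", path)
  as.integer(m[length(m)])
}

#' Read a calibration record
#'
#' JSON with fields \code{scalebar_px}, \code{scalebar_mm},
#' \code{quadrat_corner_xy} (length-2), and optional \code{side_mm}
#' (default 600) and \code{fps} (default 30).
#'
#' @param path JSON file path.
#' @return list with \code{mm_per_px}, \code{quadrat} (a
#'   \code{quadrat_spec}) and \code{fps}.
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("scalebar_px", "scalebar_mm", "quadrat_corner_xy"))
    if (is.null(j[[f]])) stop("calibration record missing field: ", f)
  mm <- calibrate_scale(j$scalebar_px, j$scalebar_mm)
  side <- if (is.null(j$side_mm)) 600 else j$side_mm
  list(mm_per_px = mm,
       quadrat = quadrat_spec(j$quadrat_corner_xy[1], j$quadrat_corner_xy[2],
                              side),
       fps = if (is.null(j$fps)) 30 else j$fps)
}

#' Read and write colour-band configuration
#'
#' JSON mapping species to \code{{lower: [h,s,b], upper: [h,s,b],
#' inverted_channels: [...]}} (\code{inverted_channels} optional, 1-based
#' channel indices; by default channels with lower > upper are inverted).
#'
#' @param path JSON file path.
#' @return named list of \code{colour_band}s.
#' @export
read_colour_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(j), function(sp) {
    e <- j[[sp]]
    inv <- NULL
    if (!is.null(e$inverted_channels)) {
      inv <- rep(FALSE, 3)
      inv[unlist(e$inverted_channels)] <- TRUE
    }
    colour_band(e$lower, e$upper, species = sp, inverted = inv)
  })
  names(out) <- names(j)
  out
}

#' @rdname read_colour_config
#' @param bands named list of \code{colour_band}s.
#' @export
write_colour_config <- function(bands, path) {
  j <- lapply(bands, function(b)
    list(lower = b$lower, upper = b$upper,
         inverted_channels = which(b$inverted)))
  jsonlite::write_json(j, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Convert between RGB and the internal HSV scale
#'
#' RGB arrays (values 0-255 or 0-1) map to HSV arrays on the internal
#' 0-255 scale (hue period 256) and back. Conversion uses
#' \code{grDevices::rgb2hsv}; this is the only place an external colour
#' convention enters.
#'
#' @param rgb array (height, width, 3), values in \[0, 255\] (or \[0, 1\]
#'   with \code{max = 1}).
#' @param max maximum RGB channel value (default 255).
#' @return HSV array on the 0-255 scale.
#' @export
rgb_to_hsv255 <- function(rgb, max = 255) {
  hw <- dim(rgb)[1:2]
  m <- grDevices::rgb2hsv(r = as.vector(rgb[, , 1]),
                          g = as.vector(rgb[, , 2]),
                          b = as.vector(rgb[, , 3]), maxColorValue = max)
  out <- array(0, dim = c(hw, 3))
  out[, , 1] <- matrix(m["h", ] * 255, hw[1], hw[2])
  out[, , 2] <- matrix(m["s", ] * 255, hw[1], hw[2])
  out[, , 3] <- matrix(m["v", ] * 255, hw[1], hw[2])
  out
}

#' @rdname rgb_to_hsv255
#' @param hsv HSV array on the 0-255 scale.
#' @return RGB array with values in \[0, 255\].
#' @export
hsv255_to_rgb <- function(hsv) {
  hw <- dim(hsv)[1:2]
  cols <- grDevices::hsv(pmin(as.vector(hsv[, , 1]) / 255, 1),
                         pmin(as.vector(hsv[, , 2]) / 255, 1),
                         pmin(as.vector(hsv[, , 3]) / 255, 1))
  m <- grDevices::col2rgb(cols)
  out <- array(0, dim = c(hw, 3))
  for (k in 1:3) out[, , k] <- matrix(m[k, ], hw[1], hw[2])
  out
}

#' Read and write plain-text PPM (P3) raster files
#'
#' PPM is the plain-text raster interchange format used for frame files
#' (no binary image readers are assumed). \code{read_frame_ppm} returns the
#' frame already converted to the internal HSV scale.
#'
#' @param path file path.
#' @return \code{read_ppm}: RGB array (height, width, 3), 0-255;
#'   \code{read_frame_ppm}: HSV array on the internal scale.
#' @export
read_ppm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P3") stop("only plain-text PPM (P3) is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxv <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != 3 * w * h) stop("truncated PPM payload")
  px <- matrix(vals, nrow = 3) # channel-fastest, row-major pixels
  out <- array(0, dim = c(h, w, 3))
  for (k in 1:3)
    out[, , k] <- matrix(px[k, ], h, w, byrow = TRUE) * (255 / maxv)
  out
}

#' @rdname read_ppm
#' @param rgb RGB array (height, width, 3), values 0-255.
#' @export
write_ppm <- function(rgb, path) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  vals <- integer(3 * w * h)
  for (k in 1:3)
    vals[seq(k, by = 3, length.out = w * h)] <-
      as.integer(round(t(rgb[, , k])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}

#' @rdname read_ppm
#' @export
read_frame_ppm <- function(path) {
  rgb_to_hsv255(read_ppm(path))
}

#' Training-image manifest and video frame counts
#'
#' Small reference tables shipped with the package: the per-species
#' training/validation/test image manifest of the detector datasets, and
#' the per-species recorded frame and video counts of the field campaign.
#'
#' @return data frame.
#' @export
training_manifest <- function() {
  utils::read.csv(system.file("extdata", "training_manifest.csv",
                              package = "beeforage"),
                  stringsAsFactors = FALSE)
}

#' @rdname training_manifest
#' @export
video_frame_counts <- function() {
  utils::read.csv(system.file("extdata", "video_frame_counts.csv",
                              package = "beeforage"),
                  stringsAsFactors = FALSE)
}
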