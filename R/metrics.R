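#' Patch attractiveness
#'
#' Total detections in a video divided by the total number of frames,
#' bee-free frames included: a per-frame mean visitation intensity.
#'
#' @param counts integer vector of per-frame detection counts.
#' @return non-negative real.
#' @export
attractiveness <- function(counts) {
  if (length(counts) == 0) stop("counts vector is empty")
  sum(counts) / length(counts)
}

#' Cover-standardised carrying capacity
#'
#' Mean simultaneous bee count conditioned on presence (total detections
#' divided by the number of frames with at least one bee), standardised by
#' the percent flower cover of the patch.
#'
#' @param counts integer vector of per-frame detection counts.
#' @param cover_pct flower cover as a percentage (0-100), must be positive.
#' @return non-negative real, or \code{NA_real_} (undefined) when no frame
#'   contains a bee.
#' @export
carrying_capacity <- function(counts, cover_pct) {
  if (length(counts) == 0) stop("counts vector is empty")
  if (cover_pct <= 0) stop("cover_pct must be positive")
  present <- sum(counts > 0)
  if (present == 0) return(NA_real_)
  (sum(counts) / present) / cover_pct
}

#' Simultaneity statistics
#'
#' Maximum simultaneous count over all frames, and the mean count over
#' frames with at least one bee (which is therefore >= 1 when defined).
#'
#' @param counts integer vector of per-frame detection counts.
#' @return list with \code{max} and \code{mean} (NA when no bee frame).
#' @export
simultaneity_stats <- function(counts) {
  if (length(counts) == 0) stop("counts vector is empty")
  present <- counts[counts > 0]
  list(max = max(counts),
       mean = if (length(present) == 0) NA_real_ else mean(present))
}

#' Classify a detection as on- or off-flower
#'
#' The bee hides the vegetation beneath it, so the box region is inspected
#' in a \emph{reference} frame: the nearest frame in time (earlier preferred
#' on ties, search window configurable) in which no detection's box
#' intersects the query region. The species colour band is applied to the
#' region; if the flower-pixel fraction reaches the threshold (20%,
#' inclusive) the bee is called on-flower.
#'
#' @param det one-row \code{detection_set} (or list with \code{frame_idx},
#'   \code{x1,y1,x2,y2}).
#' @param frames list of HSV arrays or accessor function.
#' @param dets full \code{detection_set} of the video (used to find a
#'   bee-free view of the region).
#' @param band species \code{colour_band}.
#' @param threshold on-flower fraction threshold, default 0.20 (inclusive).
#' @param search_window maximum frame distance searched for a reference
#'   frame; default \code{Inf} (whole video).
#' @param n_available frame count for function accessors.
#' @return list of class \code{on_flower_call}: \code{flower_pixel_fraction},
#'   \code{on_flower}, \code{reference_frame_idx} (0-based), and
#'   \code{resolved}. Unresolved calls (no bee-free reference frame in the
#'   window) have \code{resolved = FALSE} and NA fields.
#' @export
classify_on_flower <- function(det, frames, dets, band, threshold = 0.20,
                               search_window = Inf, n_available = NULL) {
  acc <- frame_accessor(frames, n_available)
  box <- c(x1 = det$x1[1], y1 = det$y1[1], x2 = det$x2[1], y2 = det$y2[1])
  qidx <- det$frame_idx[1]
  ref <- find_reference_frame(box, qidx, dets, acc$n, search_window)
  if (is.na(ref))
    return(structure(list(flower_pixel_fraction = NA_real_,
                          on_flower = NA, reference_frame_idx = NA_integer_,
                          resolved = FALSE),
                     class = "on_flower_call"))
  img <- acc$get(ref + 1L)
  idx <- rect_to_idx(box, dim(img))
  region <- img[idx$rows, idx$cols, , drop = FALSE]
  frac <- mean(band_mask(region, band))
  structure(list(flower_pixel_fraction = frac,
                 on_flower = frac >= threshold,
                 reference_frame_idx = as.integer(ref),
                 resolved = TRUE),
            class = "on_flower_call")
}

boxes_intersect <- function(a, b) {
  a[["x1"]] < b[["x2"]] && b[["x1"]] < a[["x2"]] &&
    a[["y1"]] < b[["y2"]] && b[["y1"]] < a[["y2"]]
}

# nearest frame (0-based) with no detection intersecting `box`;
# earlier preferred on ties; NA if none within the window
find_reference_frame <- function(box, query_idx, dets, n_frames,
                                 search_window = Inf) {
  max_off <- min(search_window, n_frames - 1)
  for (off in seq_len(max_off + 1) - 1) {
    for (cand in unique(c(query_idx - off, query_idx + off))) {
      if (cand < 0 || cand >= n_frames || cand == query_idx) next
      fd <- dets[dets$frame_idx == cand, , drop = FALSE]
      clear <- TRUE
      for (r in seq_len(nrow(fd))) {
        other <- c(x1 = fd$x1[r], y1 = fd$y1[r], x2 = fd$x2[r], y2 = fd$y2[r])
        if (boxes_intersect(box, other)) { clear <- FALSE; break }
      }
      if (clear) return(cand)
    }
  }
  NA_integer_
}

#' Classify every detection of a set
#'
#' @inheritParams classify_on_flower
#' @return data frame with one row per detection: the detection columns plus
#'   \code{flower_pixel_fraction}, \code{on_flower},
#'   \code{reference_frame_idx}, \code{resolved}.
#' @export
classify_all_on_flower <- function(dets, frames, band, threshold = 0.20,
                                   search_window = Inf, n_available = NULL) {
  calls <- lapply(seq_len(nrow(dets)), function(r)
    classify_on_flower(dets[r, , drop = FALSE], frames, dets, band,
                       threshold, search_window, n_available))
  cbind(as.data.frame(dets),
        flower_pixel_fraction = vapply(calls, `[[`, 0, "flower_pixel_fraction"),
        on_flower = vapply(calls, `[[`, NA, "on_flower"),
        reference_frame_idx = vapply(calls, `[[`, 0L, "reference_frame_idx"),
        resolved = vapply(calls, `[[`, NA, "resolved"))
}

#' On-flower time budget
#'
#' Proportion of cumulative bumblebee-time (detection x frame units) spent
#' on inflorescences, among resolved calls. Unresolved calls are excluded,
#' not imputed; their count is reported.
#'
#' @param calls data frame with logical columns \code{on_flower} and
#'   \code{resolved} (as from [classify_all_on_flower()]).
#' @return list with \code{pct_on_flower}, \code{pct_off_flower} (both NA
#'   when nothing resolved), \code{n_resolved}, \code{n_unresolved}.
#' @export
time_budget <- function(calls) {
  res <- calls$resolved %in% TRUE
  n_res <- sum(res)
  if (n_res == 0)
    return(list(pct_on_flower = NA_real_, pct_off_flower = NA_real_,
                n_resolved = 0L, n_unresolved = nrow(calls)))
  pct_on <- 100 * sum(calls$on_flower[res]) / n_res
  list(pct_on_flower = pct_on, pct_off_flower = 100 - pct_on,
       n_resolved = as.integer(n_res),
       n_unresolved = as.integer(nrow(calls) - n_res))
}

#' Per-video behavioural metrics
#'
#' Assembles the full metrics row for one video from its (post-processed)
#' detections: attractiveness, cover-standardised carrying capacity,
#' simultaneity statistics, and optionally the on-flower time budget.
#'
#' @param dets post-processed \code{detection_set} (confidence-filtered,
#'   merged, quadrat-clipped).
#' @param n_frames total frames in the video.
#' @param cover_pct percent flower cover of the quadrat.
#' @param calls optional on-flower call table from
#'   [classify_all_on_flower()].
#' @param video_id,species provenance (defaults from the detection set).
#' @return one-row data frame with the video metrics.
#' @export
video_metrics <- function(dets, n_frames, cover_pct, calls = NULL,
                          video_id = attr(dets, "video_id"),
                          species = attr(dets, "species")) {
  if (is.null(video_id)) video_id <- NA_character_
  if (is.null(species)) species <- NA_character_
  counts <- counts_per_frame(dets, n_frames)
  sim <- simultaneity_stats(counts)
  tb <- if (is.null(calls))
    list(pct_on_flower = NA_real_, pct_off_flower = NA_real_,
         n_resolved = NA_integer_, n_unresolved = NA_integer_)
  else time_budget(calls)
  data.frame(video_id = video_id, species = species,
             n_frames = as.integer(n_frames),
             total_detections = sum(counts),
             frames_with_bees = sum(counts > 0),
             attractiveness = attractiveness(counts),
             carrying_capacity = carrying_capacity(counts, cover_pct),
             flower_cover_pct = cover_pct,
             pct_time_on_flower = tb$pct_on_flower,
             max_simultaneous = sim$max,
             mean_simultaneous = sim$mean,
             n_unresolved_calls = tb$n_unresolved,
             stringsAsFactors = FALSE)
}
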