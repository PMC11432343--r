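#' Detection sets
#'
#' A detection set is a data frame of per-frame bounding boxes with columns
#' \code{frame_idx} (0-based integer), \code{x1, y1, x2, y2} (half-open pixel
#' rectangle), \code{confidence} (in \[0, 1\]), \code{label} and
#' \code{source} (\code{"raw"} or \code{"merged"}), carrying provenance
#' attributes (\code{video_id}, \code{species}).
#'
#' @param frame_idx integer vector of 0-based frame indices.
#' @param x1,y1,x2,y2 box corners in pixels.
#' @param confidence detector confidences in \[0, 1\].
#' @param label class label (recycled), default \code{"bumblebee"}.
#' @param source provenance flag (recycled), \code{"raw"} or \code{"merged"}.
#' @param video_id,species optional provenance metadata.
#' @return A data frame of class \code{detection_set}.
#' @export
detection_set <- function(frame_idx = integer(), x1 = numeric(),
                          y1 = numeric(), x2 = numeric(), y2 = numeric(),
                          confidence = numeric(), label = "bumblebee",
                          source = "raw", video_id = NA_character_,
                          species = NA_character_) {
  n <- length(frame_idx)
  stopifnot(length(x1) == n, length(y1) == n, length(x2) == n,
            length(y2) == n, length(confidence) == n)
  if (n > 0) {
    if (any(frame_idx < 0)) stop("frame indices must be non-negative")
    if (any(x2 <= x1) || any(y2 <= y1)) stop("boxes must have positive area")
    if (any(confidence < 0 | confidence > 1))
      stop("confidence must lie in [0, 1]")
  }
  d <- data.frame(frame_idx = as.integer(frame_idx),
                  x1 = as.numeric(x1), y1 = as.numeric(y1),
                  x2 = as.numeric(x2), y2 = as.numeric(y2),
                  confidence = as.numeric(confidence),
                  label = rep_len(as.character(label), n),
                  source = rep_len(as.character(source), n),
                  stringsAsFactors = FALSE)
  as_detection_set(d, video_id = video_id, species = species)
}

#' @rdname detection_set
#' @param d a data frame with the detection-set columns.
#' @export
as_detection_set <- function(d, video_id = NA_character_,
                             species = NA_character_) {
  needed <- c("frame_idx", "x1", "y1", "x2", "y2", "confidence")
  if (!all(needed %in% names(d)))
    stop("missing detection columns: ",
         paste(setdiff(needed, names(d)), collapse = ", "))
  if (is.null(d$label)) d$label <- "bumblebee"
  if (is.null(d$source)) d$source <- "raw"
  d$frame_idx <- as.integer(d$frame_idx)
  class(d) <- c("detection_set", "data.frame")
  attr(d, "video_id") <- video_id
  attr(d, "species") <- species
  d
}

# keep the class when subsetting rows
#' @export
`[.detection_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    class(out) <- c("detection_set", "data.frame")
    attr(out, "video_id") <- attr(x, "video_id")
    attr(out, "species") <- attr(x, "species")
  }
  out
}

det_centroids <- function(d) {
  cbind(x = (d$x1 + d$x2) / 2, y = (d$y1 + d$y2) / 2)
}

#' Filter detections by confidence
#'
#' Keeps detections whose confidence is greater than or equal to the
#' threshold (inclusive). The thresholds used in practice are species
#' specific: 0.7 for red clover, 0.8 for trefoil and knotweed
#' (see [species_conf_thresholds()]).
#'
#' @param dets a \code{detection_set}.
#' @param threshold confidence threshold in \[0, 1\].
#' @return the filtered \code{detection_set}, rows unaltered.
#' @export
filter_confidence <- function(dets, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  dets[dets$confidence >= threshold, , drop = FALSE]
}

#' Default per-species confidence thresholds
#'
#' @return named numeric vector of detector confidence cut-offs.
#' @export
species_conf_thresholds <- function() {
  c(lotus = 0.8, persicaria = 0.8, trifolium = 0.7)
}

#' Merge duplicate bounding boxes within a frame
#'
#' Tiled inference detects one bee several times when its body straddles a
#' tile seam. Boxes whose centroid-to-centroid Euclidean distance is at most
#' \code{merge_dist_px} are linked; each connected component (transitive
#' closure, so the result is independent of input order) is replaced by a
#' single box: the smallest rectangle containing all members, with the
#' maximum member confidence and \code{source = "merged"}.
#'
#' The field default for \code{merge_dist_px} is half an average bumblebee
#' body (15 mm) divided by the mm/px scale; see [merge_distance_px()].
#'
#' @param frame_dets a \code{detection_set} whose rows all share one
#'   \code{frame_idx}.
#' @param merge_dist_px linking distance in pixels (positive).
#' @return a \code{detection_set} of merged boxes, ordered by (x1, y1).
#' @export
merge_boxes <- function(frame_dets, merge_dist_px) {
  if (!is.numeric(merge_dist_px) || length(merge_dist_px) != 1 ||
      !is.finite(merge_dist_px) || merge_dist_px <= 0)
    stop("merge_dist_px must be a positive real")
  n <- nrow(frame_dets)
  if (n == 0) return(frame_dets)
  if (length(unique(frame_dets$frame_idx)) != 1)
    stop("merge_boxes operates on a single frame; split by frame_idx first")
  comp <- if (n == 1) 1L else {
    ctr <- det_centroids(frame_dets)
    adj <- as.matrix(stats::dist(ctr)) <= merge_dist_px
    # connected components by breadth-first flooding
    lab <- integer(n)
    cur <- 0L
    for (i in seq_len(n)) {
      if (lab[i] > 0L) next
      cur <- cur + 1L
      queue <- i
      lab[i] <- cur
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(adj[v, ] & lab == 0L)
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    lab
  }
  merged <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
    m <- frame_dets[idx, , drop = FALSE]
    data.frame(frame_idx = m$frame_idx[1],
               x1 = min(m$x1), y1 = min(m$y1),
               x2 = max(m$x2), y2 = max(m$y2),
               confidence = max(m$confidence),
               label = m$label[1], source = "merged",
               stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$x1, merged$y1, merged$x2, merged$y2), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  as_detection_set(merged, video_id = attr(frame_dets, "video_id"),
                   species = attr(frame_dets, "species"))
}

#' Merge duplicate boxes in every frame of a detection set
#'
#' @param dets a \code{detection_set} (any number of frames).
#' @param merge_dist_px linking distance in pixels.
#' @return merged \code{detection_set}, frames in ascending order.
#' @export
merge_boxes_all <- function(dets, merge_dist_px) {
  if (nrow(dets) == 0) return(dets)
  parts <- lapply(split(seq_len(nrow(dets)), dets$frame_idx),
                  function(idx) merge_boxes(dets[idx, , drop = FALSE],
                                            merge_dist_px))
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  as_detection_set(out, video_id = attr(dets, "video_id"),
                   species = attr(dets, "species"))
}

#' Duplicate-merging distance in pixels
#'
#' Half an average bumblebee body (15 mm) converted to pixels.
#'
#' @param mm_per_px calibrated pixel scale.
#' @param half_body_mm physical linking distance, default 15 mm.
#' @return distance in pixels.
#' @export
merge_distance_px <- function(mm_per_px, half_body_mm = 15) {
  if (mm_per_px <= 0) stop("mm_per_px must be positive")
  half_body_mm / mm_per_px
}

#' Keep detections whose centroid lies in the quadrat
#'
#' Boxes are not cropped; a detection is kept or dropped as a whole based on
#' the half-open centroid membership test ([centroid_in_quadrat()]).
#'
#' @param dets a \code{detection_set}.
#' @param rect quadrat rectangle (from [quadrat_rect()]).
#' @return filtered \code{detection_set}.
#' @export
clip_to_quadrat <- function(dets, rect) {
  if (nrow(dets) == 0) return(dets)
  ctr <- det_centroids(dets)
  keep <- ctr[, "x"] >= rect[["x1"]] & ctr[, "x"] < rect[["x2"]] &
    ctr[, "y"] >= rect[["y1"]] & ctr[, "y"] < rect[["y2"]]
  dets[keep, , drop = FALSE]
}

#' Match predictions to manual annotations and score F1
#'
#' Greedy one-to-one matching by ascending centroid distance: the closest
#' unmatched (prediction, truth) pair is matched while their distance is at
#' most \code{match_dist_px}. F1 is computed by the standard formula
#' \deqn{F1 = 2 TP / (2 TP + FP + FN).}
#' Empty truth and empty prediction give F1 = 1 (no errors present).
#'
#' @param pred,truth \code{detection_set}s (or data frames) sharing a frame.
#' @param match_dist_px maximum centroid distance for a match; the natural
#'   default is the duplicate-merge distance ([merge_distance_px()]).
#' @return list of class \code{match_result} with \code{TP}, \code{FP},
#'   \code{FN}, \code{f1} and a \code{pairs} data frame
#'   (\code{pred_row}, \code{truth_row}, \code{dist}).
#' @export
match_and_score <- function(pred, truth, match_dist_px) {
  if (match_dist_px <= 0) stop("match_dist_px must be positive")
  np <- nrow(pred); nt <- nrow(truth)
  pairs <- data.frame(pred_row = integer(), truth_row = integer(),
                      dist = numeric())
  if (np > 0 && nt > 0) {
    pc <- det_centroids(pred); tc <- det_centroids(truth)
    dmat <- sqrt(outer(pc[, "x"], tc[, "x"], "-")^2 +
                 outer(pc[, "y"], tc[, "y"], "-")^2)
    free_p <- rep(TRUE, np); free_t <- rep(TRUE, nt)
    repeat {
      dmat_free <- dmat
      dmat_free[!free_p, ] <- Inf
      dmat_free[, !free_t] <- Inf
      m <- min(dmat_free)
      if (!is.finite(m) || m > match_dist_px) break
      ij <- which(dmat_free == m, arr.ind = TRUE)[1, ]
      pairs <- rbind(pairs, data.frame(pred_row = ij[[1]],
                                       truth_row = ij[[2]], dist = m))
      free_p[ij[[1]]] <- FALSE
      free_t[ij[[2]]] <- FALSE
    }
  }
  tp <- nrow(pairs)
  res <- list(TP = tp, FP = np - tp, FN = nt - tp, pairs = pairs)
  res$f1 <- f1_score(res$TP, res$FP, res$FN)
  class(res) <- "match_result"
  res
}

#' F1 score from error counts
#'
#' @param TP,FP,FN non-negative counts of true positives, false positives
#'   and false negatives.
#' @return \code{2*TP / (2*TP + FP + FN)}; defined as 1 when all three are 0.
#' @export
f1_score <- function(TP, FP, FN) {
  if (TP < 0 || FP < 0 || FN < 0) stop("counts must be non-negative")
  denom <- 2 * TP + FP + FN
  if (denom == 0) return(1)
  2 * TP / denom
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP=%d FP=%d FN=%d F1=%.4f\n",
              x$TP, x$FP, x$FN, x$f1))
  invisible(x)
}

#' Per-frame detection counts
#'
#' @param dets a \code{detection_set}.
#' @param n_frames total number of frames in the video.
#' @return integer vector of length \code{n_frames}; element \code{t + 1} is
#'   the number of detections in (0-based) frame \code{t}.
#' @export
counts_per_frame <- function(dets, n_frames) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1) stop("n_frames must be at least 1")
  if (nrow(dets) > 0 && max(dets$frame_idx) >= n_frames)
    stop(sprintf("frame index %d outside 0..%d",
                 max(dets$frame_idx), n_frames - 1L))
  tabulate(dets$frame_idx + 1L, nbins = n_frames)
}
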