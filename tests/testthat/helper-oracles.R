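# Shared fixtures and independent brute-force oracles.

test_geometry <- function(side = 200, quad_side_px = 180)
  frame_geometry(side, side, mm_per_px = 600 / quad_side_px)

test_quadrat <- function(corner = 10) quadrat_spec(corner, corner, 600)

# brute-force union-find over all pairs (path compression, repeated unions)
uf_merge_oracle <- function(frame_dets, merge_dist_px) {
  n <- nrow(frame_dets)
  if (n == 0) return(frame_dets)
  cx <- (frame_dets$x1 + frame_dets$x2) / 2
  cy <- (frame_dets$y1 + frame_dets$y2) / 2
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2) <= merge_dist_px)
      parent[find(i)] <- find(j)
  }
  comp <- vapply(seq_len(n), find, 0L)
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
    m <- frame_dets[idx, , drop = FALSE]
    data.frame(frame_idx = m$frame_idx[1],
               x1 = min(m$x1), y1 = min(m$y1),
               x2 = max(m$x2), y2 = max(m$y2),
               confidence = max(m$confidence))
  }))
  out <- out[order(out$x1, out$y1, out$x2, out$y2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_frame_dets <- function(n_boxes, extent = 500, box_max = 40) {
  x1 <- runif(n_boxes, 0, extent)
  y1 <- runif(n_boxes, 0, extent)
  w <- runif(n_boxes, 2, box_max)
  h <- runif(n_boxes, 2, box_max)
  detection_set(rep(0L, n_boxes), x1, y1, x1 + w, y1 + h,
                confidence = runif(n_boxes))
}

# uniform random image with channels in [0, 255]
random_hsv_image <- function(h, w) {
  array(runif(h * w * 3, 0, 255), dim = c(h, w, 3))
}

# a small scene + stream pair used across metric tests
small_world <- function(seed = 11, n_frames = 200, lambda = 0.4,
                        p_on = 0.6, dup_rate = 0.3,
                        band = species_colour_bands()$lotus) {
  g <- test_geometry()
  q <- test_quadrat()
  scene <- random_scene_spec(g, q, band, n_flowers = 4,
                             r_range = c(14, 28), seed = seed)
  stream <- stream_spec(n_frames, lambda, p_on = p_on, dup_rate = dup_rate)
  list(geometry = g, quadrat = q, band = band, scene = scene,
       stream = stream,
       emitted = emit_stream(stream, scene, seed = seed + 1))
}
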