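test_that("filter_confidence is inclusive and leaves rows unaltered", {
  d <- detection_set(c(0L, 0L, 1L), c(0, 10, 20), c(0, 10, 20),
                     c(5, 15, 25), c(5, 15, 25),
                     confidence = c(0.69, 0.70, 0.95))
  kept <- filter_confidence(d, 0.7)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$confidence, c(0.70, 0.95))
  expect_identical(as.data.frame(filter_confidence(d, 0)),
                   as.data.frame(d))
  expect_equal(nrow(filter_confidence(d, 1.0)), 0)
  expect_error(filter_confidence(d, 1.5), "\\[0, 1\\]")
})

test_that("merge_boxes merges by transitive closure of centroid distance", {
  # two boxes 10 px apart, threshold 15: one merged box
  d2 <- detection_set(c(0L, 0L), c(0, 10), c(0, 0), c(10, 20), c(10, 10),
                      confidence = c(0.8, 0.9))
  m2 <- merge_boxes(d2, 15)
  expect_equal(nrow(m2), 1)
  expect_equal(unname(unlist(m2[1, c("x1", "y1", "x2", "y2")])),
               c(0, 0, 20, 10))
  expect_equal(m2$confidence, 0.9)
  expect_equal(m2$source, "merged")

  # chain A-B-C at 10-px steps: A and C 20 px apart still join via B
  d3 <- detection_set(rep(0L, 3), c(0, 10, 20), c(0, 0, 0),
                      c(10, 20, 30), c(10, 10, 10),
                      confidence = c(0.7, 0.8, 0.9))
  expect_equal(nrow(merge_boxes(d3, 15)), 1)
  expect_equal(nrow(merge_boxes(d3, 5)), 3)

  # single box: unchanged except the source flag
  d1 <- detection_set(0L, 5, 5, 10, 10, 0.6)
  m1 <- merge_boxes(d1, 15)
  expect_equal(as.data.frame(m1)[, 1:6], as.data.frame(d1)[, 1:6])
  expect_equal(m1$source, "merged")

  expect_error(merge_boxes(d1, 0), "positive")
  expect_error(merge_boxes(detection_set(c(0L, 1L), c(0, 0), c(0, 0),
                                         c(1, 1), c(1, 1), c(0.5, 0.5)),
                           10), "single frame")
})

test_that("merge_boxes agrees with the brute-force union-find oracle", {
  set.seed(101)
  for (i in 1:300) {
    d <- random_frame_dets(sample(1:20, 1))
    thr <- runif(1, 5, 80)
    got <- as.data.frame(merge_boxes(d, thr))
    want <- uf_merge_oracle(as.data.frame(d), thr)
    expect_equal(got[c("x1", "y1", "x2", "y2", "confidence")],
                 want[c("x1", "y1", "x2", "y2", "confidence")])
  }
})

test_that("merge_boxes is idempotent, non-increasing, permutation-invariant", {
  set.seed(202)
  for (i in 1:40) {
    d <- random_frame_dets(sample(2:15, 1))
    thr <- runif(1, 10, 60)
    m1 <- merge_boxes(d, thr)
    expect_lte(nrow(m1), nrow(d))
    expect_equal(as.data.frame(merge_boxes(m1, thr)), as.data.frame(m1))
    perm <- d[sample(nrow(d)), , drop = FALSE]
    expect_equal(as.data.frame(merge_boxes(perm, thr)), as.data.frame(m1))
  }
})

test_that("clip_to_quadrat keeps exactly centroid-inside detections", {
  rect <- px_rect(50, 50, 150, 150)
  d <- detection_set(rep(0L, 3),
                     x1 = c(90, 30, 130), y1 = c(90, 30, 90),
                     x2 = c(110, 60, 160), y2 = c(110, 60, 170),
                     confidence = rep(0.9, 3))
  kept <- clip_to_quadrat(d, rect)
  # box 2 overlaps the rect but its centroid (45, 45) is outside
  expect_equal(kept$x1, c(90, 130))
  # boxes are not cropped, even where they extend past the quadrat
  expect_equal(kept$y2[2], 170)

  set.seed(303)
  for (i in 1:20) {
    d <- random_frame_dets(30, extent = 300)
    kept <- clip_to_quadrat(d, rect)
    oracle <- vapply(seq_len(nrow(d)), function(r)
      centroid_in_quadrat(c(x1 = d$x1[r], y1 = d$y1[r],
                            x2 = d$x2[r], y2 = d$y2[r]), rect), NA)
    expect_equal(as.data.frame(kept), as.data.frame(d[oracle, ]),
                 ignore_attr = TRUE)
  }
})

test_that("filter_confidence and clip_to_quadrat commute", {
  set.seed(404)
  rect <- px_rect(100, 100, 400, 400)
  d <- random_frame_dets(60, extent = 500)
  a <- clip_to_quadrat(filter_confidence(d, 0.5), rect)
  b <- filter_confidence(clip_to_quadrat(d, rect), 0.5)
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
})

test_that("match_and_score applies the F1 formula and greedy matching", {
  expect_equal(f1_score(8, 1, 1), 16 / 18)
  expect_equal(f1_score(0, 0, 0), 1)
  expect_equal(f1_score(0, 0, 3), 0)

  truth <- detection_set(rep(0L, 3), c(0, 50, 100), c(0, 0, 0),
                         c(10, 60, 110), c(10, 10, 10), rep(1, 3))
  # perfect prediction
  perfect <- match_and_score(truth, truth, 5)
  expect_equal(c(perfect$TP, perfect$FP, perfect$FN), c(3, 0, 0))
  expect_equal(perfect$f1, 1)

  # empty prediction
  none <- match_and_score(truth[0, ], truth, 5)
  expect_equal(c(none$TP, none$FP, none$FN), c(0, 0, 3))
  expect_equal(none$f1, 0)

  # one miss, one spurious: greedy one-to-one matching
  pred <- detection_set(rep(0L, 3), c(1, 51, 200), c(0, 0, 0),
                        c(11, 61, 210), c(10, 10, 10), rep(1, 3))
  ms <- match_and_score(pred, truth, 10)
  expect_equal(c(ms$TP, ms$FP, ms$FN), c(2, 1, 1))
  expect_equal(ms$f1, 2 * 2 / (2 * 2 + 1 + 1))

  # a prediction cannot be matched twice
  pred2 <- detection_set(rep(0L, 2), c(0, 0.5), c(0, 0), c(10, 10.5),
                         c(10, 10), rep(1, 2))
  truth1 <- truth[1, , drop = FALSE]
  ms2 <- match_and_score(pred2, truth1, 10)
  expect_equal(c(ms2$TP, ms2$FP, ms2$FN), c(1, 1, 0))
})

test_that("F1 is monotone non-increasing in FP and FN", {
  for (tp in c(1, 5, 20)) {
    f <- sapply(0:10, function(fp) f1_score(tp, fp, 3))
    expect_true(all(diff(f) <= 0))
    g <- sapply(0:10, function(fn) f1_score(tp, 2, fn))
    expect_true(all(diff(g) <= 0))
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("counts_per_frame tabulates with zeros and checks range", {
  d <- detection_set(rep(0L, 3), c(0, 20, 40), c(0, 0, 0),
                     c(10, 30, 50), c(10, 10, 10), rep(0.9, 3))
  expect_equal(counts_per_frame(d, 2), c(3L, 0L))
  expect_equal(counts_per_frame(detection_set(), 5), rep(0L, 5))
  expect_error(counts_per_frame(d, 0), "at least 1")
  d2 <- detection_set(5L, 0, 0, 1, 1, 0.5)
  expect_error(counts_per_frame(d2, 5), "outside")

  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    dd <- random_frame_dets(sample(1:30, 1))
    dd$frame_idx <- sample(0:(n - 1), nrow(dd), replace = TRUE)
    expect_equal(sum(counts_per_frame(dd, n)), nrow(dd))
  }
})

test_that("merge_distance_px converts half a bee body to pixels", {
  expect_equal(merge_distance_px(0.5), 30)
  expect_equal(merge_distance_px(1.5), 10)
  expect_error(merge_distance_px(0), "positive")
})
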