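test_that("shipped species bands match the documented thresholds", {
  b <- species_colour_bands()
  expect_equal(b$lotus$lower, c(11, 42, 120))
  expect_equal(b$lotus$upper, c(255, 160, 255))
  expect_false(any(b$lotus$inverted))
  expect_equal(b$persicaria$lower, c(140, 255, 0))
  expect_equal(b$persicaria$upper, c(140, 40, 255))
  expect_equal(b$persicaria$inverted, c(FALSE, TRUE, FALSE))
  expect_equal(b$trifolium$lower, c(85, 255, 0))
  expect_equal(b$trifolium$upper, c(247, 186, 255))
  expect_equal(b$trifolium$inverted, c(FALSE, TRUE, FALSE))
})

test_that("band_mask is inclusive at bounds and honours inverted channels", {
  band <- colour_band(c(50, 100, 0), c(200, 200, 255))
  at_lower <- hsv_image(4, 4, c(50, 100, 0))
  expect_true(all(band_mask(at_lower, band)))
  off <- hsv_image(4, 4, c(49, 100, 0))
  expect_false(any(band_mask(off, band)))

  inv <- colour_band(c(50, 200, 0), c(200, 50, 255)) # S inverted
  expect_true(all(band_mask(hsv_image(2, 2, c(60, 250, 10)), inv)))
  expect_true(all(band_mask(hsv_image(2, 2, c(60, 20, 10)), inv)))
  expect_false(any(band_mask(hsv_image(2, 2, c(60, 100, 10)), inv)))

  expect_error(band_mask(array(300, dim = c(2, 2, 3)), band), "0-255")
})

test_that("band_mask agrees with a per-pixel brute-force channel test", {
  set.seed(21)
  bands <- c(species_colour_bands(),
             list(custom = colour_band(c(30, 220, 40), c(90, 60, 200))))
  for (band in bands) {
    img <- random_hsv_image(15, 12)
    got <- band_mask(img, band)
    for (i in seq_len(15)) for (j in seq_len(12)) {
      pass <- TRUE
      for (k in 1:3) {
        v <- img[i, j, k]
        ok <- if (band$inverted[k]) v >= band$lower[k] || v <= band$upper[k]
              else v >= band$lower[k] && v <= band$upper[k]
        pass <- pass && ok
      }
      if (got[i, j] != pass)
        fail(sprintf("mismatch at (%d, %d) for %s", i, j, band$species))
    }
    succeed()
  }
})

test_that("flower_cover counts masked pixels over the quadrat", {
  band <- colour_band(c(100, 100, 100), c(200, 200, 200))
  img <- hsv_image(40, 40, c(0, 0, 0))
  # paint the top-left 20 x 20 of an upper-left 40 x 40 quadrat: 25% cover
  img[1:20, 1:20, ] <- 150
  rect <- px_rect(0, 0, 40, 40)
  expect_equal(flower_cover(img, band, rect), 0.25)
  expect_equal(flower_cover(hsv_image(40, 40), band, rect), 0)
  expect_equal(flower_cover(array(150, dim = c(40, 40, 3)), band, rect), 1)

  # additivity of two disjoint painted regions
  img2 <- hsv_image(40, 40)
  img2[1:10, 1:10, ] <- 150
  imgB <- hsv_image(40, 40)
  imgB[25:34, 21:36, ] <- 150
  both <- hsv_image(40, 40)
  both[1:10, 1:10, ] <- 150
  both[25:34, 21:36, ] <- 150
  expect_equal(flower_cover(both, band, rect),
               flower_cover(img2, band, rect) + flower_cover(imgB, band, rect))
})

test_that("compute_ofc pools in-band pixels and takes channel medians", {
  band <- colour_band(c(0, 0, 0), c(255, 255, 255))
  uni <- hsv_image(5, 5, c(80, 90, 100))
  ofc <- compute_ofc(list(uni, uni), band, n_frames = 2, seed = 1)
  expect_equal(unclass(ofc)[1:3], c(h = 80, s = 90, v = 100))

  # pixels split evenly between two colours: channel-wise median of the two
  a <- hsv_image(4, 4, c(10, 100, 200))
  b <- hsv_image(4, 4, c(20, 120, 180))
  ofc2 <- compute_ofc(list(a, b), band, n_frames = 2, seed = 1)
  pooled <- rbind(matrix(rep(c(10, 100, 200), each = 16), ncol = 3),
                  matrix(rep(c(20, 120, 180), each = 16), ncol = 3))
  expect_equal(unname(unclass(ofc2)[1:3]), apply(pooled, 2, median))

  # OFC of a one-colour-in-band scene passes its own band
  narrow <- colour_band(c(75, 85, 95), c(85, 95, 105))
  mixed <- hsv_image(6, 6, c(0, 0, 0))
  mixed[1:2, 1:2, 1] <- 80; mixed[1:2, 1:2, 2] <- 90; mixed[1:2, 1:2, 3] <- 100
  ofc3 <- compute_ofc(list(mixed), narrow, n_frames = 1, seed = 3)
  expect_true(all(band_mask(array(rep(unclass(ofc3)[1:3], each = 1),
                                  dim = c(1, 1, 3)), narrow)))

  expect_error(compute_ofc(list(hsv_image(3, 3, c(0, 0, 0))), narrow,
                           n_frames = 1, seed = 1), "no in-band")
})

test_that("compute_ofc is invariant to frame order given the same pool", {
  set.seed(31)
  frames <- lapply(1:6, function(i) random_hsv_image(8, 8))
  band <- species_colour_bands()$lotus
  o1 <- compute_ofc(frames, band, n_frames = 6, seed = 5)
  o2 <- compute_ofc(rev(frames), band, n_frames = 6, seed = 5)
  expect_equal(unclass(o1)[1:3], unclass(o2)[1:3])
})

test_that("circular_colour_distance wraps hue and is a metric", {
  expect_equal(circular_colour_distance(c(10, 20, 30), c(10, 20, 30)), 0)
  expect_equal(circular_colour_distance(c(5, 100, 100), c(251, 100, 100)), 10)
  # hue term never exceeds half the period
  expect_equal(circular_colour_distance(c(0, 0, 0), c(128, 0, 0)), 128)
  expect_equal(circular_colour_distance(c(0, 0, 0), c(200, 0, 0)), 56)

  set.seed(41)
  for (i in 1:200) {
    a <- runif(3, 0, 255); b <- runif(3, 0, 255); c3 <- runif(3, 0, 255)
    dab <- circular_colour_distance(a, b)
    expect_equal(dab, circular_colour_distance(b, a))
    expect_lte(dab, circular_colour_distance(a, c3) +
                 circular_colour_distance(c3, b) + 1e-9)
    dh <- abs(a[1] - b[1])
    expect_lte(min(dh, 256 - dh), 128)
  }
})

test_that("build_heatmap averages distances and excludes bee boxes", {
  ofc <- c(h = 100, s = 100, v = 100)
  const <- hsv_image(10, 10, c(120, 100, 100))
  hm <- build_heatmap(list(const, const, const), detection_set(), ofc,
                      n_frames = 3, seed = 1)
  expect_true(all(abs(hm$mean - 20) < 1e-9))
  expect_true(all(hm$count == 3))

  # a box covering rows 1-5 x cols 1-5 in every frame: count 0, NA value
  dets <- detection_set(0:2, rep(0, 3), rep(0, 3), rep(5, 3), rep(5, 3),
                        rep(0.9, 3))
  hm2 <- build_heatmap(list(const, const, const), dets, ofc,
                       n_frames = 3, seed = 1)
  expect_true(all(is.na(hm2$mean[1:5, 1:5])))
  expect_true(all(hm2$count[1:5, 1:5] == 0))
  expect_true(all(hm2$box_count[1:5, 1:5] == 3))
  expect_true(all(hm2$count[6:10, ] == 3))

  # oracle: explicit per-pixel average over a 3-frame toy video
  set.seed(51)
  frames <- lapply(1:3, function(i) random_hsv_image(8, 8))
  d1 <- detection_set(1L, 2, 2, 5, 5, 0.9) # box only in frame 1 (0-based)
  hm3 <- build_heatmap(frames, d1, ofc, n_frames = 3, seed = 2)
  want <- matrix(0, 8, 8); cnt <- matrix(0, 8, 8)
  for (f in 1:3) {
    d <- circular_colour_distance(frames[[f]], ofc)
    use <- matrix(TRUE, 8, 8)
    if (f == 2) use[3:5, 3:5] <- FALSE # 0-based box [2,5) -> rows/cols 3..5
    want <- want + d * use
    cnt <- cnt + use
  }
  expect_equal(hm3$mean, want / cnt)
  expect_equal(hm3$count, cnt, ignore_attr = TRUE)

  expect_message(build_heatmap(frames, detection_set(), ofc, n_frames = 10,
                               seed = 1), "using all")
})

test_that("deviation_histogram samples defined pixels without replacement", {
  ofc <- c(h = 0, s = 0, v = 0)
  set.seed(61)
  frames <- lapply(1:2, function(i) random_hsv_image(12, 12))
  # box only in frame 0, so its pixels stay defined via frame 1
  dets <- detection_set(0L, 0, 0, 4, 4, 0.9)
  hm <- build_heatmap(frames, dets, ofc, n_frames = 2, seed = 3)

  # region smaller than n_points: every defined pixel exactly once
  all_vals <- deviation_histogram(hm, "all", n_points = 1e6, seed = 1)
  expect_equal(sort(all_vals), sort(hm$mean[!is.na(hm$mean)]))

  sub <- deviation_histogram(hm, "all", n_points = 30, seed = 2)
  expect_length(sub, 30)
  expect_true(all(sub %in% hm$mean))

  # full sampling of a region reproduces the region mean
  box_vals <- deviation_histogram(hm, "boxes", n_points = 1e6, seed = 1)
  expect_equal(mean(box_vals),
               mean(hm$mean[hm$box_count > 0 & !is.na(hm$mean)]))
})

test_that("cover on synthetic scenes equals the painted ground truth", {
  g <- test_geometry()
  q <- test_quadrat()
  for (band in species_colour_bands()) {
    sc <- random_scene_spec(g, q, band, n_flowers = 3, seed = 17)
    r <- render_scene(sc)
    expect_equal(flower_cover(r$frame, band, quadrat_rect(q, g)),
                 r$truth$cover_frac)
    expect_gt(r$truth$cover_frac, 0)
  }
})
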