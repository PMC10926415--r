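# A tiny still with known streaks, used across the detector tests.
render_probe <- function(tracks, seed = 5, width = 400, height = 300) {
  render_still(tracks, scene_config(width = width, height = height,
                                    seed = seed))
}

test_that("a dark noisy frame yields no detections", {
  set.seed(71)
  f <- matrix(rnorm(200 * 200, 10, 2), 200, 200)
  expect_length(segment_streaks(f), 0)
  # uniform frame (zero MAD) also yields none, without error
  expect_length(segment_streaks(matrix(10, 100, 100)), 0)
})

test_that("a single interior streak segments as one non-border mask", {
  tr <- flight_track("a", c(100, 100), 30, speed = 80 * 9,
                     wingbeat_hz = 45, baseline = 180, amplitude = 75)
  rs <- render_probe(list(tr))
  masks <- segment_streaks(rs$frame)
  expect_length(masks, 1)
  expect_false(masks[[1]]$touches_border)
  expect_gt(nrow(masks[[1]]$pixels), 100)
})

test_that("a streak exiting the frame is marked as touching the border", {
  tr <- flight_track("a", c(380, 150), 0, speed = 60 * 9,
                     wingbeat_hz = 45, baseline = 180, amplitude = 75)
  rs <- suppressWarnings(render_probe(list(tr)))
  masks <- segment_streaks(rs$frame)
  expect_length(masks, 1)
  expect_true(masks[[1]]$touches_border)
})

test_that("diagonally-touching pixels form one 8-connected component", {
  set.seed(72)
  f <- matrix(rnorm(64 * 64, 10, 2), 64, 64)
  # a strict diagonal line is 8-connected but 4-disconnected
  for (i in 1:30) f[10 + i, 10 + i] <- 250
  masks <- segment_streaks(f, detector_params(min_area = 10,
                                              closing_radius = 1))
  expect_length(masks, 1)
})

test_that("the score formula matches its arithmetic on crafted masks", {
  mk <- function(mean_on, bg) {
    structure(list(mean_intensity = mean_on, background_median = bg),
              class = "streak_mask")
  }
  expect_equal(detection_score(mk(255, 0)), 1)
  expect_equal(detection_score(mk(10, 10)), 0)
  expect_equal(detection_score(mk(130, 10)), 120 / 245)
  expect_equal(detection_score(mk(200, 255)), 0)  # saturated background
})

test_that("centerline sampling scores a saturated streak at ~1", {
  tr <- flight_track("a", c(100, 150), 10, speed = 100 * 9,
                     wingbeat_hz = 0, baseline = 255, amplitude = 0)
  rs <- render_probe(list(tr))
  m <- segment_streaks(rs$frame)[[1]]
  expect_gt(detection_score(m, rs$frame), 0.95)
  # while the rim-diluted mask mean cannot reach that
  expect_lt(detection_score(m), 0.85)
})

test_that("order-1 fits on exactly linear masks recover the endpoints", {
  px <- cbind(x = 0:20, y = 0:20)
  mask <- structure(list(pixels = px, mean_intensity = 200,
                         background_median = 10, touches_border = FALSE),
                    class = "streak_mask")
  P <- mask_to_polyline(mask, order = 1, n_vertices = 5)
  V <- unclass(P)
  expect_lt(max(abs(V[1, ] - c(0, 0))), 1)
  expect_lt(max(abs(V[nrow(V), ] - c(20, 20))), 1)
  d <- apply(V, 1, function(p) abs(p[1] - p[2]) / sqrt(2))
  expect_lt(max(d), 0.5)
})

test_that("order-2 fits recover a parabolic band's coefficients", {
  xs <- seq(0, 40, by = 0.5)
  px <- do.call(rbind, lapply(c(-1, 0, 1), function(o) {
    cbind(x = xs, y = 0.05 * (xs - 20)^2 + o)
  }))
  mask <- structure(list(pixels = px, mean_intensity = 200,
                         background_median = 10, touches_border = FALSE),
                    class = "streak_mask")
  P <- mask_to_polyline(mask, order = 2, n_vertices = 15)
  V <- unclass(P)
  fit <- stats::lm(y ~ poly(x, 2, raw = TRUE), data = as.data.frame(V))
  expect_equal(unname(stats::coef(fit)[3]), 0.05, tolerance = 0.1)
  # and the vertices stay near the true curve
  expect_lt(max(abs(V[, 2] - 0.05 * (V[, 1] - 20)^2)), 1)
})

test_that("degenerate masks raise the dedicated condition", {
  mask <- structure(list(pixels = cbind(x = rep(5, 4), y = rep(7, 4)),
                         mean_intensity = 200, background_median = 10,
                         touches_border = FALSE),
                    class = "streak_mask")
  expect_error(mask_to_polyline(mask), class = "blurtrack_degenerate_mask")
})

test_that("classification routes interior/border/short masks correctly", {
  long_tr <- flight_track("a", c(100, 100), 30, speed = 60 * 9,
                          wingbeat_hz = 45, baseline = 180, amplitude = 75)
  rs <- render_probe(list(long_tr))
  m <- segment_streaks(rs$frame)[[1]]
  expect_equal(classify_and_annotate(m, rs$frame)$kind, "polyline")

  edge_tr <- flight_track("b", c(370, 150), 0, speed = 60 * 9,
                          wingbeat_hz = 45, baseline = 180, amplitude = 75)
  rs2 <- suppressWarnings(render_probe(list(edge_tr)))
  m2 <- segment_streaks(rs2$frame)[[1]]
  a2 <- classify_and_annotate(m2, rs2$frame)
  expect_equal(a2$kind, "circle")

  # an interior blob of ~4 px extent falls below min_polyline_length
  set.seed(73)
  f <- matrix(rnorm(100 * 100, 10, 2), 100, 100)
  f[50:53, 50:53] <- 250
  m3 <- segment_streaks(f, detector_params(min_area = 10))[[1]]
  a3 <- classify_and_annotate(m3, f)
  expect_equal(a3$kind, "point")
})

test_that("annotate_image is deterministic and sorted by bounding box", {
  sc <- random_scene(3, "clean", seed = 77, mode = "still", width = 960,
                     height = 540, speed_range = c(270, 1350))
  rs <- render_still(sc$tracks, sc$cfg)
  a1 <- annotate_image(rs$frame)
  a2 <- annotate_image(rs$frame)
  expect_identical(a1, a2)
  expect_length(a1, 3)
  xmins <- vapply(a1, function(a) bbox_of(a)[[1]], numeric(1))
  expect_true(all(diff(xmins) >= 0))
  # empty frame
  set.seed(78)
  expect_length(annotate_image(matrix(rnorm(100 * 100, 10, 2), 100, 100)),
                0)
})

test_that("an interior and an edge-clipped streak annotate as polyline + circle", {
  tr1 <- flight_track("a", c(150, 100), 40, speed = 60 * 9,
                      wingbeat_hz = 45, baseline = 180, amplitude = 75)
  tr2 <- flight_track("b", c(390, 250), 0, speed = 60 * 9,
                      wingbeat_hz = 45, baseline = 180, amplitude = 75)
  rs <- suppressWarnings(render_probe(list(tr1, tr2)))
  kinds <- sort(vapply(annotate_image(rs$frame), `[[`, "", "kind"))
  expect_equal(kinds, c("circle", "polyline"))
})
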