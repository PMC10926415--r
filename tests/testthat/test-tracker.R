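poly_det <- function(x, y, score = 0.9, pair = 1) {
  detection(annotation(polyline(x, y), score), pair)
}

test_that("pairwise maximum images obey their algebra", {
  A <- matrix(runif(100, 0, 255), 10, 10)
  expect_equal(pairwise_maximum(list(A, A)), list(A))
  f1 <- matrix(c(0, 100, 50, 10), 2, 2)
  f2 <- matrix(c(30, 90, 40, 200), 2, 2)
  expect_equal(pairwise_maximum(list(f1, f2))[[1]],
               matrix(c(30, 100, 50, 200), 2, 2))
  frames <- replicate(5, matrix(runif(64), 8, 8), simplify = FALSE)
  out <- pairwise_maximum(frames)
  expect_length(out, 4)
  for (i in seq_along(out)) {
    expect_true(all(out[[i]] >= frames[[i]]))
    expect_true(all(out[[i]] >= frames[[i + 1]]))
  }
  expect_error(pairwise_maximum(frames[1]), "at least 2")
  expect_error(pairwise_maximum(list(matrix(0, 8, 8), matrix(0, 9, 8))),
               "mismatched")
})

test_that("linking joins continuing blurs and respects the threshold rule", {
  cfg <- tracking_config()
  d1 <- list(poly_det(c(0, 10), c(0, 0), pair = 1),
             poly_det(c(0, 10), c(500, 500), pair = 1))
  d2 <- list(poly_det(c(10, 20), c(0, 0), pair = 2))
  links <- link_detections(d1, d2, cfg)
  expect_equal(nrow(links), 1)
  expect_equal(unname(links[1, ]), c(1, 1))
  # crossing at right angles at the midpoints, 5 px half-lengths: every
  # endpoint is 5 px from the other polyline, so d_M = 5 and the link is
  # retained iff threshold >= 5 (inclusive link rule)
  a <- list(poly_det(c(-5, 5), c(0, 0), pair = 1))
  b <- list(poly_det(c(0, 0), c(-5, 5), pair = 2))
  expect_equal(nrow(link_detections(a, b, tracking_config(dM_threshold = 5))),
               1)
  expect_equal(nrow(link_detections(a, b, tracking_config(dM_threshold = 4.9))),
               0)
  # empty side
  expect_equal(nrow(link_detections(d1, list(), cfg)), 0)
  # circle detections never link
  circ <- list(detection(annotation(circle(5, 0, 3), 0.9), 1))
  expect_equal(nrow(link_detections(circ, d2, cfg)), 0)
})

test_that("trajectory building partitions detections and chains overlaps", {
  cfg <- tracking_config()
  # one insect across 4 pair images: abutting collinear detections
  per_pair <- lapply(1:4, function(t) {
    list(poly_det(c((t - 1) * 10, t * 10 + 10), c(0, 0), pair = t))
  })
  trajs <- build_trajectories(per_pair, cfg)
  expect_length(trajs, 1)
  expect_equal(trajs[[1]]$n_detections, 4)
  # two well-separated insects: two trajectories, no swaps
  per_pair2 <- lapply(1:3, function(t) {
    list(poly_det(c((t - 1) * 10, t * 10 + 10), c(0, 0), pair = t),
         poly_det(c((t - 1) * 10, t * 10 + 10), c(400, 400), pair = t))
  })
  trajs2 <- build_trajectories(per_pair2, cfg)
  expect_length(trajs2, 2)
  ys <- sort(vapply(trajs2, function(tr) {
    unclass(tr$detections[[1]]$annotation$shape)[1, 2]
  }, numeric(1)))
  expect_equal(ys, c(0, 400))
  # count conservation: every detection in exactly one trajectory
  expect_equal(sum(vapply(trajs2, `[[`, integer(1), "n_detections")),
               sum(lengths(per_pair2)))
  # a lone detection forms a singleton trajectory
  trajs3 <- build_trajectories(list(list(poly_det(c(0, 10), c(0, 0)))), cfg)
  expect_length(trajs3, 1)
  expect_equal(trajs3[[1]]$n_detections, 1)
})

test_that("length and score filters implement their thresholds exactly", {
  cfg <- tracking_config()
  mk_traj <- function(scores) {
    trajectory(lapply(seq_along(scores), function(i) {
      poly_det(c(i * 10, i * 10 + 10), c(0, 0), scores[i], pair = i)
    }))
  }
  short_good <- mk_traj(c(0.99, 0.99))          # 2 detections: removed
  long_good <- mk_traj(c(0.9, 0.7, 0.9))        # mean 0.8333: kept
  long_bad <- mk_traj(c(0.9, 0.6, 0.8))         # mean 0.7667: removed
  out <- filter_trajectories(list(short_good, long_good, long_bad), cfg)
  expect_length(out, 1)
  expect_equal(out[[1]]$mean_score, mean(c(0.9, 0.7, 0.9)))
  counts <- attr(out, "stage_counts")
  expect_equal(unname(counts), c(3, 2, 1))
  # filters only remove, and survivors satisfy both predicates
  for (tr in out) {
    expect_gte(tr$n_detections, cfg$min_detections)
    expect_gte(tr$mean_score, cfg$min_mean_score)
  }
})

test_that("the ROI filter keeps inclusively-inside trajectories only", {
  roi <- circle(0, 0, 100)
  inside <- trajectory(list(poly_det(c(0, 50), c(0, 0))))
  boundary <- trajectory(list(poly_det(c(0, 100), c(0, 0))))  # vertex at r
  outside <- trajectory(list(poly_det(c(0, 101), c(0, 0))))
  out <- roi_filter(list(inside, boundary, outside), roi)
  expect_length(out, 2)
})

test_that("displacement direction follows the oriented detection chain", {
  t1 <- trajectory(list(poly_det(c(0, 5), c(0, 0), pair = 1),
                        poly_det(c(5, 10), c(0, 0), pair = 2)))
  expect_equal(trajectory_direction(t1), 0)
  t2 <- trajectory(list(poly_det(c(0, 0), c(0, 5), pair = 1),
                        poly_det(c(0, 0), c(5, 10), pair = 2)))
  expect_equal(trajectory_direction(t2), 90)
  # reversed vertex order within detections must not flip the answer
  t3 <- trajectory(list(poly_det(c(5, 0), c(0, 0), pair = 1),
                        poly_det(c(10, 5), c(0, 0), pair = 2)))
  expect_equal(trajectory_direction(t3), 0)
  expect_error(trajectory_direction(trajectory(list(poly_det(c(0, 5),
                                                             c(0, 0))))),
               "fewer than 2")
})

test_that("a synthetic straight-line track reports its true heading", {
  sc <- random_scene(1, "clean", seed = 99, mode = "sequence", width = 640,
                     height = 480, n_frames = 30)
  # overwrite the heading with a known value, keep everything else drawn
  tr <- sc$tracks[[1]]
  known <- flight_track("k", c(150, 120), 30, speed = 400,
                        wingbeat_hz = tr$wingbeat_hz, baseline = 200,
                        amplitude = 55)
  rsq <- render_sequence(list(known), sc$cfg)
  ts <- track_batch(rsq$frames, tracking_config())
  expect_length(ts, 1)
  expect_equal(trajectory_direction(ts[[1]]), 30, tolerance = 3 / 30)
})

test_that("track_batch recovers a small clean clip end to end", {
  sc <- random_scene(2, "clean", seed = 13, mode = "sequence", width = 640,
                     height = 480, n_frames = 40,
                     speed_range = c(100, 1500) * 4 / 9)
  rsq <- render_sequence(sc$tracks, sc$cfg)
  ts <- track_batch(rsq$frames, tracking_config())
  expect_length(ts, 2)
  ev <- evaluate_tracking(ts, sequence_pair_truth(sc$tracks, sc$cfg))
  expect_equal(ev$summary$n_recovered, 2)
  expect_equal(ev$summary$identity_swaps, 0)
  # deterministic rerun
  ts2 <- track_batch(rsq$frames, tracking_config())
  expect_identical(generics::tidy(ts), generics::tidy(ts2))
  # the roi filter composes into the pipeline
  roi <- circle(320, 240, 150)
  ts3 <- track_batch(rsq$frames, tracking_config(roi = roi))
  expect_lte(length(ts3), length(ts))
})

test_that("tidy/glance summarize a trajectory set faithfully", {
  sc <- random_scene(1, "clean", seed = 14, mode = "sequence", width = 640,
                     height = 480, n_frames = 30)
  rsq <- render_sequence(sc$tracks, sc$cfg)
  ts <- track_batch(rsq$frames, tracking_config())
  tb <- generics::tidy(ts)
  expect_equal(nrow(tb), sum(vapply(ts, `[[`, integer(1), "n_detections")))
  expect_true(all(diff(tb$pair_index[tb$trajectory_id == 1]) == 1))
  g <- generics::glance(ts)
  expect_equal(g$n_trajectories, length(ts))
  expect_gte(g$n_detections, g$n_built)
  p <- ggplot2::autoplot(ts)
  expect_s3_class(p, "ggplot")
})
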