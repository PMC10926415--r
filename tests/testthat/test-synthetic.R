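test_that("rendering is bit-identical given the same seed and inputs", {
  tr <- flight_track("a", c(100, 100), 30, speed = 80 * 9,
                     wingbeat_hz = 45, baseline = 190, amplitude = 65)
  cfg <- scene_config(width = 320, height = 240, seed = 5)
  r1 <- render_still(list(tr), cfg)
  r2 <- render_still(list(tr), cfg)
  expect_identical(r1$frame, r2$frame)
  expect_identical(r1$truth, r2$truth)
  # a different seed changes the noise field
  r3 <- render_still(list(tr), scene_config(width = 320, height = 240,
                                            seed = 6))
  expect_false(identical(r1$frame, r3$frame))
  # scene draws are reproducible too
  s1 <- random_scene(3, "clean", seed = 7, mode = "still", width = 640,
                     height = 480)
  s2 <- random_scene(3, "clean", seed = 7, mode = "still", width = 640,
                     height = 480)
  expect_identical(s1, s2)
  expect_length(random_scene(0, "clean", seed = 1, mode = "still")$tracks, 0)
})

test_that("rendered streak pixels cover the truth polyline", {
  tr <- flight_track("a", c(60, 60), 25, speed = 100 * 9,
                     wingbeat_hz = 45, baseline = 190, amplitude = 65)
  cfg <- scene_config(width = 320, height = 240, seed = 8)
  rs <- render_still(list(tr), cfg)
  pts <- resample_polyline(rs$truth$ann[[1]]$shape, 1)
  vals <- rs$frame[cbind(round(pts[, 2]) + 1, round(pts[, 1]) + 1)]
  expect_true(all(vals > cfg$background_level + 50))
})

test_that("rendered intensity modulation carries wingbeat_hz x exposure cycles", {
  # the modulation law itself: cycles over the exposure window, analytic
  tr <- flight_track("a", c(0, 0), 0, speed = 900, wingbeat_hz = 54,
                     baseline = 190, amplitude = 65)
  exposure <- 1 / 9
  t <- seq(0, exposure, length.out = 20001)
  I <- blurtrack:::track_intensity(tr, t)
  phase <- 54 * t  # cycles elapsed
  expect_equal(max(phase), 54 * exposure, tolerance = 1e-9)
  # count rising zero-crossings of the centred signal: one per full cycle
  ctr <- I - mean(range(I))
  crossings <- sum(diff(sign(ctr)) > 0)
  expect_equal(crossings, floor(54 * exposure))
})

test_that("sequences abut consecutive blurs when exposure equals 1/fps", {
  tr <- flight_track("a", c(60, 120), 0, speed = 450, wingbeat_hz = 40,
                     baseline = 190, amplitude = 65, t_ref = 0)
  cfg <- scene_config(width = 320, height = 240, fps = 30,
                      exposure = 1 / 30, n_frames = 5, seed = 9)
  rsq <- render_sequence(list(tr), cfg)
  expect_length(rsq$frames, 5)
  polys <- rsq$truth$ann
  for (i in seq_len(nrow(rsq$truth) - 1)) {
    a <- unclass(polys[[i]]$shape)
    b <- unclass(polys[[i + 1]]$shape)
    expect_lt(sqrt(sum((a[nrow(a), ] - b[1, ])^2)), 1e-6)
  }
  # truth polylines are collinear for a straight path
  dirs <- vapply(polys, function(p) {
    v <- unclass(p$shape)
    atan2(v[nrow(v), 2] - v[1, 2], v[nrow(v), 1] - v[1, 1])
  }, numeric(1))
  expect_lt(max(abs(diff(dirs))), 1e-6)
})

test_that("shorter exposures leave kinematically-sized gaps between blurs", {
  sp <- 600; fps <- 30; expo <- 1 / 60
  tr <- flight_track("a", c(40, 120), 0, speed = sp, wingbeat_hz = 40,
                     baseline = 190, amplitude = 65)
  cfg <- scene_config(width = 320, height = 240, fps = fps,
                      exposure = expo, n_frames = 3, seed = 10)
  rsq <- render_sequence(list(tr), cfg)
  a <- unclass(rsq$truth$ann[[1]]$shape)
  b <- unclass(rsq$truth$ann[[2]]$shape)
  gap <- sqrt(sum((b[1, ] - a[nrow(a), ])^2))
  expect_equal(gap, sp * (1 / fps - expo), tolerance = 1e-6)
  # an exposure exceeding the frame interval is rejected for sequences
  bad <- scene_config(width = 320, height = 240, fps = 30, exposure = 1 / 9,
                      n_frames = 3)
  expect_error(render_sequence(list(tr), bad), "exposure")
})

test_that("edge-exiting paths yield circle truth; off-frame tracks warn", {
  tr_edge <- flight_track("a", c(310, 120), 0, speed = 450,
                          wingbeat_hz = 40, baseline = 190, amplitude = 65)
  cfg <- scene_config(width = 320, height = 240, seed = 11)
  rs <- suppressWarnings(render_still(list(tr_edge), cfg))
  expect_equal(rs$truth$kind, "circle")
  expect_true(rs$truth$clipped)
  tr_out <- flight_track("b", c(-500, -500), 0, speed = 100,
                         wingbeat_hz = 40, baseline = 190, amplitude = 65)
  expect_warning(render_still(list(tr_out), cfg), "outside")
  # zero tracks: pure noise frame, empty truth
  rs0 <- render_still(list(), cfg)
  expect_equal(nrow(rs0$truth), 0)
  expect_lt(max(rs0$frame), cfg$background_level + 8 * cfg$noise_sigma)
})

test_that("the clean preset enforces pairwise path separation", {
  sc <- random_scene(5, "clean", seed = 12, mode = "sequence", width = 854,
                     height = 480, n_frames = 60,
                     speed_range = c(100, 1500) * 4 / 9)
  expect_length(sc$tracks, 5)
  t <- seq(0, sc$cfg$n_frames / sc$cfg$fps, by = 0.02)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      pi_ <- track_position(sc$tracks[[i]], t)
      pj <- track_position(sc$tracks[[j]], t)
      dmin <- min(sqrt((pi_[, 1] - pj[, 1])^2 + (pi_[, 2] - pj[, 2])^2))
      expect_gte(dmin, 80)
    }
  }
  # per-exposure blur length stays above the annotation floor
  for (tr in sc$tracks) {
    expect_gte(tr$speed * sc$cfg$exposure, 12)
  }
})

test_that("flight_track validates its physical invariants", {
  expect_error(flight_track("a", c(0, 0), 0, speed = 0), "speed")
  expect_error(flight_track("a", c(0, 0), 0, 100, wingbeat_hz = -1),
               "wingbeat")
  expect_error(flight_track("a", c(0, 0), 0, 100, baseline = 200,
                            amplitude = 100), "255")
  expect_error(scene_config(width = 32), "64")
})
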