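#' Scene configuration for the synthetic generator
#'
#' Defaults emulate the night-capture setup the rest of the package is
#' designed around: 1080p frames, 30 frames/s video, 1/9 s still exposure,
#' a dark Gaussian-noise background and 3 px wide streaks.
#'
#' @param width,height Frame size in pixels (>= 64; default 1920 x 1080).
#' @param fps Frames per second for sequences (default 30).
#' @param exposure Exposure time in seconds (default 1/9, the typical
#'   night still exposure). Frame sequences require `exposure <= 1/fps`;
#'   the constraint is checked when a sequence is rendered, since stills
#'   have no frame interval.
#' @param n_frames Number of frames for sequences (default 1).
#' @param background_level Mean background intensity (default 10).
#' @param noise_sigma Gaussian background noise s.d. (default 2).
#' @param streak_width Rendered blur width in pixels (default 3).
#' @param seed RNG seed controlling the background noise (default 1).
#' @return A list of class `"scene_config"`.
#' @export
scene_config <- function(width = 1920, height = 1080, fps = 30,
                         exposure = 1 / 9, n_frames = 1,
                         background_level = 10, noise_sigma = 2,
                         streak_width = 3, seed = 1) {
  if (width < 64 || height < 64) {
    stop("scene_config: dimensions must be >= 64", call. = FALSE)
  }
  if (exposure <= 0 || fps <= 0) {
    stop("scene_config: exposure and fps must be positive", call. = FALSE)
  }
  structure(list(width = width, height = height, fps = fps,
                 exposure = exposure, n_frames = n_frames,
                 background_level = background_level,
                 noise_sigma = noise_sigma, streak_width = streak_width,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Construct a ground-truth flight track
#'
#' Position is a per-axis polynomial of time of order <= 2:
#' `pos(t) = start + velocity * t + 0.5 * accel * t^2`, i.e. a straight
#' or gently curved path — the same "simple curves" assumption the
#' polyline regression relies on. Intensity along the blur is modulated
#' as a raised sinusoid `baseline + amplitude * (0.5 + 0.5 *
#' sin(2 pi wingbeat_hz t))`, so the number of intensity cycles rendered
#' over an exposure is exactly `wingbeat_hz * exposure`.
#'
#' @param identity Track identifier.
#' @param start Length-2 position `c(x, y)` at `t = t_ref` (px).
#' @param heading_deg Direction of travel in image coordinates (degrees;
#'   y increases down-image).
#' @param speed Speed in px/s (> 0).
#' @param accel Length-2 acceleration `c(ax, ay)` in px/s^2 (the order-2
#'   path term; default none).
#' @param wingbeat_hz Wingbeat frequency in Hz (>= 0; 0 disables
#'   modulation).
#' @param baseline,amplitude Intensity baseline and modulation amplitude;
#'   `baseline + amplitude` must not exceed 255.
#' @param t_ref Reference time of `start` in seconds (default 0).
#' @param frames_visible Optional inclusive frame-index range
#'   `c(first, last)` outside which the track is not rendered.
#' @return An object of class `"flight_track"`.
#' @export
flight_track <- function(identity, start, heading_deg, speed,
                         accel = c(0, 0), wingbeat_hz = 50,
                         baseline = 60, amplitude = 140, t_ref = 0,
                         frames_visible = NULL) {
  if (speed <= 0) stop("flight_track: speed must be > 0", call. = FALSE)
  if (wingbeat_hz < 0) {
    stop("flight_track: wingbeat_hz must be >= 0", call. = FALSE)
  }
  if (baseline + amplitude > 255) {
    stop("flight_track: baseline + amplitude must be <= 255", call. = FALSE)
  }
  th <- heading_deg * pi / 180
  v <- speed * c(cos(th), sin(th))
  structure(list(identity = identity,
                 coef_x = c(start[1] - v[1] * t_ref - 0.5 * accel[1] * t_ref^2,
                            v[1] + accel[1] * t_ref, 0.5 * accel[1]),
                 coef_y = c(start[2] - v[2] * t_ref - 0.5 * accel[2] * t_ref^2,
                            v[2] + accel[2] * t_ref, 0.5 * accel[2]),
                 speed = speed, wingbeat_hz = wingbeat_hz,
                 baseline = baseline, amplitude = amplitude,
                 frames_visible = frames_visible),
            class = "flight_track")
}

#' Position of a track at given times
#'
#' @param track A [flight_track()].
#' @param t Numeric vector of times in seconds.
#' @return Matrix (length(t) x 2) of x,y positions.
#' @export
track_position <- function(track, t) {
  cbind(track$coef_x[1] + track$coef_x[2] * t + track$coef_x[3] * t^2,
        track$coef_y[1] + track$coef_y[2] * t + track$coef_y[3] * t^2)
}

track_intensity <- function(track, t) {
  track$baseline + track$amplitude *
    (0.5 + 0.5 * sin(2 * pi * track$wingbeat_hz * t))
}

## Stamp one track's blur over time window [t0, t1] into `img` (max
## composition with an anti-aliased linear-falloff cross-section).
.stamp_track <- function(img, track, t0, t1, streak_width) {
  H <- nrow(img); W <- ncol(img)
  sp_end <- sqrt((track$coef_x[2] + 2 * track$coef_x[3] * c(t0, t1))^2 +
                 (track$coef_y[2] + 2 * track$coef_y[3] * c(t0, t1))^2)
  n <- max(8, ceiling(max(sp_end) * (t1 - t0) / 0.4))
  t <- seq(t0, t1, length.out = n)
  pos <- track_position(track, t)
  I <- track_intensity(track, t)
  rad <- streak_width / 2
  K <- ceiling(rad + 0.5)
  rx <- round(pos[, 1]); ry <- round(pos[, 2])
  idx_all <- integer(0); val_all <- numeric(0)
  for (dx in -K:K) {
    for (dy in -K:K) {
      ix <- rx + dx; iy <- ry + dy
      d <- sqrt((ix - pos[, 1])^2 + (iy - pos[, 2])^2)
      cov <- pmin(1, pmax(0, rad + 0.5 - d))
      ok <- cov > 0 & ix >= 0 & ix < W & iy >= 0 & iy < H
      if (!any(ok)) next
      idx_all <- c(idx_all, iy[ok] + 1 + H * ix[ok])
      val_all <- c(val_all, I[ok] * cov[ok])
    }
  }
  if (length(idx_all) == 0) return(img)
  ord <- order(val_all)   # ascending, so the max wins on duplicate pixels
  idx_all <- idx_all[ord]; val_all <- val_all[ord]
  img[idx_all] <- pmax(img[idx_all], val_all)
  img
}

## Truth annotation of a track over [t0, t1]: a polyline sampled from the
## exact path when fully in-frame, a circle around the in-frame portion
## when the path exits the frame, NULL when entirely out of frame.
.truth_annotation <- function(track, t0, t1, cfg) {
  n <- max(16, ceiling(track$speed * (t1 - t0) / 2))
  t <- seq(t0, t1, length.out = n)
  pos <- track_position(track, t)
  inside <- pos[, 1] >= 0 & pos[, 1] <= cfg$width - 1 &
    pos[, 2] >= 0 & pos[, 2] <= cfg$height - 1
  if (!any(inside)) return(NULL)
  d <- diff(pos)
  arc <- sum(sqrt(rowSums(d^2)))
  if (all(inside)) {
    nv <- max(2, min(25, ceiling(arc / 15) + 1))
    tv <- seq(t0, t1, length.out = nv)
    pv <- track_position(track, tv)
    ann <- annotation(polyline(pv[, 1], pv[, 2]))
  } else {
    mec <- min_enclosing_circle(pos[inside, , drop = FALSE])
    ann <- annotation(circle(mec$cx, mec$cy,
                             max(mec$r, 0.5) + cfg$streak_width / 2))
  }
  list(ann = ann, arc_length = arc, clipped = !all(inside))
}

.track_visible_in_frame <- function(track, frame_i) {
  fv <- track$frames_visible
  is.null(fv) || (frame_i >= fv[1] && frame_i <= fv[2])
}

#' Render a single long-exposure still
#'
#' Background is `background_level` plus seeded Gaussian noise; each track
#' contributes an anti-aliased, wingbeat-modulated streak along its path
#' over `[t0, t0 + exposure]`. Deterministic given the seed. Ground truth
#' is the exact sampled path polyline per track, or an enclosing circle
#' when the path exits the frame; tracks entirely out of frame are
#' excluded with a warning.
#'
#' @param tracks List of [flight_track()] objects.
#' @param cfg A [scene_config()].
#' @param t0 Exposure start time in seconds (default 0).
#' @return List with `frame` (numeric matrix) and `truth` (tibble:
#'   `identity`, `kind`, `ann` list-column of [annotation()]s,
#'   `wingbeat_hz`, `arc_length`, `clipped`).
#' @export
render_still <- function(tracks, cfg = scene_config(), t0 = 0) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  img <- matrix(stats::rnorm(cfg$height * cfg$width, cfg$background_level,
                             cfg$noise_sigma),
                cfg$height, cfg$width)
  t1 <- t0 + cfg$exposure
  rows <- list()
  for (tr in tracks) {
    tru <- .truth_annotation(tr, t0, t1, cfg)
    if (is.null(tru)) {
      warning(sprintf("render_still: track '%s' entirely outside the frame",
                      tr$identity), call. = FALSE)
      next
    }
    img <- .stamp_track(img, tr, t0, t1, cfg$streak_width)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      identity = as.character(tr$identity), kind = tru$ann$kind,
      ann = list(tru$ann), wingbeat_hz = tr$wingbeat_hz,
      arc_length = tru$arc_length, clipped = tru$clipped)
  }
  truth <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(identity = character(0), kind = character(0),
                   ann = list(), wingbeat_hz = numeric(0),
                   arc_length = numeric(0), clipped = logical(0))
  list(frame = pmin(pmax(img, 0), 255), truth = truth)
}

#' Render a frame sequence
#'
#' Frame `i` exposes over `[(i - 1)/fps, (i - 1)/fps + exposure]`. With
#' `exposure = 1/fps` the consecutive blurs of one insect abut
#' end-to-end, guaranteeing overlap in the pairwise maximum images; a
#' shorter exposure leaves gaps of `speed * (1/fps - exposure)` pixels.
#'
#' @param tracks List of [flight_track()] objects.
#' @param cfg A [scene_config()] with `n_frames >= 2` and
#'   `exposure <= 1/fps`.
#' @return List with `frames` (list of matrices) and `truth` (tibble as in
#'   [render_still()] plus a `frame` column).
#' @export
render_sequence <- function(tracks, cfg) {
  if (cfg$n_frames < 2) {
    stop("render_sequence: n_frames must be >= 2", call. = FALSE)
  }
  if (cfg$exposure > 1 / cfg$fps + 1e-12) {
    stop("render_sequence: exposure must be <= 1/fps", call. = FALSE)
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  frames <- vector("list", cfg$n_frames)
  rows <- list()
  for (i in seq_len(cfg$n_frames)) {
    img <- matrix(stats::rnorm(cfg$height * cfg$width,
                               cfg$background_level, cfg$noise_sigma),
                  cfg$height, cfg$width)
    t0 <- (i - 1) / cfg$fps
    t1 <- t0 + cfg$exposure
    for (tr in tracks) {
      if (!.track_visible_in_frame(tr, i)) next
      tru <- .truth_annotation(tr, t0, t1, cfg)
      if (is.null(tru)) next
      img <- .stamp_track(img, tr, t0, t1, cfg$streak_width)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        frame = i, identity = as.character(tr$identity),
        kind = tru$ann$kind, ann = list(tru$ann),
        wingbeat_hz = tr$wingbeat_hz, arc_length = tru$arc_length,
        clipped = tru$clipped)
    }
    frames[[i]] <- pmin(pmax(img, 0), 255)
  }
  truth <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(frame = integer(0), identity = character(0),
                   kind = character(0), ann = list(),
                   wingbeat_hz = numeric(0), arc_length = numeric(0),
                   clipped = logical(0))
  list(frames = frames, truth = truth)
}

#' Ground-truth polylines per maximum image
#'
#' The detector operates on pairwise maximum images, where an insect's
#' blur spans the combined exposure window of frames `t` and `t + 1`.
#' This returns, per pair index, the exact truth polyline of that combined
#' window for every track fully inside the frame (clipped windows are
#' omitted; they surface as circle annotations, which never link).
#'
#' @param tracks List of [flight_track()] objects.
#' @param cfg A [scene_config()].
#' @return Tibble with columns `pair_index`, `identity`, `poly`
#'   (list-column of [polyline()]s).
#' @export
sequence_pair_truth <- function(tracks, cfg) {
  rows <- list()
  for (t in seq_len(cfg$n_frames - 1)) {
    t0 <- (t - 1) / cfg$fps
    t1 <- t / cfg$fps + cfg$exposure
    for (tr in tracks) {
      if (!.track_visible_in_frame(tr, t) &&
          !.track_visible_in_frame(tr, t + 1)) next
      tru <- .truth_annotation(tr, t0, t1, cfg)
      if (is.null(tru) || tru$clipped) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pair_index = t, identity = as.character(tr$identity),
        poly = list(tru$ann$shape))
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(pair_index = integer(0), identity = character(0),
                   poly = list())
}

#' Draw a random ground-truthed scene
#'
#' Seeded draws of speed, heading, curvature, wingbeat frequency and
#' contrast for `n_insects` tracks, plus a matching [scene_config()].
#' The `"clean"` preset rejection-samples tracks until (a) every
#' per-exposure blur is at least 12 px long (shorter blurs are point
#' annotations by design and cannot carry a wingbeat or a link), (b) each
#' track is fully inside the frame for at least `min_interior_frames`
#' consecutive frames (sequences) or entirely inside (stills), and (c) no
#' two tracks approach within `separation` px at time offsets up to 0.1 s
#' — the regime in which the tracker is expected to be exact. The
#' `"hard"` preset drops the separation constraint and lowers contrast.
#'
#' @param n_insects Number of tracks (>= 0).
#' @param preset `"clean"` or `"hard"`.
#' @param seed RNG seed (also used for the scene background).
#' @param mode `"still"` (single 1/9 s exposure) or `"sequence"` (video
#'   frames with `exposure = 1/fps`).
#' @param width,height,fps,n_frames Scene geometry (defaults 1920 x 1080,
#'   30 fps, 60 frames for sequences).
#' @param speed_range Speed draw range in px/s (default 100-1500; floored
#'   so blurs reach 12 px per exposure).
#' @param wingbeat_range Wingbeat draw range in Hz (default 20-80).
#' @param separation Minimum pairwise path separation for the clean
#'   preset (default 80 px, twice the default linking threshold).
#' @param min_interior_frames Minimum consecutive fully-interior frames
#'   per track in clean sequences (default 8).
#' @return List with `tracks` and `cfg`, reproducible given `seed`.
#' @export
random_scene <- function(n_insects, preset = c("clean", "hard"), seed = 1,
                         mode = c("still", "sequence"), width = 1920,
                         height = 1080, fps = 30, n_frames = 60,
                         speed_range = c(100, 1500),
                         wingbeat_range = c(20, 80), separation = 80,
                         min_interior_frames = 8) {
  preset <- match.arg(preset)
  mode <- match.arg(mode)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  exposure <- if (mode == "still") 1 / 9 else 1 / fps
  if (mode == "still") n_frames <- 1
  cfg <- scene_config(width = width, height = height, fps = fps,
                      exposure = exposure, n_frames = n_frames,
                      seed = seed)
  clip_T <- n_frames / fps
  min_speed <- max(speed_range[1], 12 / exposure)
  tracks <- list()
  for (id in seq_len(n_insects)) {
    ok <- FALSE
    for (try in seq_len(500)) {
      speed <- stats::runif(1, min_speed, max(speed_range[2], min_speed))
      heading <- stats::runif(1, 0, 360)
      wb <- stats::runif(1, wingbeat_range[1], wingbeat_range[2])
      if (preset == "clean") {
        # IR-flash moths render near-white: wing-glint peaks saturate, the
        # body/trough brightness sets the baseline
        baseline <- stats::runif(1, 180, 220)
        amplitude <- 255 - baseline
      } else {
        baseline <- stats::runif(1, 20, 40)
        amplitude <- stats::runif(1, 20, min(60, 255 - baseline))
      }
      if (mode == "still") {
        chord <- speed * exposure
        inset <- min(chord + 10, (min(width, height) - 20) / 2)
        start <- c(stats::runif(1, inset, width - 1 - inset),
                   stats::runif(1, inset, height - 1 - inset))
        # gentle curvature: sag up to 5% of the chord
        sag <- stats::runif(1, 0, 0.05) * chord
        amag <- 8 * sag / exposure^2
        aphi <- (heading + 90) * pi / 180
        cand <- flight_track(id, start, heading, speed,
                             accel = amag * c(cos(aphi), sin(aphi)),
                             wingbeat_hz = wb, baseline = baseline,
                             amplitude = amplitude)
        tcheck <- seq(0, exposure, length.out = 64)
        pos <- track_position(cand, tcheck)
        if (any(pos[, 1] < 5 | pos[, 1] > width - 6 |
                pos[, 2] < 5 | pos[, 2] > height - 6)) next
        if (preset == "clean" &&
            !.paths_separated_still(cand, tracks, tcheck, separation)) next
      } else {
        t_mid <- stats::runif(1, 0.2 * clip_T, 0.8 * clip_T)
        start <- c(stats::runif(1, 60, width - 61),
                   stats::runif(1, 60, height - 61))
        amag <- stats::runif(1, 0, 20)
        aphi <- stats::runif(1, 0, 2 * pi)
        cand <- flight_track(id, start, heading, speed,
                             accel = amag * c(cos(aphi), sin(aphi)),
                             wingbeat_hz = wb, baseline = baseline,
                             amplitude = amplitude, t_ref = t_mid)
        interior <- .interior_frames(cand, cfg)
        if (.max_run(interior) < min_interior_frames) next
        # one pass through the view: a curving track that exits and
        # re-enters would legitimately split into two trajectories
        if (sum(rle(interior)$values) != 1) next
        if (preset == "clean" &&
            !.paths_separated_seq(cand, tracks, clip_T, separation)) next
      }
      tracks[[length(tracks) + 1L]] <- cand
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(sprintf(
        "random_scene: could not place insect %d under the '%s' preset",
        id, preset), call. = FALSE)
    }
  }
  list(tracks = tracks, cfg = cfg)
}

## Frames in which the track's whole per-frame blur (plus detector border
## margin and streak width) is inside the frame.
.interior_frames <- function(track, cfg, margin = 6) {
  vapply(seq_len(cfg$n_frames), function(i) {
    t0 <- (i - 1) / cfg$fps
    tt <- seq(t0, t0 + cfg$exposure, length.out = 16)
    pos <- track_position(track, tt)
    all(pos[, 1] >= margin & pos[, 1] <= cfg$width - 1 - margin &
        pos[, 2] >= margin & pos[, 2] <= cfg$height - 1 - margin)
  }, logical(1))
}

.max_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

.paths_separated_still <- function(cand, tracks, tcheck, separation) {
  pc <- track_position(cand, tcheck)
  for (tr in tracks) {
    po <- track_position(tr, tcheck)
    dmin <- min(sqrt(outer(pc[, 1], po[, 1], `-`)^2 +
                     outer(pc[, 2], po[, 2], `-`)^2))
    if (dmin < separation) return(FALSE)
  }
  TRUE
}

## Pairwise separation at time offsets up to 0.1 s (a follower insect at a
## small lag can still place blurs within linking range of the leader's,
## so simultaneous separation alone is not enough).
.paths_separated_seq <- function(cand, tracks, clip_T, separation,
                                 dt = 0.02, max_lag = 0.1) {
  t <- seq(0, clip_T, by = dt)
  pc <- track_position(cand, t)
  lags <- -round(max_lag / dt):round(max_lag / dt)
  n <- length(t)
  for (tr in tracks) {
    po <- track_position(tr, t)
    for (lg in lags) {
      ia <- seq(max(1, 1 + lg), min(n, n + lg))
      ib <- ia - lg
      d2 <- (pc[ia, 1] - po[ib, 1])^2 + (pc[ia, 2] - po[ib, 2])^2
      if (min(d2) < separation^2) return(FALSE)
    }
  }
  TRUE
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
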