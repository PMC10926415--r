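#' Tracking configuration
#'
#' @param dM_threshold Maximum matching distance (px) for a retained link
#'   (default 40 at 1080p; scale with frame size).
#' @param min_detections Minimum detections per kept trajectory
#'   (default 3).
#' @param min_mean_score Minimum mean detection score per kept trajectory
#'   (default 0.8).
#' @param roi Optional [circle()] region of interest; trajectories leaving
#'   it are removed to eliminate the directional bias of the rectangular
#'   frame.
#' @param detector A [detector_params()] used on the maximum images.
#' @return A list of class `"tracking_config"`.
#' @export
tracking_config <- function(dM_threshold = 40, min_detections = 3,
                            min_mean_score = 0.8, roi = NULL,
                            detector = detector_params()) {
  if (dM_threshold <= 0 || min_detections <= 0) {
    stop("tracking_config: thresholds must be positive", call. = FALSE)
  }
  if (min_mean_score < 0 || min_mean_score > 1) {
    stop("tracking_config: min_mean_score must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(roi) && !inherits(roi, "circle")) {
    stop("tracking_config: roi must be a circle", call. = FALSE)
  }
  structure(list(dM_threshold = dM_threshold,
                 min_detections = min_detections,
                 min_mean_score = min_mean_score, roi = roi,
                 detector = detector),
            class = "tracking_config")
}

#' Construct a detection
#'
#' An annotation bound to the maximum image it was found in. `pair_index`
#' is 1-based: pair `t` is the pixelwise maximum of frames `t` and `t + 1`.
#'
#' @param ann An [annotation()] (its score becomes the detection score).
#' @param pair_index Index of the maximum image (>= 1).
#' @return An object of class `"detection"`.
#' @export
detection <- function(ann, pair_index) {
  stopifnot(is_annotation(ann), pair_index >= 1)
  structure(list(annotation = ann, score = ann$score,
                 pair_index = as.integer(pair_index)),
            class = "detection")
}

#' Construct a trajectory
#'
#' @param detections List of [detection()] objects with strictly
#'   consecutive `pair_index` values.
#' @return An object of class `"trajectory"` with derived `n_detections`
#'   and `mean_score`.
#' @export
trajectory <- function(detections) {
  pi <- vapply(detections, `[[`, integer(1), "pair_index")
  if (length(pi) > 1 && any(diff(pi) != 1L)) {
    stop("trajectory: pair_index values must be strictly consecutive",
         call. = FALSE)
  }
  structure(list(detections = detections,
                 n_detections = length(detections),
                 mean_score = mean(vapply(detections, `[[`, numeric(1),
                                          "score"))),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d detections, pairs %d-%d, mean score %.3f>\n",
              x$n_detections, x$detections[[1]]$pair_index,
              x$detections[[x$n_detections]]$pair_index, x$mean_score))
  invisible(x)
}

#' Pairwise maximum images of a frame sequence
#'
#' Element `i` is the pixelwise maximum of frames `i` and `i + 1` —
#' equivalent to doubling the exposure, so the consecutive motion blurs of
#' one insect overlap within each maximum image and can be chained.
#'
#' @param frames List of >= 2 frames with identical dimensions.
#' @return List of `length(frames) - 1` maximum images.
#' @export
pairwise_maximum <- function(frames) {
  if (length(frames) < 2) {
    stop("pairwise_maximum: at least 2 frames required", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop(sprintf(
      "pairwise_maximum: mismatched frame dimensions (%s)",
      paste(apply(dims, 2, paste, collapse = "x"), collapse = ", ")),
      call. = FALSE)
  }
  lapply(seq_len(length(frames) - 1),
         function(i) pmax(frames[[i]], frames[[i + 1]]))
}

#' Link detections between two consecutive time steps
#'
#' Builds the matching-distance cost matrix between the polyline
#' detections of pair `t` and pair `t + 1` and solves the assignment
#' problem, pruning links above `dM_threshold`. Circle and point
#' detections never participate in linking (their matching distance is
#' undefined); they form singleton trajectories instead.
#'
#' @param dets_t,dets_t1 Lists of [detection()] objects.
#' @param cfg A [tracking_config()].
#' @return Integer matrix with columns `row` (index into `dets_t`) and
#'   `col` (index into `dets_t1`).
#' @export
link_detections <- function(dets_t, dets_t1, cfg = tracking_config()) {
  it <- which(vapply(dets_t, function(d) d$annotation$kind, character(1)) ==
                "polyline")
  it1 <- which(vapply(dets_t1, function(d) d$annotation$kind, character(1)) ==
                 "polyline")
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  if (length(it) == 0 || length(it1) == 0) return(empty)
  cost <- matrix(0, length(it), length(it1))
  for (i in seq_along(it)) {
    for (j in seq_along(it1)) {
      cost[i, j] <- matching_distance(dets_t[[it[i]]]$annotation$shape,
                                      dets_t1[[it1[j]]]$annotation$shape)
    }
  }
  pairs <- solve_assignment(cost, cfg$dM_threshold)
  if (nrow(pairs) == 0) return(empty)
  cbind(row = it[pairs[, 1]], col = it1[pairs[, 2]])
}

#' Build trajectories from per-pair detection lists
#'
#' Iterates the linking procedure over consecutive pair indices: linked
#' detections extend trajectories, unlinked detections start new ones.
#' Every detection ends up in exactly one trajectory.
#'
#' @param per_pair List (indexed by pair) of lists of [detection()]
#'   objects; element `t` must hold detections with `pair_index == t`.
#' @param cfg A [tracking_config()].
#' @return List of [trajectory()] objects.
#' @export
build_trajectories <- function(per_pair, cfg = tracking_config()) {
  chains <- list()   # each: list(dets = list of detection, last_pair, kind)
  for (t in seq_along(per_pair)) {
    dets <- per_pair[[t]]
    if (length(dets) > 0) {
      stopifnot(all(vapply(dets, `[[`, integer(1), "pair_index") == t))
    }
    active <- which(vapply(chains, function(ch) {
      ch$last_pair == t - 1L && ch$kind == "polyline"
    }, logical(1)))
    linked_new <- integer(0)
    if (length(active) > 0 && length(dets) > 0) {
      last_dets <- lapply(chains[active], function(ch) {
        ch$dets[[length(ch$dets)]]
      })
      links <- link_detections(last_dets, dets, cfg)
      for (k in seq_len(nrow(links))) {
        ci <- active[links[k, 1]]
        di <- links[k, 2]
        chains[[ci]]$dets <- c(chains[[ci]]$dets, dets[di])
        chains[[ci]]$last_pair <- t
        linked_new <- c(linked_new, di)
      }
    }
    for (di in setdiff(seq_along(dets), linked_new)) {
      chains[[length(chains) + 1L]] <- list(
        dets = dets[di], last_pair = t,
        kind = dets[[di]]$annotation$kind)
    }
  }
  lapply(chains, function(ch) trajectory(ch$dets))
}

#' Filter trajectories by length and mean score
#'
#' Removes trajectories with fewer than `min_detections` detections, then
#' those with mean detection score below `min_mean_score` (in that order;
#' the result is order-independent but the order is pinned for
#' reproducible stage logs).
#'
#' @param trajs List of [trajectory()] objects.
#' @param cfg A [tracking_config()].
#' @return Filtered list, with attribute `"stage_counts"` giving the count
#'   after each stage.
#' @export
filter_trajectories <- function(trajs, cfg = tracking_config()) {
  n0 <- length(trajs)
  trajs <- trajs[vapply(trajs, `[[`, integer(1), "n_detections") >=
                   cfg$min_detections]
  n1 <- length(trajs)
  trajs <- trajs[vapply(trajs, `[[`, numeric(1), "mean_score") >=
                   cfg$min_mean_score]
  attr(trajs, "stage_counts") <- c(input = n0, after_length = n1,
                                   after_score = length(trajs))
  trajs
}

#' Constrain trajectories to a circular region of interest
#'
#' A trajectory is kept iff every vertex of every one of its polyline
#' detections lies at distance <= `r` (inclusive) from the ROI centre; by
#' convexity the vertex test covers whole segments. Kept trajectories are
#' unchanged.
#'
#' @param trajs List of [trajectory()] objects.
#' @param roi A [circle()].
#' @return Filtered list.
#' @export
roi_filter <- function(trajs, roi) {
  stopifnot(inherits(roi, "circle"))
  keep <- vapply(trajs, function(tr) {
    all(vapply(tr$detections, function(d) {
      if (d$annotation$kind != "polyline") return(TRUE)
      v <- unclass(d$annotation$shape)
      all(sqrt((v[, 1] - roi$cx)^2 + (v[, 2] - roi$cy)^2) <= roi$r)
    }, logical(1)))
  }, logical(1))
  trajs[keep]
}

#' Displacement direction of a trajectory
#'
#' Orients the chain of polyline detections consistently (each detection's
#' start vertex is the endpoint nearer the previous detection's oriented
#' end; the first detection is oriented so that its end lies nearer the
#' second detection's chain) and returns the angle of the net displacement
#' from the first oriented start to the last oriented end.
#'
#' Image coordinates: y increases down the image, so 90 degrees points
#' down-image. Conversion to compass bearings requires the camera
#' orientation and is left to the caller.
#'
#' @param traj A [trajectory()] with >= 2 polyline detections.
#' @return Angle in degrees in `(-180, 180]`.
#' @export
trajectory_direction <- function(traj) {
  polys <- purrr::keep(traj$detections,
                       function(d) d$annotation$kind == "polyline")
  if (length(polys) < 2) {
    stop("trajectory_direction: undefined for fewer than 2 polyline detections",
         call. = FALSE)
  }
  P <- lapply(polys, function(d) unclass(d$annotation$shape))
  ends <- function(v) list(first = v[1, ], last = v[nrow(v), ])
  # orient the first detection toward the second chain
  e1 <- ends(P[[1]])
  d_first <- point_to_polyline_distance(e1$first, polys[[2]]$annotation$shape)
  d_last <- point_to_polyline_distance(e1$last, polys[[2]]$annotation$shape)
  if (d_first < d_last) P[[1]] <- P[[1]][rev(seq_len(nrow(P[[1]]))), ]
  for (k in seq_along(P)[-1]) {
    prev_end <- P[[k - 1]][nrow(P[[k - 1]]), ]
    ek <- ends(P[[k]])
    if (sum((ek$last - prev_end)^2) < sum((ek$first - prev_end)^2)) {
      P[[k]] <- P[[k]][rev(seq_len(nrow(P[[k]]))), ]
    }
  }
  start <- P[[1]][1, ]
  end <- P[[length(P)]][nrow(P[[length(P)]]), ]
  ang <- atan2(end[2] - start[2], end[1] - start[1]) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  unname(ang)
}

#' Track insects across a batch of frames
#'
#' The full tracking pipeline: pairwise maximum images, detection on each
#' maximum image, assignment-based linking into trajectories, then the
#' length, score and (when configured) ROI filters. Deterministic given
#' the frames and configuration. Trajectories do not bridge across
#' batches; process one clip per call.
#'
#' @param frames List of >= 2 frames (numeric matrices, same dimensions).
#' @param cfg A [tracking_config()].
#' @return An object of class `"trajectory_set"`: the list of kept
#'   [trajectory()] objects, with attributes `"stage_counts"` (detections
#'   and trajectory counts at each pipeline stage) and `"config"`.
#' @seealso [tidy.trajectory_set()], [glance.trajectory_set()],
#'   [autoplot.trajectory_set()]
#' @export
track_batch <- function(frames, cfg = tracking_config()) {
  maxes <- pairwise_maximum(frames)
  per_pair <- lapply(seq_along(maxes), function(t) {
    anns <- annotate_image(maxes[[t]], cfg$detector)
    lapply(anns, detection, pair_index = t)
  })
  n_det <- sum(lengths(per_pair))
  trajs <- build_trajectories(per_pair, cfg)
  n_built <- length(trajs)
  trajs <- filter_trajectories(trajs, cfg)
  fc <- attr(trajs, "stage_counts")
  n_roi <- NA_integer_
  if (!is.null(cfg$roi)) {
    trajs <- roi_filter(trajs, cfg$roi)
    n_roi <- length(trajs)
  }
  structure(unclass(trajs),
            stage_counts = c(detections = n_det, built = n_built,
                             after_length = unname(fc["after_length"]),
                             after_score = unname(fc["after_score"]),
                             after_roi = n_roi),
            config = cfg,
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  sc <- attr(x, "stage_counts")
  cat(sprintf("<trajectory_set: %d trajectories from %d detections>\n",
              length(x), sc[["detections"]]))
  invisible(x)
}
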