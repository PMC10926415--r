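#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trajectory set into a flat detection table
#'
#' One row per detection: trajectory id, maximum-image index, score, kind,
#' detection midpoint, and the per-trajectory summaries (length, mean
#' score, displacement direction where defined).
#'
#' @param x A `trajectory_set` from [track_batch()].
#' @param ... Unused.
#' @return A tibble with columns `trajectory_id`, `pair_index`, `score`,
#'   `kind`, `x`, `y`, `n_detections`, `mean_score`, `direction_deg`.
#' @export
tidy.trajectory_set <- function(x, ...) {
  skeleton <- tibble::tibble(
    trajectory_id = integer(0), pair_index = integer(0),
    score = numeric(0), kind = character(0), x = numeric(0),
    y = numeric(0), n_detections = integer(0), mean_score = numeric(0),
    direction_deg = numeric(0))
  if (length(x) == 0) return(skeleton)
  purrr::map_dfr(seq_along(x), function(ti) {
    tr <- x[[ti]]
    dir <- tryCatch(trajectory_direction(tr), error = function(e) NA_real_)
    purrr::map_dfr(tr$detections, function(d) {
      bb <- bbox_of(d$annotation)
      tibble::tibble(
        trajectory_id = ti, pair_index = d$pair_index, score = d$score,
        kind = d$annotation$kind,
        x = (bb[[1]] + bb[[3]]) / 2, y = (bb[[2]] + bb[[4]]) / 2,
        n_detections = tr$n_detections, mean_score = tr$mean_score,
        direction_deg = dir)
    })
  })
}

#' One-row summary of a trajectory set
#'
#' @param x A `trajectory_set` from [track_batch()].
#' @param ... Unused.
#' @return A tibble with `n_trajectories`, `n_detections` (total raw
#'   detections), `n_built`, `n_after_length`, `n_after_score`,
#'   `n_after_roi`, `mean_length` and `mean_score`.
#' @export
glance.trajectory_set <- function(x, ...) {
  sc <- attr(x, "stage_counts")
  tibble::tibble(
    n_trajectories = length(x),
    n_detections = unname(sc[["detections"]]),
    n_built = unname(sc[["built"]]),
    n_after_length = unname(sc[["after_length"]]),
    n_after_score = unname(sc[["after_score"]]),
    n_after_roi = unname(sc[["after_roi"]]),
    mean_length = if (length(x)) {
      mean(vapply(x, `[[`, integer(1), "n_detections"))
    } else NA_real_,
    mean_score = if (length(x)) {
      mean(vapply(x, `[[`, numeric(1), "mean_score"))
    } else NA_real_)
}

#' Plot the trajectories of a trajectory set
#'
#' Polyline detections are drawn in image coordinates (y axis reversed),
#' coloured by trajectory — the standard diagnostic overlay for checking
#' a clip's tracking result.
#'
#' @param object A `trajectory_set` from [track_batch()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_set <- function(object, ...) {
  segs <- purrr::map_dfr(seq_along(object), function(ti) {
    purrr::map_dfr(object[[ti]]$detections, function(d) {
      if (d$annotation$kind != "polyline") return(NULL)
      v <- unclass(d$annotation$shape)
      tibble::tibble(trajectory_id = factor(ti),
                     pair_index = d$pair_index,
                     x = v[, 1], y = v[, 2],
                     piece = paste(ti, d$pair_index))
    })
  })
  ggplot2::ggplot(segs, ggplot2::aes(x = .data$x, y = .data$y,
                                     group = .data$piece,
                                     colour = .data$trajectory_id)) +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "trajectory") +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#'
#' @param object A `pr_curve` from [precision_recall_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall,
                                       y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}

#' Plot a blur intensity profile
#'
#' @param object A `blur_profile` from [extract_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.blur_profile <- function(object, ...) {
  df <- tibble::tibble(arc = seq_along(object$samples) - 1,
                       intensity = object$samples)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arc, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arc length (px)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Tidy a VIA project into a region table
#'
#' @param x A [via_project()].
#' @param ... Unused.
#' @return A tibble with one row per region: `filename`, `region`, `kind`,
#'   `score`, bounding box and polyline arc length.
#' @export
tidy.via_project <- function(x, ...) {
  purrr::map_dfr(x$records, function(r) {
    tb <- annotations_tbl(r$regions)
    if (nrow(tb) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(filename = r$filename), tb)
  })
}

#' @importFrom rlang .data
NULL
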