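#' Construct an annotation
#'
#' An annotation marks one insect motion blur in one image: a polyline for a
#' fully visible blur, an enclosing circle for a blur clipped by the frame
#' edge or occluded, or a point for a blur too short to trace. Automatic
#' annotations carry a detection confidence score in `[0, 1]`.
#'
#' @param shape A [polyline()], [circle()] or [point_mark()].
#' @param score Optional detection score in `[0, 1]` (`NA` for manual
#'   annotations).
#' @param attrs Optional named list of extra region attributes (character
#'   values) preserved through VIA round trips, e.g. a trajectory id.
#' @return An object of class `"annotation"` with fields `kind`
#'   (`"polyline"`, `"circle"` or `"point"`), `shape`, `score`, `attrs`.
#' @examples
#' annotation(polyline(c(0, 10), c(0, 0)), score = 0.9)
#' @export
annotation <- function(shape, score = NA_real_, attrs = list()) {
  kind <- switch(class(shape)[1],
    polyline = "polyline",
    circle = "circle",
    point_mark = "point",
    stop("annotation: shape must be a polyline, circle or point_mark",
         call. = FALSE)
  )
  if (!is.na(score) && (score < 0 || score > 1)) {
    stop("annotation: score must be in [0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, shape = shape, score = as.numeric(score),
                 attrs = attrs),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation: %s%s>\n", x$kind,
              if (is.na(x$score)) "" else sprintf(", score %.3f", x$score)))
  invisible(x)
}

is_annotation <- function(x) inherits(x, "annotation")

#' Tidy a list of annotations into a tibble
#'
#' One row per annotation with its kind, score, bounding box and (for
#' polylines) arc length.
#'
#' @param anns List of [annotation()] objects.
#' @return A tibble.
#' @export
annotations_tbl <- function(anns) {
  purrr::map_dfr(seq_along(anns), function(i) {
    a <- anns[[i]]
    bb <- bbox_of(a)
    tibble::tibble(
      region = i, kind = a$kind, score = a$score,
      x_min = bb[[1]], y_min = bb[[2]], x_max = bb[[3]], y_max = bb[[4]],
      arc_length = if (a$kind == "polyline") polyline_length(a$shape)
                   else NA_real_
    )
  })
}
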