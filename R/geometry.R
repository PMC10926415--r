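#' Construct a polyline
#'
#' A polyline is an ordered chain of 2-D vertices tracing the path of a
#' motion-blur streak. Coordinates follow the VIA pixel convention:
#' `x` is the column and `y` the row, origin at the centre of the top-left
#' pixel, 0-based, sub-pixel positions allowed.
#'
#' @param x,y Numeric vectors of equal length (>= 2) with the vertex
#'   coordinates in pixels.
#' @return A numeric matrix of class `"polyline"` with columns `x` and `y`.
#' @examples
#' P <- polyline(c(0, 3), c(0, 4))
#' polyline_length(P) # 5
#' @export
polyline <- function(x, y) {
  if (length(x) != length(y)) {
    stop("polyline: x and y must have the same length", call. = FALSE)
  }
  if (length(x) < 2) {
    stop("polyline: at least 2 vertices required", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("polyline: all coordinates must be finite", call. = FALSE)
  }
  v <- cbind(x = as.numeric(x), y = as.numeric(y))
  dup <- rowSums(abs(diff(v))) == 0
  if (any(dup)) {
    stop("polyline: consecutive vertices must be distinct", call. = FALSE)
  }
  structure(v, class = "polyline")
}

#' @export
print.polyline <- function(x, ...) {
  cat(sprintf("<polyline: %d vertices, length %.2f px>\n",
              nrow(x), polyline_length(x)))
  invisible(x)
}

is_polyline <- function(x) inherits(x, "polyline")

#' Construct a circle or point mark
#'
#' Circles annotate motion blurs that are clipped by the frame edge or
#' occluded; point marks annotate blurs too short to trace.
#'
#' @param cx,cy Centre / position in pixels.
#' @param r Radius in pixels (> 0).
#' @return An object of class `"circle"` or `"point_mark"`.
#' @export
circle <- function(cx, cy, r) {
  stopifnot(is.finite(cx), is.finite(cy), is.finite(r))
  if (r <= 0) stop("circle: radius must be > 0", call. = FALSE)
  structure(list(cx = as.numeric(cx), cy = as.numeric(cy), r = as.numeric(r)),
            class = "circle")
}

#' @rdname circle
#' @export
point_mark <- function(cx, cy) {
  stopifnot(is.finite(cx), is.finite(cy))
  structure(list(cx = as.numeric(cx), cy = as.numeric(cy)),
            class = "point_mark")
}

#' Arc length of a polyline
#'
#' @param P A [polyline()].
#' @return Total Euclidean length in pixels.
#' @export
polyline_length <- function(P) {
  d <- diff(unclass(P))
  sum(sqrt(rowSums(d^2)))
}

## Distances from a set of points (k x 2) to one segment a-b, exact
## (projection clamped to the segment).
.points_to_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  dx <- pts[, 1] - a[1]
  dy <- pts[, 2] - a[2]
  t <- if (len2 > 0) pmin(1, pmax(0, (dx * ab[1] + dy * ab[2]) / len2)) else 0
  sqrt((dx - t * ab[1])^2 + (dy - t * ab[2])^2)
}

## Minimum distance from each of k points to polyline P (k-vector).
.points_to_polyline <- function(pts, P) {
  P <- unclass(P)
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(P) - 1)) {
    d <- pmin(d, .points_to_segment(pts, P[i, ], P[i + 1, ]))
  }
  d
}

#' Distance from a point to a polyline
#'
#' Exact minimum over all segments of the point-to-segment distance.
#'
#' @param pt Numeric length-2 vector `c(x, y)`.
#' @param P A [polyline()].
#' @return Distance in pixels (0 iff the point lies on the polyline).
#' @export
point_to_polyline_distance <- function(pt, P) {
  .points_to_polyline(matrix(pt, 1, 2), P)[1]
}

#' Matching distance between two polylines
#'
#' The linking cost used when chaining detections across maximum images:
#' the second-smallest element of the multiset of the four endpoint-to-
#' other-polyline distances
#' \{d(a_first, Pb), d(a_last, Pb), d(b_first, Pa), d(b_last, Pa)\}.
#' Near zero for blurs that continue one another (abutting or overlapping
#' end-to-end), large for chance crossings at an angle. Symmetric, but not
#' a metric: distinct abutting segments score 0.
#'
#' @param Pa,Pb Polylines.
#' @return Matching distance in pixels.
#' @export
matching_distance <- function(Pa, Pb) {
  ea <- unclass(Pa)[c(1, nrow(Pa)), , drop = FALSE]
  eb <- unclass(Pb)[c(1, nrow(Pb)), , drop = FALSE]
  d <- c(.points_to_polyline(ea, Pb), .points_to_polyline(eb, Pa))
  sort(d)[2]
}

#' Resample a polyline at a fixed arc-length step
#'
#' @param P A [polyline()].
#' @param step Arc-length step in pixels.
#' @return Matrix of sample points (includes both endpoints); with
#'   `tangents = TRUE`, a list with `points` and unit `tangents`.
#' @param tangents Also return per-sample unit tangent vectors.
#' @keywords internal
#' @export
resample_polyline <- function(P, step = 0.5, tangents = FALSE) {
  V <- unclass(P)
  seg <- diff(V)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  L <- cum[length(cum)]
  s <- unique(c(seq(0, L, by = step), L))
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(V) - 1)
  frac <- (s - cum[idx]) / seglen[idx]
  pts <- V[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  if (!tangents) return(pts)
  tg <- seg[idx, , drop = FALSE] / seglen[idx]
  list(points = pts, tangents = tg, arc = s)
}

#' Hausdorff distance between two polylines
#'
#' Symmetric Hausdorff distance between the polylines as point sets,
#' computed by sampling both at `step` arc-length resolution and taking
#' exact point-to-polyline distances from each sample set to the other
#' polyline. Accuracy is bounded by the sampling step (+/- 0.5 px at the
#' default).
#'
#' @param Pa,Pb Polylines.
#' @param step Resampling step in pixels (default 0.5).
#' @return Hausdorff distance in pixels.
#' @export
hausdorff_distance <- function(Pa, Pb, step = 0.5) {
  sa <- resample_polyline(Pa, step)
  sb <- resample_polyline(Pb, step)
  max(max(.points_to_polyline(sa, Pb)), max(.points_to_polyline(sb, Pa)))
}

#' Axis-aligned bounding box of an annotation or shape
#'
#' @param a An [annotation()], [polyline()], [circle()] or [point_mark()].
#' @return Named numeric vector `c(x_min, y_min, x_max, y_max)`.
#' @export
bbox_of <- function(a) {
  UseMethod("bbox_of")
}

#' @export
bbox_of.annotation <- function(a) bbox_of(a$shape)

#' @export
bbox_of.polyline <- function(a) {
  v <- unclass(a)
  c(x_min = min(v[, 1]), y_min = min(v[, 2]),
    x_max = max(v[, 1]), y_max = max(v[, 2]))
}

#' @export
bbox_of.circle <- function(a) {
  c(x_min = a$cx - a$r, y_min = a$cy - a$r,
    x_max = a$cx + a$r, y_max = a$cy + a$r)
}

#' @export
bbox_of.point_mark <- function(a) {
  c(x_min = a$cx, y_min = a$cy, x_max = a$cx, y_max = a$cy)
}

#' Intersection-over-union of two bounding boxes
#'
#' @param b1,b2 Boxes as returned by [bbox_of()].
#' @return Ratio in `[0, 1]`; 0 when disjoint or when both boxes are
#'   degenerate (zero area); 1 only for identical non-degenerate boxes.
#' @export
bbox_iou <- function(b1, b2) {
  a1 <- (b1[3] - b1[1]) * (b1[4] - b1[2])
  a2 <- (b2[3] - b2[1]) * (b2[4] - b2[2])
  if (a1 == 0 && a2 == 0) return(0)
  iw <- min(b1[3], b2[3]) - max(b1[1], b2[1])
  ih <- min(b1[4], b2[4]) - max(b1[2], b2[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  unname(inter / (a1 + a2 - inter))
}

#' Minimum enclosing circle of a point set
#'
#' Welzl's algorithm applied to the convex hull vertices (deterministic
#' order, no shuffling; hull sizes here are small).
#'
#' @param pts Numeric matrix (k x 2) of x,y coordinates.
#' @return A [circle()].
#' @export
min_enclosing_circle <- function(pts) {
  pts <- unique(pts[, 1:2, drop = FALSE])
  if (nrow(pts) == 1) {
    return(structure(list(cx = pts[1, 1], cy = pts[1, 2], r = 0),
                     class = "circle"))
  }
  if (nrow(pts) > 3) {
    h <- grDevices::chull(pts[, 1], pts[, 2])
    pts <- pts[h, , drop = FALSE]
  }
  mec <- .welzl(pts, matrix(numeric(0), 0, 2))
  structure(list(cx = mec[1], cy = mec[2], r = sqrt(mec[3])),
            class = "circle")
}

## Welzl recursion; returns c(cx, cy, r^2).
.welzl <- function(pts, boundary) {
  if (nrow(pts) == 0 || nrow(boundary) == 3) {
    return(.circle_from_boundary(boundary))
  }
  p <- pts[nrow(pts), , drop = FALSE]
  rest <- pts[-nrow(pts), , drop = FALSE]
  c0 <- .welzl(rest, boundary)
  if ((p[1] - c0[1])^2 + (p[2] - c0[2])^2 <= c0[3] * (1 + 1e-12) + 1e-12) {
    return(c0)
  }
  .welzl(rest, rbind(boundary, p))
}

.circle_from_boundary <- function(b) {
  n <- nrow(b)
  if (n == 0) return(c(0, 0, -1))
  if (n == 1) return(c(b[1, 1], b[1, 2], 0))
  if (n == 2) {
    c(mean(b[, 1]), mean(b[, 2]), sum((b[1, ] - b[2, ])^2) / 4)
  } else {
    ax <- b[1, 1]; ay <- b[1, 2]
    bx <- b[2, 1]; by <- b[2, 2]
    cx <- b[3, 1]; cy <- b[3, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) {
      # collinear boundary: fall back to the farthest pair
      dd <- as.matrix(stats::dist(b))
      ij <- which(dd == max(dd), arr.ind = TRUE)[1, ]
      return(.circle_from_boundary(b[ij, , drop = FALSE]))
    }
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
}
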