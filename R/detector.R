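#' Detector parameters
#'
#' Settings for the classical streak detector. The detector binarizes a
#' frame at `background median + threshold_k * MAD`, closes small gaps,
#' extracts 8-connected components, and converts each surviving component
#' to an annotation. It is a deterministic, pluggable stand-in for a
#' learned instance-segmentation backend exposing the same contract
#' (masks in, scored annotations out).
#'
#' @param threshold_k Binarization threshold in MAD multiples above the
#'   background median (default 8).
#' @param min_area Minimum component area in pixels (default 20).
#' @param closing_radius Morphological closing radius in pixels (default 1).
#' @param border_margin Pixels from the frame edge within which a component
#'   counts as touching the border (default 2).
#' @param min_polyline_length Minimum fitted arc length in pixels below
#'   which a blur is annotated as a point (default 10).
#' @param polyline_order Polynomial degree of the mask-to-polyline
#'   regression (default 2; flight paths within one exposure are
#'   well-modelled by low-order curves).
#' @param vertices_per_polyline Vertex count of inferred polylines
#'   (default 10).
#' @return A list of class `"detector_params"`.
#' @export
detector_params <- function(threshold_k = 8, min_area = 20,
                            closing_radius = 1, border_margin = 2,
                            min_polyline_length = 10, polyline_order = 2,
                            vertices_per_polyline = 10) {
  p <- list(threshold_k = threshold_k, min_area = min_area,
            closing_radius = closing_radius, border_margin = border_margin,
            min_polyline_length = min_polyline_length,
            polyline_order = polyline_order,
            vertices_per_polyline = vertices_per_polyline)
  if (any(unlist(p) <= 0)) {
    stop("detector_params: all parameters must be positive", call. = FALSE)
  }
  if (polyline_order < 1) {
    stop("detector_params: polyline_order must be >= 1", call. = FALSE)
  }
  if (vertices_per_polyline < polyline_order + 1) {
    stop("detector_params: vertices_per_polyline must be >= polyline_order + 1",
         call. = FALSE)
  }
  structure(p, class = "detector_params")
}

## Robust background statistics on a stride-4 pixel subsample (noise is
## i.i.d. and streaks sparse, so the subsample is statistically equivalent
## and four times cheaper to sort).
.background_stats <- function(frame) {
  sub <- frame[seq(1, length(frame), by = 4L)]
  med <- stats::median(sub)
  madv <- stats::median(abs(sub - med)) * 1.4826
  c(median = med, mad = madv)
}

#' Segment bright streaks in a frame
#'
#' Binarize at `median + threshold_k * MAD` (per-frame robust background
#' statistics), apply morphological closing, label 8-connected components
#' and drop those smaller than `min_area`. A frame with zero MAD (uniform)
#' yields no detections.
#'
#' @param frame Numeric matrix in `[0, 255]`.
#' @param params A [detector_params()].
#' @return List of streak masks; each is a list with `pixels` (n x 2 matrix
#'   of 0-based x,y pixel coordinates), `mean_intensity`, `touches_border`,
#'   `background_median` and `frame_dim`.
#' @export
segment_streaks <- function(frame, params = detector_params()) {
  .check_frame(frame)
  bg <- .background_stats(frame)
  if (bg[["mad"]] == 0) return(list())
  bin <- frame > bg[["median"]] + params$threshold_k * bg[["mad"]]
  if (!any(bin)) return(list())
  brush <- EBImage::makeBrush(2L * as.integer(params$closing_radius) + 1L,
                              shape = "disc")
  closed <- EBImage::closing(bin, brush)
  lab <- .label8(closed)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  idx <- which(lab > 0)
  comp <- split(idx, lab[idx])
  H <- nrow(frame); W <- ncol(frame)
  m <- as.integer(params$border_margin)
  masks <- list()
  for (px_idx in comp) {
    if (length(px_idx) < params$min_area) next
    row <- (px_idx - 1L) %% H         # 0-based row  = y
    col <- (px_idx - 1L) %/% H        # 0-based col  = x
    touches <- any(col < m | col > W - 1L - m | row < m | row > H - 1L - m)
    masks[[length(masks) + 1L]] <- structure(list(
      pixels = cbind(x = as.numeric(col), y = as.numeric(row)),
      mean_intensity = mean(frame[px_idx]),
      touches_border = touches,
      background_median = bg[["median"]],
      frame_dim = c(H, W)
    ), class = "streak_mask")
  }
  masks
}

## 8-connected labelling: EBImage::bwlabel is 4-connected, so merge label
## pairs that touch diagonally.
.label8 <- function(bin) {
  lab <- EBImage::bwlabel(bin)
  n <- max(lab)
  if (n < 2) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-H, -1]; b2 <- lab[-1, -W]    # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- c(0L, as.integer(root))
  matrix(remap[lab + 1L], H, W)
}

#' Detection confidence of a streak mask
#'
#' Contrast-based score: `(mean_on - background_median) /
#' (255 - background_median)`, clipped to `[0, 1]` (0 when the background
#' median is saturated). Monotone in streak contrast, so thresholding on
#' it orders detections from faint to bright.
#'
#' `mean_on` is the on-streak brightness: the mean frame intensity sampled
#' (bilinearly, at 1 px steps) along the mask's fitted centerline. The
#' segmented mask also contains the streak's dim anti-aliased rim, whose
#' pixels would dilute a plain mask mean — a saturated streak must score
#' 1, and only the centerline mean achieves that. When `frame` is omitted
#' or the centerline is degenerate, the mask pixel mean is used instead.
#'
#' @param mask A streak mask from [segment_streaks()].
#' @param frame The frame the mask was segmented from (optional but
#'   recommended; enables centerline sampling).
#' @return Score in `[0, 1]`.
#' @export
detection_score <- function(mask, frame = NULL) {
  bg <- mask$background_median
  if (bg >= 255) return(0)
  mean_on <- mask$mean_intensity
  if (!is.null(frame)) {
    ctr <- tryCatch(mask_to_polyline(mask, 2, 10),
                    blurtrack_degenerate_mask = function(e) NULL)
    if (!is.null(ctr)) {
      pts <- resample_polyline(ctr, 1)
      pts[, 1] <- pmin(pmax(pts[, 1], 0), ncol(frame) - 1)
      pts[, 2] <- pmin(pmax(pts[, 2], 0), nrow(frame) - 1)
      mean_on <- mean(.bilinear(frame, pts[, 1], pts[, 2]))
    }
  }
  min(1, max(0, (mean_on - bg) / (255 - bg)))
}

#' Infer a polyline from a streak mask by polynomial regression
#'
#' Mask pixel coordinates are rotated into their principal-axis frame (the
#' direction of largest coordinate variance; isotropic ties break toward
#' the x-axis), a least-squares polynomial `v = sum c_k u^k` is fitted, and
#' the fit is evaluated at `n_vertices` equally spaced positions and
#' rotated back. When the mask has fewer distinct principal-axis
#' coordinates than `order + 1`, the order falls back to what the data
#' support (down to 1); a mask with a single distinct coordinate raises a
#' degenerate-mask error (condition class `"blurtrack_degenerate_mask"`).
#'
#' @param mask A streak mask from [segment_streaks()].
#' @param order Polynomial degree (default 2).
#' @param n_vertices Number of polyline vertices (default 10).
#' @return A [polyline()].
#' @export
mask_to_polyline <- function(mask, order = 2, n_vertices = 10) {
  pts <- mask$pixels
  mu <- colMeans(pts)
  ctr <- sweep(pts, 2, mu)
  cv <- crossprod(ctr) / nrow(ctr)
  eg <- eigen(cv, symmetric = TRUE)
  if (abs(eg$values[1] - eg$values[2]) < 1e-12) {
    v1 <- c(1, 0)
  } else {
    v1 <- eg$vectors[, 1]
  }
  # deterministic sign: principal axis points toward +x (or +y if vertical)
  if (v1[1] < 0 || (v1[1] == 0 && v1[2] < 0)) v1 <- -v1
  v2 <- c(-v1[2], v1[1])
  u <- ctr %*% v1
  v <- ctr %*% v2
  n_distinct <- length(unique(round(u, 9)))
  if (n_distinct < 2) {
    stop(structure(class = c("blurtrack_degenerate_mask", "error",
                             "condition"),
                   list(message = "mask_to_polyline: degenerate mask (single principal-axis coordinate)",
                        call = NULL)))
  }
  ord <- min(order, n_distinct - 1)
  X <- outer(as.numeric(u), 0:ord, `^`)
  cf <- stats::lsfit(X, v, intercept = FALSE)$coefficients
  ug <- seq(min(u), max(u), length.out = n_vertices)
  vg <- outer(ug, 0:ord, `^`) %*% cf
  out <- cbind(mu[1] + ug * v1[1] + vg * v2[1],
               mu[2] + ug * v1[2] + vg * v2[2])
  keep <- c(TRUE, rowSums(abs(diff(out))) > 0)
  out <- out[keep, , drop = FALSE]
  polyline(out[, 1], out[, 2])
}

#' Convert a streak mask to an annotation
#'
#' A mask touching the frame border becomes a circle annotation (minimum
#' enclosing circle of its pixels), since the blur may be clipped and its
#' path cannot be traced reliably. Interior masks get a fitted polyline;
#' if the fitted arc length falls below `min_polyline_length` — too short
#' to show a wingbeat — the blur is annotated as a point at the mask
#' centroid. The detection score is attached in every case.
#'
#' @param mask A streak mask from [segment_streaks()].
#' @param frame The frame the mask came from (for centerline scoring).
#' @param params A [detector_params()].
#' @return An [annotation()].
#' @export
classify_and_annotate <- function(mask, frame = NULL,
                                  params = detector_params()) {
  score <- detection_score(mask, frame)
  if (mask$touches_border) {
    return(annotation(min_enclosing_circle(mask$pixels), score))
  }
  P <- tryCatch(
    mask_to_polyline(mask, params$polyline_order,
                     params$vertices_per_polyline),
    blurtrack_degenerate_mask = function(e) NULL
  )
  if (is.null(P) || polyline_length(P) < params$min_polyline_length) {
    mu <- colMeans(mask$pixels)
    return(annotation(point_mark(mu[1], mu[2]), score))
  }
  annotation(P, score)
}

#' Detect and annotate all streaks in a frame
#'
#' Composition of [segment_streaks()] and [classify_and_annotate()]; the
#' result is sorted by bounding-box `x_min`, then `y_min`, so identical
#' frames always yield identical annotation lists.
#'
#' @param frame Numeric matrix in `[0, 255]`.
#' @param params A [detector_params()].
#' @return List of [annotation()] objects.
#' @export
annotate_image <- function(frame, params = detector_params()) {
  masks <- segment_streaks(frame, params)
  anns <- lapply(masks, classify_and_annotate, frame = frame,
                 params = params)
  if (length(anns) == 0) return(anns)
  bb <- t(vapply(anns, bbox_of, numeric(4)))
  anns[order(bb[, 1], bb[, 2])]
}
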