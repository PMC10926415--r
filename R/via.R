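#' Construct an image record
#'
#' One entry of a VIA project: an image filename, its file size (or -1 when
#' unknown, e.g. annotation files shipped without the images), the ordered
#' list of region annotations, and an optional exposure time.
#'
#' @param filename Non-empty image filename.
#' @param file_size Size in bytes; -1 when unknown.
#' @param regions List of [annotation()] objects.
#' @param exposure_time Optional exposure in seconds (> 0).
#' @return An object of class `"image_record"`.
#' @export
image_record <- function(filename, file_size = -1L, regions = list(),
                         exposure_time = NULL) {
  if (!is.character(filename) || nchar(filename) == 0) {
    stop("image_record: filename must be a non-empty string", call. = FALSE)
  }
  if (!is.null(exposure_time) && exposure_time <= 0) {
    stop("image_record: exposure_time must be > 0", call. = FALSE)
  }
  stopifnot(all(vapply(regions, is_annotation, logical(1))))
  structure(list(filename = filename, file_size = as.integer(file_size),
                 regions = regions, exposure_time = exposure_time),
            class = "image_record")
}

#' Construct a VIA project
#'
#' @param records List of [image_record()] objects; the filename+file_size
#'   keys must be unique.
#' @return An object of class `"via_project"`.
#' @export
via_project <- function(records = list()) {
  stopifnot(all(vapply(records, inherits, logical(1), "image_record")))
  keys <- vapply(records, .record_key, character(1))
  if (anyDuplicated(keys)) {
    stop("via_project: duplicate filename+file_size keys", call. = FALSE)
  }
  structure(list(records = records), class = "via_project")
}

#' @export
print.via_project <- function(x, ...) {
  nr <- sum(vapply(x$records, function(r) length(r$regions), integer(1)))
  cat(sprintf("<via_project: %d images, %d regions>\n",
              length(x$records), nr))
  invisible(x)
}

## VIA keys entries by filename concatenated with file size; unknown size
## (-1) is serialized as 0.
.record_key <- function(r) {
  paste0(r$filename, max(r$file_size, 0L))
}

.fmt_num <- function(x) sprintf("%.17g", x)

#' Read a VIA version-2 project file
#'
#' Accepts both a full VIA project document (with `_via_img_metadata`) and
#' the bare image-metadata mapping. Polyline, circle and point regions are
#' parsed; any other region shape is skipped with a warning, and the skip
#' count is attached as attribute `"skipped"`. A region attribute `"score"`
#' parseable as a number in `[0, 1]` becomes the annotation score; all other
#' region attributes are preserved verbatim.
#'
#' @param x Path to a JSON file, or a JSON string.
#' @return A [via_project()] with attribute `"skipped"` (count of skipped
#'   regions).
#' @export
read_via_project <- function(x) {
  txt <- if (length(x) == 1 && !grepl("[{]", x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      stop("read_via_project: malformed JSON: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  meta <- if (!is.null(doc[["_via_img_metadata"]])) {
    doc[["_via_img_metadata"]]
  } else {
    doc
  }
  skipped <- 0L
  records <- purrr::imap(meta, function(entry, key) {
    fname <- entry$filename %||% key
    fsize <- as.integer(entry$size %||% -1L)
    if (fsize <= 0) fsize <- -1L
    regions <- list()
    for (ri in seq_along(entry$regions)) {
      reg <- entry$regions[[ri]]
      sa <- reg$shape_attributes
      ra <- reg$region_attributes %||% list()
      score <- NA_real_
      if (!is.null(ra$score)) {
        sc <- suppressWarnings(as.numeric(ra$score))
        if (!is.na(sc) && sc >= 0 && sc <= 1) score <- sc
        ra$score <- NULL
      }
      shape <- switch(sa$name %||% "",
        polyline = {
          px <- unlist(sa$all_points_x)
          py <- unlist(sa$all_points_y)
          if (length(px) != length(py) || length(px) < 2) {
            stop(sprintf(
              "read_via_project: invalid polyline in image '%s', region %d",
              fname, ri), call. = FALSE)
          }
          polyline(px, py)
        },
        circle = circle(sa$cx, sa$cy, sa$r),
        point = point_mark(sa$cx, sa$cy),
        {
          skipped <<- skipped + 1L
          warning(sprintf(
            "read_via_project: skipping region of unknown shape '%s' (image '%s', region %d)",
            sa$name %||% "<missing>", fname, ri), call. = FALSE)
          NULL
        }
      )
      if (!is.null(shape)) {
        at <- if (length(ra)) lapply(ra, as.character) else list()
        regions <- c(regions, list(annotation(shape, score, attrs = at)))
      }
    }
    exp_t <- NULL
    fa <- entry$file_attributes %||% list()
    if (!is.null(fa$exposure_time)) {
      et <- suppressWarnings(as.numeric(fa$exposure_time))
      if (!is.na(et) && et > 0) exp_t <- et
    }
    image_record(fname, fsize, regions, exp_t)
  })
  p <- via_project(unname(records))
  attr(p, "skipped") <- skipped
  p
}

#' Write a VIA version-2 project file
#'
#' Emits the full-document VIA dialect (with `_via_img_metadata`).
#' Coordinates and scores are serialized with 17 significant digits, so
#' `read_via_project(write_via_project(p))` reproduces `p` bit-faithfully.
#'
#' @param p A [via_project()].
#' @param path Optional file path; when `NULL` the JSON text is returned.
#' @return The JSON text, invisibly when written to `path`.
#' @export
write_via_project <- function(p, path = NULL) {
  stopifnot(inherits(p, "via_project"))
  meta <- list()
  for (r in p$records) {
    regions <- lapply(r$regions, function(a) {
      sa <- switch(a$kind,
        polyline = list(name = "polyline",
                        all_points_x = as.list(unclass(a$shape)[, 1]),
                        all_points_y = as.list(unclass(a$shape)[, 2])),
        circle = list(name = "circle", cx = a$shape$cx, cy = a$shape$cy,
                      r = a$shape$r),
        point = list(name = "point", cx = a$shape$cx, cy = a$shape$cy)
      )
      ra <- a$attrs %||% list()
      if (!is.na(a$score)) ra <- c(list(score = .fmt_num(a$score)), ra)
      list(shape_attributes = sa, region_attributes = ra)
    })
    fa <- list()
    if (!is.null(r$exposure_time)) {
      fa$exposure_time <- .fmt_num(r$exposure_time)
    }
    meta[[.record_key(r)]] <- list(
      filename = r$filename,
      size = max(r$file_size, 0L),
      regions = regions,
      file_attributes = fa
    )
  }
  doc <- list(
    `_via_settings` = list(ui = list(), core = list(), project = list(
      name = "blurtrack")),
    `_via_img_metadata` = meta,
    `_via_attributes` = list(region = list(), file = list())
  )
  txt <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                          null = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Exposure time for an image
#'
#' Looks up the exposure time needed by wingbeat estimation: the EXIF
#' `ExposureTime` tag when `x` is an image file that carries one, the
#' record's own exposure when `x` is an [image_record()], otherwise the
#' configured default. Reports where the value came from.
#'
#' @param x Path to an image file, or an [image_record()].
#' @param default Fallback exposure in seconds, or `NULL`.
#' @return List with `exposure_s` and `source` (`"exif"`, `"record"` or
#'   `"config"`). Errors when no source is available.
#' @export
exposure_time_for <- function(x, default = NULL) {
  if (inherits(x, "image_record")) {
    if (!is.null(x$exposure_time)) {
      return(list(exposure_s = x$exposure_time, source = "record"))
    }
  } else if (is.character(x) && file.exists(x)) {
    et <- read_exif_exposure(x)
    if (!is.null(et)) return(list(exposure_s = et, source = "exif"))
  }
  if (!is.null(default)) {
    if (default <= 0) stop("exposure_time_for: default must be > 0",
                           call. = FALSE)
    return(list(exposure_s = default, source = "config"))
  }
  stop("exposure_time_for: no exposure available (no EXIF ExposureTime and ",
       "no configured default); wingbeat estimation requires one",
       call. = FALSE)
}

#' @importFrom rlang %||%
NULL
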