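# Programmatic binary fixtures (built at test time; the repository ships
# text only).

# Minimal JPEG byte stream carrying only an EXIF APP1 segment with an
# ExposureTime rational — enough for the EXIF reader, which never decodes
# pixel data. Synthetic stand-in for a camera JPEG.
write_jpeg_with_exif <- function(path, num, den, big_endian = FALSE) {
  u16b <- function(x) as.raw(c(x %/% 256, x %% 256))
  if (big_endian) {
    u16 <- u16b
    u32 <- function(x) as.raw(c((x %/% 16777216) %% 256, (x %/% 65536) %% 256,
                                (x %/% 256) %% 256, x %% 256))
    order_mark <- charToRaw("MM")
  } else {
    u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
    u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                (x %/% 65536) %% 256,
                                (x %/% 16777216) %% 256))
    order_mark <- charToRaw("II")
  }
  tiff <- c(order_mark, u16(42), u32(8),
            u16(1),                                    # one IFD0 entry
            u16(0x829A), u16(5), u32(1), u32(26),      # rational at offset 26
            u32(0),                                    # no next IFD
            u32(num), u32(den))
  app1 <- c(charToRaw("Exif"), as.raw(c(0, 0)), tiff)
  jpg <- c(as.raw(c(0xFF, 0xD8)),
           as.raw(c(0xFF, 0xE1)), u16b(length(app1) + 2), app1,
           as.raw(c(0xFF, 0xD9)))
  writeBin(jpg, path)
  invisible(path)
}

# Seeded random VIA project with mixed region shapes for round-trip
# property tests.
rand_via_project <- function(n_images = 3, max_regions = 4) {
  records <- lapply(seq_len(n_images), function(i) {
    regions <- lapply(seq_len(sample(0:max_regions, 1)), function(j) {
      kind <- sample(c("polyline", "circle", "point"), 1)
      shape <- switch(kind,
        polyline = rand_polyline(sample(2:6, 1), lim = 500),
        circle = circle(runif(1, 10, 500), runif(1, 10, 500),
                        runif(1, 1, 50)),
        point = point_mark(runif(1, 0, 500), runif(1, 0, 500)))
      score <- if (runif(1) < 0.7) runif(1) else NA_real_
      attrs <- if (runif(1) < 0.3) list(label = "moth") else list()
      annotation(shape, score, attrs)
    })
    image_record(sprintf("img_%03d.png", i),
                 if (runif(1) < 0.5) sample.int(1e6, 1) else -1L,
                 regions,
                 exposure_time = if (runif(1) < 0.5) runif(1, 0.01, 0.5)
                                 else NULL)
  })
  via_project(records)
}

# Strip the reader's bookkeeping attribute so projects compare with
# identical().
strip_skips <- function(p) {
  attr(p, "skipped") <- NULL
  p
}
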