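#' Read the EXIF ExposureTime tag from an image file
#'
#' Minimal EXIF reader covering exactly what wingbeat estimation needs: the
#' `ExposureTime` rational (tag 0x829A), looked up in IFD0 and in the Exif
#' sub-IFD (pointer tag 0x8769) of the TIFF structure embedded in a JPEG
#' APP1 segment, or of a bare TIFF file.
#'
#' @param path Image file path.
#' @return Exposure time in seconds, or `NULL` when the tag is absent or
#'   the file carries no EXIF block.
#' @export
read_exif_exposure <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) return(NULL)
  tiff_off <- NULL
  if (raw[1] == as.raw(0xff) && raw[2] == as.raw(0xd8)) {
    # JPEG: walk marker segments looking for APP1/Exif
    i <- 3
    while (i + 3 <= length(raw)) {
      if (raw[i] != as.raw(0xff)) break
      marker <- as.integer(raw[i + 1])
      if (marker == 0xd9 || marker == 0xda) break  # EOI / start of scan
      seglen <- as.integer(raw[i + 2]) * 256L + as.integer(raw[i + 3])
      if (marker == 0xe1 && seglen >= 8 &&
          identical(raw[(i + 4):(i + 9)],
                    as.raw(c(0x45, 0x78, 0x69, 0x66, 0x00, 0x00)))) {
        tiff_off <- i + 10
        break
      }
      i <- i + 2 + seglen
    }
  } else if ((raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49)) ||
             (raw[1] == as.raw(0x4d) && raw[2] == as.raw(0x4d))) {
    tiff_off <- 1
  }
  if (is.null(tiff_off)) return(NULL)
  tiff <- raw[tiff_off:length(raw)]
  if (length(tiff) < 8) return(NULL)
  le <- tiff[1] == as.raw(0x49)
  u16 <- function(off) {
    b <- as.integer(tiff[(off + 1):(off + 2)])
    if (le) b[1] + b[2] * 256L else b[2] + b[1] * 256L
  }
  u32 <- function(off) {
    b <- as.numeric(tiff[(off + 1):(off + 4)])
    if (le) sum(b * 256^(0:3)) else sum(b * 256^(3:0))
  }
  if (u16(2) != 42L) return(NULL)
  scan_ifd <- function(off) {
    if (off + 2 > length(tiff)) return(NULL)
    n <- u16(off)
    for (k in seq_len(n)) {
      e <- off + 2 + (k - 1) * 12
      tag <- u16(e)
      type <- u16(e + 2)
      if (tag == 0x829A && type == 5) {          # ExposureTime, rational
        v <- u32(e + 8)
        num <- u32(v); den <- u32(v + 4)
        if (den > 0) return(num / den)
      }
      if (tag == 0x8769) {                        # Exif sub-IFD pointer
        sub <- scan_ifd(u32(e + 8))
        if (!is.null(sub)) return(sub)
      }
    }
    NULL
  }
  scan_ifd(u32(4))
}
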