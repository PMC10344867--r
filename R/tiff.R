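# Minimal baseline TIFF I/O (little-endian, uncompressed, 16-bit grayscale,
# one page per channel). Hand-written because no TIFF package ships with the
# target R stack; covers exactly the subset this package emits.

tiff_tag <- function(con, id, type, count, value) {
  writeBin(as.integer(id), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3L) { # SHORT, left-justified in the 4-byte slot
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write / read a well image as multi-page TIFF
#'
#' One 16-bit grayscale page per channel in fixed order BFP, GFP, mCherry
#' (uncompressed, little-endian). The conventional filename is
#' `{plate}_{well}.tif`, see [well_tiff_name()].
#'
#' @param img a `well_image`.
#' @param path output path.
#' @return `read_well_tiff` returns a `well_image` (without scene metadata).
#' @export
write_well_tiff <- function(img, path) {
  chs <- img$channels[c("BFP", "GFP", "mCherry")]
  if (any(vapply(chs, is.null, logical(1)))) {
    stop_input("well image must have BFP, GFP and mCherry channels")
  }
  H <- nrow(chs[[1]]); W <- ncol(chs[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  data_off <- 8L
  nbytes <- 2L * H * W
  ifd_off <- data_off + 3L * nbytes
  writeBin(ifd_off, con, size = 4, endian = "little")
  for (m in chs) {
    v <- as.integer(t(m)) # TIFF strips are row-major
    v <- ifelse(v > 32767L, v - 65536L, v) # two's-complement for writeBin
    writeBin(v, con, size = 2, endian = "little")
  }
  ifd_size <- 2L + 9L * 12L + 4L
  for (p in 0:2) {
    writeBin(9L, con, size = 2, endian = "little")
    tiff_tag(con, 256, 3, 1, W)                    # ImageWidth
    tiff_tag(con, 257, 3, 1, H)                    # ImageLength
    tiff_tag(con, 258, 3, 1, 16)                   # BitsPerSample
    tiff_tag(con, 259, 3, 1, 1)                    # Compression: none
    tiff_tag(con, 262, 3, 1, 1)                    # Photometric: BlackIsZero
    tiff_tag(con, 273, 4, 1, data_off + p * nbytes) # StripOffsets
    tiff_tag(con, 277, 3, 1, 1)                    # SamplesPerPixel
    tiff_tag(con, 278, 3, 1, H)                    # RowsPerStrip
    tiff_tag(con, 279, 4, 1, nbytes)               # StripByteCounts
    nxt <- if (p < 2) ifd_off + (p + 1L) * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_well_tiff
#' @param path input path.
#' @export
read_well_tiff <- function(path) {
  if (!file.exists(path)) stop_input("TIFF not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (magic != "II") stop_input("not a little-endian TIFF: ", path)
  readBin(con, "integer", 1, size = 2, endian = "little")
  ifd_off <- readBin(con, "integer", 1, size = 4, endian = "little")
  pages <- list()
  while (ifd_off != 0) {
    seek(con, ifd_off)
    n <- readBin(con, "integer", 1, size = 2, endian = "little")
    tags <- list()
    for (i in seq_len(n)) {
      id <- readBin(con, "integer", 1, size = 2, endian = "little")
      type <- readBin(con, "integer", 1, size = 2, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little") # count
      val <- if (type == 3L) {
        v <- readBin(con, "integer", 1, size = 2, endian = "little",
                     signed = FALSE)
        readBin(con, "integer", 1, size = 2, endian = "little")
        v
      } else {
        readBin(con, "integer", 1, size = 4, endian = "little")
      }
      tags[[as.character(id)]] <- val
    }
    nxt <- readBin(con, "integer", 1, size = 4, endian = "little")
    W <- tags[["256"]]; H <- tags[["257"]]
    if (!identical(tags[["259"]], 1L) || !identical(tags[["258"]], 16L)) {
      stop_input("unsupported TIFF encoding in ", path)
    }
    seek(con, tags[["273"]])
    v <- readBin(con, "integer", H * W, size = 2, endian = "little",
                 signed = FALSE)
    pages[[length(pages) + 1L]] <- matrix(as.numeric(v), nrow = H, ncol = W,
                                          byrow = TRUE)
    ifd_off <- nxt
  }
  if (length(pages) != 3L) {
    stop_input("expected 3 channel pages in ", path, ", found ",
               length(pages))
  }
  base <- sub("\\.tif{1,2}$", "", basename(path))
  parts <- strsplit(base, "_")[[1]]
  well <- parts[length(parts)]
  structure(list(
    channels = list(BFP = pages[[1]], GFP = pages[[2]], mCherry = pages[[3]]),
    well = well, plate_id = paste(parts[-length(parts)], collapse = "_"),
    row = match(substr(well, 1, 1), LETTERS),
    col = suppressWarnings(as.integer(substr(well, 2, nchar(well))))),
    class = "well_image")
}

#' Conventional TIFF filename for a well
#' @param plate_id plate identifier.
#' @param row,col well address (row 1-based, rendered as a letter).
#' @return `"{plate}_{row}{col}.tif"`, e.g. `"P01_A01.tif"`.
#' @export
well_tiff_name <- function(plate_id, row, col) {
  sprintf("%s_%s.tif", plate_id, well_name(row, col))
}
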