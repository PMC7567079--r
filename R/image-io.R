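# Image input. PNG decoding is delegated to the png package; TIFF support
# is a small built-in baseline decoder (uncompressed strips, grayscale or
# RGB, 8/16-bit) because no TIFF reader is available among the package's
# allowed dependencies.

#' Read a fundus image as a grayscale intensity raster
#'
#' Decodes an 8- or 16-bit PNG or baseline TIFF and returns a numeric
#' matrix of intensities in \[0, 1\], indexed (row, col) with row 1 at the
#' top. RGB images are reduced using the green channel only, the standard
#' practice in retinal imaging (vessels have maximal contrast against the
#' fundus background in green); any alpha channel is ignored.
#'
#' @param path Path to a PNG or TIFF file. The format is detected from the
#'   file's magic bytes, not its extension.
#' @return A numeric matrix with attribute \code{provenance} recording the
#'   source path and the channel-conversion rule applied.
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(64), 8, 8), f)
#' img <- read_image(f)
#' range(img)
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image, no such file: ", path,
                               call. = FALSE)
  magic <- readBin(path, "raw", n = 4L)
  arr <- if (length(magic) >= 4L &&
             identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    png::readPNG(path)
  } else if (length(magic) >= 2L &&
             (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
              identical(magic[1:2], as.raw(c(0x4d, 0x4d))))) {
    read_tiff_baseline(path)
  } else {
    stop("unrecognized image format (expected PNG or TIFF): ", path,
         call. = FALSE)
  }
  note <- "grayscale"
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] >= 3L) {
      arr <- arr[, , 2L]
      note <- "rgb: green channel"
    } else {
      arr <- arr[, , 1L]  # gray + alpha
      note <- "gray+alpha: first channel"
    }
  }
  if (length(arr) == 0L || nrow(arr) < 1L || ncol(arr) < 1L) {
    stop("zero-size image: ", path, call. = FALSE)
  }
  if (any(!is.finite(arr)) || min(arr) < 0 || max(arr) > 1) {
    stop("image intensities outside [0,1] after decoding: ", path,
         call. = FALSE)
  }
  attr(arr, "provenance") <- c(path = path, conversion = note)
  arr
}

# Baseline TIFF decoder: little/big endian, uncompressed strips,
# PhotometricInterpretation 0/1/2, 8- or 16-bit samples.
#' @noRd
read_tiff_baseline <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  byte_order <- readBin(con, "raw", 2L)
  le <- identical(byte_order, as.raw(c(0x49, 0x49)))
  endian <- if (le) "little" else "big"
  # 4-byte fields are read signed: R has no unsigned 32-bit type, and
  # classic TIFF offsets/counts fit in a signed 32-bit range
  rd <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  signed = size > 2L, endian = endian)
  magic <- rd(1L, 2L)
  if (magic != 42L) stop("not a classic TIFF file: ", path, call. = FALSE)
  ifd_off <- rd(1L, 4L)
  seek(con, ifd_off)
  n_entries <- rd(1L, 2L)
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- rd(1L, 2L); type <- rd(1L, 2L); count <- rd(1L, 4L)
    val_raw <- readBin(con, "raw", 4L)
    size <- c(1L, 1L, 2L, 4L)[match(type, c(1L, 2L, 3L, 4L))]
    if (is.na(size)) { next }
    vals <- if (size * count <= 4L) {
      readBin(val_raw, "integer", n = count, size = size,
              signed = size > 2L, endian = endian)
    } else {
      off <- readBin(val_raw, "integer", size = 4L, endian = endian)
      pos <- seek(con)
      seek(con, off)
      v <- rd(count, size)
      seek(con, pos)
      v
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", tag, " missing: ", path,
                                 call. = FALSE)
      default
    } else v
  }
  w <- need(256L); h <- need(257L)
  bits <- need(258L, 8L)[1L]
  comp <- need(259L, 1L)
  photo <- need(262L, 1L)
  offsets <- need(273L)
  spp <- need(277L, 1L)
  rows_per_strip <- need(278L, h)
  counts <- need(279L)
  if (comp != 1L) {
    stop("only uncompressed TIFF is supported (Compression=", comp, "): ",
         path, call. = FALSE)
  }
  if (!bits %in% c(8L, 16L)) {
    stop("only 8/16-bit TIFF is supported: ", path, call. = FALSE)
  }
  ssize <- bits %/% 8L
  vals <- integer(0)
  for (i in seq_along(offsets)) {
    seek(con, offsets[i])
    vals <- c(vals, rd(counts[i] %/% ssize, ssize))
  }
  maxv <- 2^bits - 1
  px <- vals / maxv
  if (spp == 1L) {
    m <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
    if (photo == 0L) m <- 1 - m  # WhiteIsZero
    m
  } else {
    a <- array(NA_real_, dim = c(h, w, spp))
    for (s in seq_len(spp)) {
      a[, , s] <- matrix(px[seq(s, length(px), by = spp)], nrow = h,
                         ncol = w, byrow = TRUE)
    }
    a
  }
}

#' Write a binary raster as an 8-bit PNG (0/255), for debug output
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
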