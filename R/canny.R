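#' Canny edge detection with quantile hysteresis thresholds
#'
#' Classical Canny chain: Gaussian smoothing at scale \code{sigma},
#' gradient by central first differences, non-maximum suppression
#' perpendicular to the local edge direction, then double thresholding
#' with hysteresis. The two thresholds are quantiles of the nonzero
#' gradient magnitudes, which makes the detector invariant to affine
#' rescaling of the input intensities.
#'
#' The detector responds to intensity *edges*, so a vessel (a dark ridge a
#' few pixels wide) yields two parallel contours, one along each side. See
#' \code{\link{clean_mask}} for the closing step that fuses them into a
#' solid vessel band before skeletonization.
#'
#' @param image Numeric matrix of intensities in \[0, 1\].
#' @param sigma Gaussian smoothing scale in pixels.
#' @param low_quantile,high_quantile Quantile thresholds in (0, 1),
#'   \code{low_quantile < high_quantile}. Weak edge pixels (above low) are
#'   kept only when 8-connected to a strong pixel (above high).
#' @return Logical matrix of edge pixels (same shape as \code{image}). A
#'   constant image yields an all-\code{FALSE} mask.
#' @export
canny_edges <- function(image, sigma = 1.4, low_quantile = 0.80,
                        high_quantile = 0.95) {
  stopifnot(is.matrix(image))
  if (!(low_quantile > 0 && low_quantile < high_quantile &&
        high_quantile < 1)) {
    stop("need 0 < low_quantile < high_quantile < 1", call. = FALSE)
  }
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  sm <- gaussian_blur(image, sigma)
  # central first differences (zero at the border rows/cols)
  gr <- matrix(0, h, w)  # d/drow
  gc <- matrix(0, h, w)  # d/dcol
  if (h >= 3L) gr[2:(h - 1), ] <- (sm[3:h, ] - sm[1:(h - 2), ]) / 2
  if (w >= 3L) gc[, 2:(w - 1)] <- (sm[, 3:w] - sm[, 1:(w - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  nz <- mag[mag > 0]
  if (length(nz) == 0L) return(matrix(FALSE, h, w))
  # thresholds are quantiles of the above-noise-floor magnitudes: the
  # floor (3x the median) tracks the sensor noise level, so the working
  # population is edge-dominated and the thresholds do not drift with the
  # fraction of the frame covered by vessels; everything stays invariant
  # to affine intensity rescaling
  floor_mag <- 3 * stats::median(nz)
  ref <- nz[nz > floor_mag]
  if (length(ref) < 2L) ref <- nz
  lo <- stats::quantile(ref, low_quantile, names = FALSE)
  hi <- stats::quantile(ref, high_quantile, names = FALSE)

  # non-maximum suppression: quantize gradient direction into 4 sectors
  # and compare against the two neighbours along the gradient
  ang <- atan2(gr, gc)            # in (-pi, pi]
  sector <- (round(ang / (pi / 4)) %% 4L)  # 0:E/W 1:NE/SW 2:N/S 3:NW/SE
  nmax <- matrix(FALSE, h, w)
  sector_offs <- list(`0` = c(0L, 1L), `1` = c(1L, 1L),
                      `2` = c(1L, 0L), `3` = c(1L, -1L))
  for (s in 0:3) {
    off <- sector_offs[[as.character(s)]]
    m1 <- shift_mat_num(mag, off[1L], off[2L])
    m2 <- shift_mat_num(mag, -off[1L], -off[2L])
    # strict on the forward side so plateau ties yield a 1-px response
    nmax <- nmax | (sector == s & mag > m1 & mag >= m2)
  }
  nmax <- nmax & mag > 0

  strong <- nmax & mag >= hi
  weak <- nmax & mag >= lo
  if (!any(strong)) return(matrix(FALSE, h, w))
  # hysteresis: keep weak components that contain a strong pixel
  lab <- label_components(weak, 8L)
  keep <- unique(lab[strong])
  weak & matrix(lab %in% keep, h, w)
}

#' @noRd
shift_mat_num <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  rs <- max(1L, 1L - dr):min(h, h - dr)
  cs <- max(1L, 1L - dc):min(w, w - dc)
  if (length(rs) < 1L || length(cs) < 1L) return(out)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Clean a raw edge mask into a solid vessel mask
#'
#' Three steps, in order: (1) morphological closing with a
#' \code{(2*close_radius+1)}-pixel square, which fuses the double contour
#' the Canny detector draws along each thin vessel into one solid band;
#' (2) optional circular field mask emulating the focused circular border
#' of a fundus photograph (everything outside a centred disc is cleared);
#' (3) removal of small foreground components (area < \code{min_object_px}),
#' which suppresses speckle before skeletonization.
#'
#' After closing, enclosed background holes that are thin slivers
#' (inscribed Chebyshev radius at most \code{fill_sliver_px}) are filled:
#' they arise where the two contours of a wide vessel fused only
#' intermittently, and cannot be meshes at any realistic vessel spacing.
#'
#' @param mask Logical matrix (vessel evidence).
#' @param min_object_px Minimum component area kept, in pixels.
#' @param circular_mask_fraction Disc diameter as a fraction of
#'   \code{min(dim(mask))}, or \code{"none"}.
#' @param close_radius Closing element radius; 0 disables closing.
#' @param fill_sliver_px Maximum inscribed radius of holes to fill;
#'   0 disables.
#' @return Logical matrix of the same shape.
#' @export
clean_mask <- function(mask, min_object_px = 30L,
                       circular_mask_fraction = "none", close_radius = 1L,
                       fill_sliver_px = 0L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  out <- mask
  if (close_radius > 0L) {
    out <- erode_square(dilate_square(out, close_radius), close_radius)
  }
  if (fill_sliver_px > 0L && any(out)) {
    out <- fill_slivers(out, fill_sliver_px)
  }
  if (!identical(circular_mask_fraction, "none")) {
    f <- as.numeric(circular_mask_fraction)
    h <- nrow(out); w <- ncol(out)
    rad <- f * min(h, w) / 2
    cr <- (h + 1) / 2; cc <- (w + 1) / 2
    d2 <- outer((seq_len(h) - cr)^2, (seq_len(w) - cc)^2, `+`)
    out <- out & (d2 <= rad^2)
  }
  if (min_object_px > 0L && any(out)) {
    lab <- label_components(out, 8L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_px)
    out <- matrix(lab %in% keep, nrow(out), ncol(out))
  }
  out
}

# Fill enclosed background holes whose inscribed Chebyshev radius is <= r
# (erosion depth with a 3x3 element).
#' @noRd
fill_slivers <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- label_components(!mask, 4L)
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  ids <- setdiff(unique(lab[lab > 0L]), border)
  for (i in ids) {
    px <- which(lab == i, arr.ind = TRUE)
    r0 <- min(px[, 1L]); r1 <- max(px[, 1L])
    c0 <- min(px[, 2L]); c1 <- max(px[, 2L])
    reg <- matrix(FALSE, r1 - r0 + 3L, c1 - c0 + 3L)
    reg[cbind(px[, 1L] - r0 + 2L, px[, 2L] - c0 + 2L)] <- TRUE
    depth <- 0L
    while (any(reg) && depth <= r) {
      reg <- erode_square(reg, 1L)
      depth <- depth + 1L
    }
    if (!any(reg)) mask[lab == i] <- TRUE  # eroded away within r steps
  }
  mask
}
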