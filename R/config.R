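#' Analysis configuration for the vessel-quantification pipeline
#'
#' Collects every tunable parameter of the image pipeline and the
#' statistical layer. All geometric quantities are in pixel units; the
#' source images carry no physical calibration, so no micron conversion is
#' attempted anywhere in the package.
#'
#' @param canny_sigma Gaussian smoothing scale (px) used by the Canny
#'   detector. Vessels in small-animal fundus images are ridges a few
#'   pixels wide; the default 1.4 px keeps the two flanking edge contours
#'   of a thin vessel close enough to be fused by the closing step.
#' @param canny_low_quantile,canny_high_quantile Hysteresis thresholds,
#'   expressed as quantiles of the above-noise-floor gradient magnitudes
#'   (the floor is 3x the median magnitude, which tracks the sensor noise
#'   level). Quantiles keep the detector invariant to affine rescaling of
#'   the intensities, and referencing them to the noise floor keeps them
#'   stable across scenes of different vessel density.
#' @param circular_mask_fraction Diameter of the centred circular fundus
#'   field, as a fraction of \code{min(height, width)}, or \code{"none"} to
#'   disable field masking.
#' @param min_object_px Connected foreground components smaller than this
#'   (in pixels) are removed from the binary mask before skeletonization.
#' @param close_radius Radius of the square structuring element used for
#'   morphological closing of the edge map (the element is a
#'   \code{(2r+1) x (2r+1)} square). Closing fuses the double contour the
#'   Canny detector draws along each vessel into one solid band; radius 3
#'   bridges the interior gap left by vessels up to roughly 5-6 px wide.
#'   The closing reach also sets the minimum separation at which two
#'   distinct vessels remain distinct.
#' @param fill_sliver_px Enclosed background holes whose inscribed
#'   (Chebyshev) radius is at most this value are filled after closing;
#'   such thin slivers are contour-fusion artifacts, not meshes. 0
#'   disables.
#' @param prune_spur_px Terminal skeleton paths of at most this length
#'   ending at a junction are removed (thinning-artifact spurs); 0
#'   disables. Free-standing short elements are never pruned.
#' @param min_mesh_px Smallest enclosed area (px^2) counted as a mesh;
#'   smaller enclosed pockets are closing artifacts at the stated vessel
#'   widths, not meshes.
#' @param diagonal_step Length charged for one diagonal pixel move when
#'   measuring path lengths; default \code{sqrt(2)}. Set to 1 to emulate
#'   raw pixel counting.
#' @param mesh_scope \code{"master"} (default) counts meshes as the bounded
#'   faces of the master subgraph only; \code{"all"} counts every bounded
#'   face of the full skeleton.
#' @param alpha Significance level for group comparisons.
#'
#' @return An object of class \code{vasc_config} (a named list).
#' @export
#' @examples
#' cfg <- vasc_config(canny_sigma = 2)
#' cfg$canny_sigma
vasc_config <- function(canny_sigma = 1.4,
                        canny_low_quantile = 0.10,
                        canny_high_quantile = 0.30,
                        circular_mask_fraction = "none",
                        min_object_px = 30L,
                        close_radius = 3L,
                        fill_sliver_px = 2L,
                        prune_spur_px = 4L,
                        min_mesh_px = 300,
                        diagonal_step = sqrt(2),
                        mesh_scope = c("master", "all"),
                        alpha = 0.05) {
  mesh_scope <- match.arg(mesh_scope)
  if (!is.numeric(canny_sigma) || canny_sigma <= 0) {
    stop("canny_sigma must be > 0", call. = FALSE)
  }
  if (!(canny_low_quantile > 0 && canny_low_quantile < canny_high_quantile &&
        canny_high_quantile < 1)) {
    stop("need 0 < canny_low_quantile < canny_high_quantile < 1",
         call. = FALSE)
  }
  if (!identical(circular_mask_fraction, "none")) {
    f <- as.numeric(circular_mask_fraction)
    if (!is.finite(f) || f <= 0) {
      stop("circular_mask_fraction must be positive or \"none\"",
           call. = FALSE)
    }
    circular_mask_fraction <- f
  }
  if (min_object_px < 0) stop("min_object_px must be >= 0", call. = FALSE)
  if (close_radius < 0) stop("close_radius must be >= 0", call. = FALSE)
  if (fill_sliver_px < 0) stop("fill_sliver_px must be >= 0", call. = FALSE)
  if (prune_spur_px < 0) stop("prune_spur_px must be >= 0", call. = FALSE)
  if (min_mesh_px < 0) stop("min_mesh_px must be >= 0", call. = FALSE)
  if (diagonal_step <= 0) stop("diagonal_step must be > 0", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  structure(
    list(canny_sigma = canny_sigma,
         canny_low_quantile = canny_low_quantile,
         canny_high_quantile = canny_high_quantile,
         circular_mask_fraction = circular_mask_fraction,
         min_object_px = as.integer(min_object_px),
         close_radius = as.integer(close_radius),
         fill_sliver_px = as.integer(fill_sliver_px),
         prune_spur_px = as.integer(prune_spur_px),
         min_mesh_px = min_mesh_px,
         diagonal_step = diagonal_step,
         mesh_scope = mesh_scope,
         alpha = alpha),
    class = "vasc_config"
  )
}

#' Read an analysis configuration from a flat key=value text file
#'
#' Unknown keys are an error, so that typos in a config file cannot be
#' silently ignored. Blank lines and lines starting with \code{#} are
#' skipped.
#'
#' @param path Path to the configuration file.
#' @return A \code{vasc_config} object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defaults <- vasc_config()
  numeric_keys <- c("canny_sigma", "canny_low_quantile", "canny_high_quantile",
                    "min_object_px", "close_radius", "fill_sliver_px",
                    "prune_spur_px", "min_mesh_px", "diagonal_step", "alpha")
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults)) {
      stop("unknown config key: ", key, call. = FALSE)
    }
    args[[key]] <- if (key %in% numeric_keys) as.numeric(val) else val
  }
  do.call(vasc_config, args)
}

#' @export
print.vasc_config <- function(x, ...) {
  cat("<vasc_config>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}
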