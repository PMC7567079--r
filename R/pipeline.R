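#' Run the full vessel-quantification pipeline on one image
#'
#' Deterministic composition: Canny edge detection, mask cleaning
#' (closing, optional circular field mask, speckle removal),
#' skeletonization, skeleton-graph construction, element classification,
#' master-structure resolution, mesh detection, and feature computation.
#' Identical input and configuration yield bit-identical output.
#'
#' @param image Numeric intensity matrix in \[0, 1\]
#'   (see \code{\link{read_image}}).
#' @param config A \code{\link{vasc_config}}.
#' @param keep_intermediates If TRUE, the returned feature set carries the
#'   binary mask and skeleton as attributes (for debugging and stage
#'   testing).
#' @return A \code{vasc_features} object.
#' @export
#' @examples
#' img <- matrix(1, 64, 64)
#' img[30:34, 10:54] <- 0  # one dark horizontal vessel
#' run_pipeline(img, vasc_config())$isolated_segments
run_pipeline <- function(image, config = vasc_config(),
                         keep_intermediates = FALSE) {
  stopifnot(is.matrix(image), inherits(config, "vasc_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  edges <- stage("canny_edges", canny_edges(
    image, config$canny_sigma, config$canny_low_quantile,
    config$canny_high_quantile))
  mask <- stage("clean_mask", clean_mask(
    edges, config$min_object_px, config$circular_mask_fraction,
    config$close_radius, config$fill_sliver_px))
  skeleton <- stage("skeletonize_mask", skeletonize_mask(mask))
  if (config$prune_spur_px > 0L) {
    skeleton <- stage("prune_spurs",
                      prune_spurs(skeleton, config$prune_spur_px))
  }
  feats <- stage("features", skeleton_features(skeleton, config))
  if (keep_intermediates) {
    attr(feats, "mask") <- mask
    attr(feats, "skeleton") <- skeleton
  }
  feats
}

#' Compute the feature set directly from a skeleton raster
#'
#' The graph-and-features half of the pipeline, usable on its own for
#' pre-skeletonized rasters (and for validating against synthetic ground
#' truth, where the noise-free centerline raster is available).
#'
#' @param skeleton Logical skeleton raster.
#' @param config A \code{\link{vasc_config}} (uses \code{diagonal_step}
#'   and \code{mesh_scope}).
#' @return A \code{vasc_features} object.
#' @export
skeleton_features <- function(skeleton, config = vasc_config()) {
  graph <- build_skeleton_graph(skeleton, config$diagonal_step)
  classification <- classify_elements(graph)
  master <- find_master_structure(graph, classification)
  meshes <- find_meshes(graph, master, config$mesh_scope,
                        config$min_mesh_px)
  compute_features(graph, classification, master, meshes)
}
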