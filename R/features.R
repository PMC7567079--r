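# Element taxonomy, master-structure resolution, mesh detection, and the
# 20-metric per-image feature set.

#' Canonical feature names, in canonical column order
#'
#' @return Character vector of the 20 feature names.
#' @export
feature_names <- function() {
  c("extremities", "nodes", "junctions",
    "branches", "branch_length",
    "segments", "segment_length",
    "isolated_segments", "isolated_length",
    "master_segments", "master_segment_length", "master_junctions",
    "meshes", "mesh_area", "mean_mesh_size", "mesh_index",
    "branching_interval", "pieces", "total_length", "branching_length")
}

#' Classify skeleton edges as branches, segments or isolated elements
#'
#' A \emph{branch} has exactly one extremity endpoint and one junction
#' endpoint; a \emph{segment} connects two junctions (possibly the same
#' one, for a loop anchored at a single junction); an \emph{isolated
#' element} lies in a connected component containing no junction (lone
#' lines and junction-free rings). An edge joining two extremities is
#' counted with the isolated elements.
#'
#' @param graph A \code{skeleton_graph}.
#' @return Character vector, one of \code{"branch"}, \code{"segment"},
#'   \code{"isolated"} per edge (in \code{graph$edges} order).
#' @export
classify_elements <- function(graph) {
  edges <- graph$edges
  if (nrow(edges) == 0L) return(character(0))
  comp_of_edge <- vapply(edges$path, function(p) graph$components[p[1L]],
                         integer(1))
  node_comps <- unique(graph$components[graph$class_map == 3L])
  vapply(seq_len(nrow(edges)), function(i) {
    a <- edges$a_type[i]; b <- edges$b_type[i]
    if (a == "loop") return("isolated")
    if (!(comp_of_edge[i] %in% node_comps)) return("isolated")
    if (a == "junction" && b == "junction") return("segment")
    if (xor(a == "junction", b == "junction")) return("branch")
    "isolated"  # extremity-extremity inside a junction-bearing component
  }, character(1))
}

#' Resolve the master structure of a skeleton graph
#'
#' The master segments are the loop-bearing core of the network: starting
#' from the subgraph of segments only, every segment with an endpoint
#' junction of degree 1 in the current subgraph is deleted, repeatedly,
#' until a fixpoint. Surviving segments are master segments; junctions
#' with at least three incident master-segment endpoints are master
#' junctions (a loop anchored at a junction contributes two endpoints).
#' A pure tree prunes away completely: no master segments, no master
#' junctions, and therefore no meshes.
#'
#' @param graph A \code{skeleton_graph}.
#' @param classification From \code{\link{classify_elements}}.
#' @return List with \code{master_edges} (logical per edge) and
#'   \code{master_junctions} (integer junction ids).
#' @export
find_master_structure <- function(graph, classification) {
  edges <- graph$edges
  nj <- nrow(graph$junctions)
  master <- rep(FALSE, nrow(edges))
  if (nrow(edges) == 0L || nj == 0L) {
    return(list(master_edges = master, master_junctions = integer(0)))
  }
  seg <- which(classification == "segment")
  alive <- rep(TRUE, length(seg))
  a <- edges$a_id[seg]; b <- edges$b_id[seg]
  repeat {
    deg <- tabulate(c(a[alive], b[alive]), nbins = nj)
    drop <- alive & (deg[a] == 1L | deg[b] == 1L)
    if (!any(drop)) break
    alive <- alive & !drop
  }
  master[seg[alive]] <- TRUE
  deg <- tabulate(c(a[alive], b[alive]), nbins = nj)
  list(master_edges = master,
       master_junctions = which(deg >= 3L))
}

#' Detect meshes: enclosed areas bounded by the master structure
#'
#' The master subgraph (master segments plus the pixels of their incident
#' junctions) is rasterized onto a blank canvas; the background is then
#' flood-filled 4-connectedly from the raster border, and every remaining
#' background region is a mesh whose area is its pixel count. Vessel
#' pixels themselves are excluded from the area. With
#' \code{mesh_scope = "all"} the full skeleton is rasterized instead, so
#' every bounded face (including junction-free rings) counts.
#'
#' @param graph A \code{skeleton_graph}.
#' @param master From \code{\link{find_master_structure}}.
#' @param mesh_scope \code{"master"} or \code{"all"}.
#' @param min_area Smallest area (px^2) counted as a mesh; enclosed
#'   regions below it are treated as contour artifacts and dropped.
#' @return Data frame with one row per mesh: \code{id}, \code{area} (px^2)
#'   and a list column \code{junctions} of bounding junction ids.
#' @export
find_meshes <- function(graph, master, mesh_scope = "master",
                        min_area = 0) {
  h <- graph$dim[1L]; w <- graph$dim[2L]
  canvas <- matrix(FALSE, h, w)
  if (mesh_scope == "all") {
    canvas[graph$class_map > 0L] <- TRUE
  } else {
    me <- which(master$master_edges)
    if (length(me)) {
      for (i in me) canvas[graph$edges$path[[i]]] <- TRUE
      jids <- unique(c(graph$edges$a_id[me], graph$edges$b_id[me]))
      for (j in jids) canvas[graph$junctions$pixels[[j]]] <- TRUE
    }
  }
  empty <- data.frame(id = integer(0), area = numeric(0))
  empty$junctions <- list()
  if (!any(canvas)) return(empty)
  lab <- label_components(!canvas, 4L)
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  ids <- setdiff(sort(unique(lab[lab > 0L])), border)
  if (min_area > 0 && length(ids)) {
    areas <- vapply(ids, function(i) sum(lab == i), numeric(1))
    ids <- ids[areas >= min_area]
  }
  if (length(ids) == 0L) return(empty)
  jn_pix <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(graph$junctions))) {
    jn_pix[graph$junctions$pixels[[i]]] <- TRUE
  }
  jlab <- matrix(0L, h, w)
  for (i in seq_len(nrow(graph$junctions))) {
    jlab[graph$junctions$pixels[[i]]] <- graph$junctions$id[i]
  }
  out <- data.frame(id = seq_along(ids),
                    area = vapply(ids, function(i) sum(lab == i), numeric(1)))
  out$junctions <- lapply(ids, function(i) {
    ring <- dilate_square(lab == i, 1L)
    sort(unique(jlab[ring & jn_pix]))
  })
  out
}

#' Compute the full 20-metric vascular feature set
#'
#' Counts and lengths follow the architecture taxonomy: extremity and node
#' pixel counts, junction (node-cluster) count, branch/segment/isolated
#' element counts and total lengths, the master structure, mesh count and
#' areas, and the derived ratios. Ratios with an empty denominator
#' (mesh index with no master segments, branching interval with no
#' branches, mean mesh size with no meshes) are reported as 0 and flagged
#' in the \code{zero_denominator} attribute so downstream tables stay
#' total.
#'
#' Identities guaranteed by construction:
#' \code{pieces = branches + segments + isolated_segments},
#' \code{total_length = branch_length + segment_length + isolated_length},
#' \code{branching_length = branch_length + segment_length}.
#'
#' @param graph A \code{skeleton_graph}.
#' @param classification From \code{\link{classify_elements}}.
#' @param master From \code{\link{find_master_structure}}.
#' @param meshes From \code{\link{find_meshes}}.
#' @return Object of class \code{vasc_features}: a named list of the 20
#'   metrics (see \code{\link{feature_names}}).
#' @export
compute_features <- function(graph, classification, master, meshes) {
  cls <- graph$class_map
  edges <- graph$edges
  len_of <- function(sel) if (any(sel)) sum(edges$length[sel]) else 0
  is_branch <- classification == "branch"
  is_segment <- classification == "segment"
  is_isolated <- classification == "isolated"
  f <- list()
  f$extremities <- sum(cls == 1L)
  f$nodes <- sum(cls == 3L)
  f$junctions <- nrow(graph$junctions)
  f$branches <- sum(is_branch)
  f$branch_length <- len_of(is_branch)
  f$segments <- sum(is_segment)
  f$segment_length <- len_of(is_segment)
  f$isolated_segments <- sum(is_isolated)
  f$isolated_length <- len_of(is_isolated)
  f$master_segments <- sum(master$master_edges)
  f$master_segment_length <- len_of(master$master_edges)
  f$master_junctions <- length(master$master_junctions)
  f$meshes <- nrow(meshes)
  f$mesh_area <- if (nrow(meshes)) sum(meshes$area) else 0
  zero_den <- character(0)
  if (f$meshes > 0) {
    f$mean_mesh_size <- f$mesh_area / f$meshes
  } else {
    f$mean_mesh_size <- 0; zero_den <- c(zero_den, "mean_mesh_size")
  }
  if (f$master_segments > 0) {
    f$mesh_index <- f$master_segment_length / f$master_segments
  } else {
    f$mesh_index <- 0; zero_den <- c(zero_den, "mesh_index")
  }
  if (f$branches > 0) {
    f$branching_interval <- f$segment_length / f$branches
  } else {
    f$branching_interval <- 0; zero_den <- c(zero_den, "branching_interval")
  }
  f$pieces <- f$branches + f$segments + f$isolated_segments
  f$total_length <- f$branch_length + f$segment_length + f$isolated_length
  f$branching_length <- f$branch_length + f$segment_length
  f <- f[feature_names()]
  structure(f, class = "vasc_features", zero_denominator = zero_den)
}

#' @export
print.vasc_features <- function(x, ...) {
  cat("<vasc_features>\n")
  for (k in feature_names()) cat(sprintf("  %-22s %g\n", k, x[[k]]))
  zd <- attr(x, "zero_denominator")
  if (length(zd)) cat("  (zero denominator:", paste(zd, collapse = ", "), ")\n")
  invisible(x)
}

#' @export
as.data.frame.vasc_features <- function(x, ...) {
  as.data.frame(unclass(x)[feature_names()], ...)
}
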