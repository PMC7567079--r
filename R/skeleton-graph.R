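# Skeleton graph construction: classify skeleton pixels, cluster junction
# pixels, and trace the paths between them. This is the explicit form of
# the "analyzed tree" that every architecture feature is computed from.

#' Classify every skeleton pixel as extremity, slab or node
#'
#' The class is decided by the number of skeleton pixels in the
#' 8-neighbourhood: 0 or 1 neighbours make an extremity (an isolated pixel
#' is a degenerate extremity), exactly 2 a slab (path interior), and 3 or
#' more a node (junction evidence).
#'
#' @param skeleton Logical matrix (one-pixel-wide skeleton).
#' @return Integer matrix: 0 background, 1 extremity, 2 slab, 3 node.
#' @export
#' @examples
#' sk <- matrix(FALSE, 3, 7); sk[2, 2:6] <- TRUE
#' table(classify_pixels(sk))
classify_pixels <- function(skeleton) {
  stopifnot(is.matrix(skeleton), is.logical(skeleton))
  nc <- neighbor_count(skeleton, 8L)
  cls <- matrix(0L, nrow(skeleton), ncol(skeleton))
  cls[skeleton & nc <= 1L] <- 1L
  cls[skeleton & nc == 2L] <- 2L
  cls[skeleton & nc >= 3L] <- 3L
  cls
}

#' Cluster node pixels into junctions
#'
#' A junction is an 8-connected component of node pixels (several node
#' pixels packed together at a thick crossing count as one junction). A
#' single node pixel forms a junction of size 1.
#'
#' @param class_map Integer matrix from \code{\link{classify_pixels}}.
#' @return A data frame with one row per junction: \code{id}, \code{size},
#'   centroid \code{r}, \code{c}, and a list column \code{pixels} of
#'   linear pixel indices.
#' @export
cluster_junctions <- function(class_map) {
  h <- nrow(class_map)
  nodes <- class_map == 3L
  lab <- label_components(nodes, 8L)
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) {
    return(data.frame(id = integer(0), size = integer(0),
                      r = numeric(0), c = numeric(0)))
  }
  pix <- lapply(ids, function(i) order_rc(which(lab == i), h))
  rc <- lapply(pix, idx_to_rc, h = h)
  out <- data.frame(
    id = seq_along(ids),
    size = vapply(pix, length, integer(1)),
    r = vapply(rc, function(m) mean(m[, 1L]), numeric(1)),
    c = vapply(rc, function(m) mean(m[, 2L]), numeric(1))
  )
  out$pixels <- pix
  out
}

#' Build the full skeleton graph of an image
#'
#' Runs \code{\link{classify_pixels}}, \code{\link{cluster_junctions}} and
#' \code{\link{trace_edges}} and bundles the results with the 8-connected
#' component labelling of the skeleton.
#'
#' @param skeleton Logical skeleton raster.
#' @param diagonal_step Length charged per diagonal move (default
#'   \code{sqrt(2)}; use 1 for raw pixel counting).
#' @return An object of class \code{skeleton_graph}: a list with
#'   \code{dim}, \code{class_map}, \code{junctions}, \code{edges},
#'   \code{components} (label matrix) and \code{diagonal_step}.
#' @export
build_skeleton_graph <- function(skeleton, diagonal_step = sqrt(2)) {
  cls <- classify_pixels(skeleton)
  jn <- cluster_junctions(cls)
  edges <- trace_edges(cls, jn, diagonal_step = diagonal_step)
  structure(
    list(dim = dim(skeleton),
         class_map = cls,
         junctions = jn,
         edges = edges,
         components = label_components(skeleton, 8L),
         diagonal_step = diagonal_step),
    class = "skeleton_graph"
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %dx%d raster, %d skeleton px\n",
              x$dim[1], x$dim[2], sum(x$class_map > 0L)))
  cat(sprintf("  junctions: %d   edges: %d   components: %d\n",
              nrow(x$junctions), nrow(x$edges),
              max(0L, max(x$components))))
  invisible(x)
}

#' Trace the edges of a skeleton between junctions and extremities
#'
#' Walks from every extremity and from every slab pixel adjacent to a
#' junction, through slab pixels, until another extremity or junction is
#' reached. Each slab pixel belongs to exactly one edge. Junction-free
#' cycles (pure rings) are traced as single closed-loop edges. Edge length
#' is the sum of per-step costs: 1 for an orthogonal move,
#' \code{diagonal_step} for a diagonal move; for closed loops the closing
#' step is included. Traversal visits start pixels in (row, col) order and
#' prefers the lexicographically smallest neighbour, so edge pixel
#' orderings are deterministic.
#'
#' @param class_map Integer matrix from \code{\link{classify_pixels}}.
#' @param junctions Data frame from \code{\link{cluster_junctions}}.
#' @param diagonal_step Diagonal move cost.
#' @return A data frame with one row per edge: endpoint types
#'   (\code{"junction"}, \code{"extremity"} or \code{"loop"}), endpoint
#'   ids (junction id, or linear pixel index for extremities), length, and
#'   a list column \code{path} of ordered linear pixel indices.
#' @export
trace_edges <- function(class_map, junctions, diagonal_step = sqrt(2)) {
  h <- nrow(class_map); w <- ncol(class_map)
  sk_idx <- which(class_map > 0L)
  empty <- data.frame(a_type = character(0), a_id = integer(0),
                      b_type = character(0), b_id = integer(0),
                      length = numeric(0))
  empty$path <- list()
  if (length(sk_idx) == 0L) return(empty)

  # junction id per node pixel
  jid <- integer(h * w)
  for (i in seq_len(nrow(junctions))) jid[junctions$pixels[[i]]] <- junctions$id[i]

  # adjacency: for each skeleton pixel, its skeleton neighbours in
  # (row, col) order of the neighbour pixel
  pad_ok <- function(r, c) r >= 1L & r <= h & c >= 1L & c <= w
  neighbors_of <- function(p) {
    rc <- idx_to_rc(p, h)
    nb_r <- rc[1L] + NB8[, 1L]; nb_c <- rc[2L] + NB8[, 2L]
    ok <- pad_ok(nb_r, nb_c)
    nb <- rc_to_idx(nb_r[ok], nb_c[ok], h)
    nb <- nb[class_map[nb] > 0L]
    order_rc(nb, h)
  }
  cls <- as.integer(class_map)
  # consistency guard: a slab must have exactly 2 skeleton neighbours
  ncount <- neighbor_count(class_map > 0L, 8L)
  bad <- which(cls == 2L & as.integer(ncount) != 2L)
  if (length(bad)) {
    stop("inconsistent class map: slab pixel with != 2 neighbours ",
         "(thinning contract violated)", call. = FALSE)
  }

  step_cost <- function(p, q) {
    dr <- abs(((p - 1L) %% h) - ((q - 1L) %% h))
    dc <- abs(((p - 1L) %/% h) - ((q - 1L) %/% h))
    ifelse(dr + dc == 2L, diagonal_step, 1)
  }

  used_slab <- logical(h * w)    # slab pixels consumed by an edge
  ext_done <- logical(h * w)     # extremities consumed as walk endpoints
  edges <- list()

  end_desc <- function(p) {
    if (cls[p] == 3L) list(type = "junction", id = jid[p])
    else list(type = "extremity", id = p)
  }

  walk <- function(start, second) {
    # start is an endpoint pixel (extremity or node); second is the first
    # path pixel after it. Returns the ordered pixel path ending at an
    # extremity or node pixel.
    path <- c(start, second)
    prev <- start; cur <- second
    while (cls[cur] == 2L) {
      nb <- neighbors_of(cur)
      nxt <- nb[nb != prev]
      if (length(nxt) == 0L) break   # cannot happen on a consistent map
      prev <- cur; cur <- nxt[1L]
      path <- c(path, cur)
    }
    path
  }

  add_edge <- function(path) {
    a <- end_desc(path[1L]); b <- end_desc(path[length(path)])
    interior <- path[-c(1L, length(path))]
    used_slab[interior[cls[interior] == 2L]] <<- TRUE
    len <- if (length(path) >= 2L) {
      sum(step_cost(path[-length(path)], path[-1L]))
    } else 0
    edges[[length(edges) + 1L]] <<- list(
      a_type = a$type, a_id = a$id, b_type = b$type, b_id = b$id,
      length = len, path = path)
  }

  # 1) walks from extremities
  for (e in order_rc(which(cls == 1L), h)) {
    if (ext_done[e]) next
    ext_done[e] <- TRUE
    nb <- neighbors_of(e)
    if (length(nb) == 0L) next      # degenerate isolated pixel: no edge
    path <- walk(e, nb[1L])
    last <- path[length(path)]
    if (cls[last] == 1L) ext_done[last] <- TRUE
    if (cls[last] == 2L) {
      # 2-pixel dead end cannot occur (slab needs 2 neighbours); but a
      # direct extremity-extremity pair ends on cls == 1 above
      stop("walk terminated on a slab pixel", call. = FALSE)
    }
    add_edge(path)
  }

  # 2) walks from slab pixels adjacent to junctions
  node_adjacent <- which(cls == 2L & as.integer(
    neighbor_count(class_map == 3L, 8L)) > 0L)
  for (s in order_rc(node_adjacent, h)) {
    if (used_slab[s]) next
    nb <- neighbors_of(s)
    nodes_nb <- nb[cls[nb] == 3L]
    start <- nodes_nb[1L]
    path <- walk(start, s)
    add_edge(path)
  }

  # 3) node-node adjacencies between *different* junction clusters cannot
  # occur (clusters are 8-connected components), so what remains are pure
  # rings of slab pixels
  remaining <- which(cls == 2L & !used_slab)
  remaining <- order_rc(remaining, h)
  for (s in remaining) {
    if (used_slab[s]) next
    nb <- neighbors_of(s)
    path <- c(s)
    prev <- s; cur <- nb[1L]
    while (cur != s) {
      path <- c(path, cur)
      nxt <- neighbors_of(cur)
      nxt <- nxt[nxt != prev]
      prev <- cur; cur <- nxt[1L]
    }
    used_slab[path] <- TRUE
    len <- sum(step_cost(path, c(path[-1L], path[1L])))
    edges[[length(edges) + 1L]] <- list(
      a_type = "loop", a_id = NA_integer_, b_type = "loop",
      b_id = NA_integer_, length = len, path = path)
  }

  if (length(edges) == 0L) return(empty)
  out <- data.frame(
    a_type = vapply(edges, `[[`, character(1), "a_type"),
    a_id = vapply(edges, `[[`, integer(1), "a_id"),
    b_type = vapply(edges, `[[`, character(1), "b_type"),
    b_id = vapply(edges, `[[`, integer(1), "b_id"),
    length = vapply(edges, `[[`, numeric(1), "length")
  )
  out$path <- lapply(edges, `[[`, "path")
  out
}

#' Dump a skeleton graph as JSON (debug / oracle interface)
#'
#' Writes junction centroids and sizes, and edges with endpoint
#' descriptors and lengths. Pixel paths are omitted by default to keep
#' files small.
#'
#' @param graph A \code{skeleton_graph}.
#' @param path Output path.
#' @param paths Include per-edge pixel index paths.
#' @return Invisibly, \code{path}.
#' @export
write_graph_json <- function(graph, path, paths = FALSE) {
  jn <- graph$junctions
  edges <- graph$edges
  payload <- list(
    dim = graph$dim,
    junctions = data.frame(id = jn$id, size = jn$size, r = jn$r, c = jn$c),
    edges = data.frame(a_type = edges$a_type, a_id = edges$a_id,
                       b_type = edges$b_type, b_id = edges$b_id,
                       length = edges$length)
  )
  if (paths) payload$edge_paths <- edges$path
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
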