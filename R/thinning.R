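# Topology-preserving thinning. A pixel may be deleted only when it is a
# *simple* pixel: removing it changes neither the 8-connectivity of the
# foreground nor the 4-connectivity of the background in its 3x3
# neighbourhood (the standard digital-topology characterization via the
# two connectivity numbers). Deletions are applied sequentially, with the
# simplicity test re-evaluated against the current raster, so component
# and hole counts are preserved by construction. Endpoint pixels (exactly
# one foreground neighbour) are never deleted, which preserves the tips of
# open vessel branches.

.retvasc_env <- new.env(parent = emptyenv())

# Lookup table over the 256 possible 8-neighbourhood configurations:
# TRUE when the centre pixel is simple.
#' @noRd
simple_point_lut <- function() {
  lut <- .retvasc_env$simple_lut
  if (!is.null(lut)) return(lut)
  coords <- NB8  # fixed bit order: bit i <-> NB8 row i
  adj8 <- function(a, b) max(abs(coords[a, ] - coords[b, ])) == 1L
  adj4 <- function(a, b) sum(abs(coords[a, ] - coords[b, ])) == 1L
  n_components <- function(cells, adj_fun) {
    if (length(cells) == 0L) return(0L)
    seen <- logical(length(cells))
    ncomp <- 0L
    for (s in seq_along(cells)) {
      if (seen[s]) next
      ncomp <- ncomp + 1L
      queue <- s
      seen[s] <- TRUE
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (t in seq_along(cells)) {
          if (!seen[t] && adj_fun(cells[cur], cells[t])) {
            seen[t] <- TRUE
            queue <- c(queue, t)
          }
        }
      }
    }
    ncomp
  }
  is4 <- vapply(1:8, function(i) sum(abs(coords[i, ])) == 1L, logical(1))
  lut <- logical(256L)
  for (code in 0:255) {
    fg <- which(bitwAnd(code, bitwShiftL(1L, 0:7)) > 0L)
    bg <- setdiff(1:8, fg)
    t8 <- n_components(fg, adj8)
    # background components restricted to the ring, 4-adjacency, that
    # touch the centre through a 4-neighbour
    bg4 <- bg
    if (length(bg4)) {
      comp_touch <- 0L
      seen <- logical(length(bg4))
      for (s in seq_along(bg4)) {
        if (seen[s]) next
        queue <- s; seen[s] <- TRUE; members <- bg4[s]
        while (length(queue)) {
          cur <- queue[[1]]; queue <- queue[-1]
          for (t in seq_along(bg4)) {
            if (!seen[t] && adj4(bg4[cur], bg4[t])) {
              seen[t] <- TRUE; queue <- c(queue, t); members <- c(members, bg4[t])
            }
          }
        }
        if (any(is4[members])) comp_touch <- comp_touch + 1L
      }
      t4 <- comp_touch
    } else t4 <- 0L
    lut[code + 1L] <- (t8 == 1L && t4 == 1L)
  }
  .retvasc_env$simple_lut <- lut
  lut
}

#' Reduce a binary vessel mask to a one-pixel-wide skeleton
#'
#' Iterative directional border peeling constrained to simple pixels.
#' The result has the same number of 8-connected foreground components
#' and the same number of holes (4-connected enclosed background regions)
#' as the input — the property every downstream topology feature relies
#' on. Tips of open lines are preserved; traversal order is fixed
#' (N, S, W, E sweeps, pixels in row-major order) so the output is
#' deterministic.
#'
#' @param mask Logical matrix.
#' @return Logical matrix: the skeleton.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  h <- nrow(mask); w <- ncol(mask)
  if (!any(mask)) return(mask)
  lut <- simple_point_lut()
  hp <- h + 2L
  pad <- matrix(FALSE, hp, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  off_lin <- NB8[, "dc"] * hp + NB8[, "dr"]
  bit <- 2L^(0:7)
  # border directions: a pixel is peelable in a sweep only if its
  # 4-neighbour in that direction is background
  dir_off <- c(N = -1L, S = 1L, W = -hp, E = hp)
  repeat {
    changed <- FALSE
    for (d in dir_off) {
      idx <- which(pad)
      idx <- idx[!pad[idx + d]]
      if (!length(idx)) next
      for (p in idx) {
        if (!pad[p]) next
        nb <- pad[p + off_lin]
        s <- sum(nb)
        if (s <= 1L) next           # endpoint or isolated: keep
        code <- sum(bit[nb])
        if (lut[code + 1L]) {
          pad[p] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  pad[2:(h + 1L), 2:(w + 1L), drop = FALSE]
}

#' Count holes (enclosed background regions) of a binary raster
#'
#' Background is labelled with 4-connectivity (the dual of 8-connected
#' foreground); a hole is a background component containing no border
#' pixel. Used as the flood-fill oracle for topology conservation and for
#' mesh detection.
#'
#' @param mask Logical matrix.
#' @return Integer hole count.
#' @export
count_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- label_components(!mask, 4L)
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  length(setdiff(unique(lab[lab > 0L]), border))
}

#' Prune short terminal spurs from a skeleton
#'
#' Removes, in one pass, every terminal path of length at most
#' \code{max_len} pixels that ends at a junction: such spurs are typical
#' boundary artifacts of thinning a band-shaped mask. Free-standing short
#' elements (components without a junction) are never touched, so real
#' isolated fragments survive.
#'
#' @param skeleton Logical skeleton raster.
#' @param max_len Maximum spur length in pixels (0 disables).
#' @return Logical matrix.
#' @export
prune_spurs <- function(skeleton, max_len = 4L) {
  if (max_len <= 0L || !any(skeleton)) return(skeleton)
  h <- nrow(skeleton)
  cls <- classify_pixels(skeleton)
  nb_of <- function(p) {
    rc <- idx_to_rc(p, h)
    nr <- rc[1L] + NB8[, 1L]; nc <- rc[2L] + NB8[, 2L]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= ncol(skeleton)
    nb <- rc_to_idx(nr[ok], nc[ok], h)
    nb[skeleton[nb]]
  }
  drop <- integer(0)
  for (e in which(cls == 1L)) {
    path <- e
    prev <- -1L; cur <- e
    hit_node <- FALSE
    for (step in seq_len(max_len)) {
      nxt <- setdiff(nb_of(cur), prev)
      if (length(nxt) == 0L) break
      nxt <- nxt[1L]
      if (cls[nxt] == 3L) { hit_node <- TRUE; break }
      if (cls[nxt] == 1L) break     # short free element: keep
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
    if (hit_node) drop <- c(drop, path)
  }
  skeleton[drop] <- FALSE
  # a pruned spur can leave a one-pixel thickness bump on the remaining
  # line (a node only by diagonal adjacency); re-thinning removes it and
  # is a no-op on an already clean skeleton
  if (length(drop)) skeleton <- skeletonize_mask(skeleton)
  skeleton
}
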