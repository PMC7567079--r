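# Low-level raster utilities shared by the edge-detection, skeleton and
# feature modules. All rasters are plain R matrices indexed (row, col),
# row 1 at the top; logical matrices represent binary masks.

# 8-neighbourhood offsets in a fixed (row, col) order; the bit order is
# relied upon by the simple-point lookup table in thinning.R.
NB8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)
NB4 <- cbind(dr = c(-1L, 0L, 0L, 1L), dc = c(0L, -1L, 1L, 0L))

#' Shift a matrix by (dr, dc), padding with `fill`
#' @noRd
shift_mat <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L - dr):min(h, h - dr)
  cs <- max(1L, 1L - dc):min(w, w - dc)
  if (length(rs) < 1L || length(cs) < 1L) return(out)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Count foreground neighbours of every pixel (8- or 4-neighbourhood)
#' @noRd
neighbor_count <- function(mask, connectivity = 8L) {
  offs <- if (connectivity == 8L) NB8 else NB4
  acc <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs))) {
    acc <- acc + shift_mat(mask, offs[i, 1L], offs[i, 2L])
  }
  acc
}

#' Label connected components of a logical mask
#'
#' Returns an integer matrix: 0 for background, 1..k for components.
#' Foreground connectivity is 8 by default (4 for background/hole work,
#' following the standard digital-topology duality).
#' @noRd
label_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  vid <- integer(h * w)
  vid[idx] <- seq_along(idx)
  # forward offsets only, so each adjacency is built once
  offs <- if (connectivity == 8L) {
    cbind(c(1L, 0L, 1L, 1L), c(0L, 1L, 1L, -1L))
  } else {
    cbind(c(1L, 0L), c(0L, 1L))
  }
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(offs))) {
    nr <- r + offs[i, 1L]; ncl <- cc + offs[i, 2L]
    ok <- nr >= 1L & nr <= h & ncl >= 1L & ncl <= w
    nidx <- (ncl[ok] - 1L) * h + nr[ok]
    hit <- vid[nidx] > 0L
    from <- c(from, vid[idx[ok]][hit])
    to <- c(to, vid[nidx][hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Binary dilation / erosion with a (2r+1)^2 square structuring element
#' @noRd
dilate_square <- function(mask, r = 1L) {
  out <- mask
  for (k in seq_len(r)) {
    acc <- out
    for (i in seq_len(nrow(NB8))) {
      acc <- acc | shift_mat(out, NB8[i, 1L], NB8[i, 2L])
    }
    out <- acc
  }
  out
}

#' @noRd
erode_square <- function(mask, r = 1L) {
  out <- mask
  for (k in seq_len(r)) {
    acc <- out
    for (i in seq_len(nrow(NB8))) {
      acc <- acc & shift_mat(out, NB8[i, 1L], NB8[i, 2L], fill = TRUE)
    }
    out <- acc
  }
  out
}

#' Binary dilation with a Euclidean disk of radius r (pixel centres)
#' @noRd
dilate_disk <- function(mask, r) {
  if (r <= 0) return(mask)
  ri <- as.integer(ceiling(r))
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (dr in -ri:ri) for (dc in -ri:ri) {
    if (dr * dr + dc * dc <= r * r + 1e-9) {
      out <- out | shift_mat(mask, dr, dc)
    }
  }
  out
}

#' Separable Gaussian smoothing with replicate padding
#' @noRd
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m, along_rows) {
    acc <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(x)) {
      d <- x[i]
      sh <- if (along_rows) shift_replicate(m, d, 0L) else shift_replicate(m, 0L, d)
      acc <- acc + k[i] * sh
    }
    acc
  }
  conv1(conv1(img, TRUE), FALSE)
}

#' Shift with replicate (edge-clamp) padding, for smoothing
#' @noRd
shift_replicate <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

#' Linear index helpers (column-major, as R stores matrices)
#' @noRd
idx_to_rc <- function(idx, h) {
  cbind(r = ((idx - 1L) %% h) + 1L, c = ((idx - 1L) %/% h) + 1L)
}

#' @noRd
rc_to_idx <- function(r, c, h) (c - 1L) * h + r

#' Order pixel linear indices by (row, col) lexicographically
#' @noRd
order_rc <- function(idx, h) {
  rc <- idx_to_rc(idx, h)
  idx[order(rc[, 1L], rc[, 2L])]
}
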