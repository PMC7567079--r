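# Hand-built skeleton fixtures (all degree-correct under 8-connectivity:
# rings use diamond/chamfered corners so ring pixels have exactly two
# neighbours) and independent brute-force oracles implemented with plain
# base R loops -- no package internals.

mk <- function(h, w) matrix(FALSE, h, w)

# 5-px horizontal line in a 3x7 raster
fix_line <- function() {
  m <- mk(3, 7); m[2, 2:6] <- TRUE; m
}

# plus sign: full middle row and column of a 7x7 raster
fix_plus <- function() {
  m <- mk(7, 7); m[4, ] <- TRUE; m[, 4] <- TRUE; m
}

# 8-px diamond ring (every pixel has exactly 2 neighbours)
fix_ring <- function() {
  m <- mk(7, 7)
  px <- rbind(c(2, 4), c(3, 3), c(4, 2), c(5, 3), c(6, 4), c(5, 5),
              c(4, 6), c(3, 5))
  m[px] <- TRUE; m
}

# "H": two vertical strokes joined by a crossbar in a 9x9 raster
fix_h <- function() {
  m <- mk(9, 9)
  m[2:8, 2] <- TRUE; m[2:8, 8] <- TRUE; m[5, 3:7] <- TRUE
  m
}

# theta: chamfered octagonal ring with a horizontal chord, 15x18
# (chamfered corners keep every ring pixel at exactly 2 neighbours; the
# only node clusters are where the chord meets the ring)
fix_theta <- function() {
  m <- mk(15, 18)
  m[3, 5:11] <- TRUE                       # top
  m[13, 5:11] <- TRUE                      # bottom
  m[5:11, 3] <- TRUE                       # left
  m[5:11, 13] <- TRUE                      # right
  m[cbind(c(4, 4, 12, 12), c(4, 12, 4, 12))] <- TRUE  # chamfers
  m[8, 4:12] <- TRUE                       # chord
  m
}

# theta with a 4-px tail extending the chord past the right junction
fix_theta_tail <- function() {
  m <- fix_theta()
  m[8, 14:17] <- TRUE
  m
}

# --- independent oracles -------------------------------------------------

# neighbour count by explicit double loop
oracle_neighbors <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!m[r, c]) next
    n <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1L && rr <= h && cc >= 1L && cc <= w && m[rr, cc]) {
        n <- n + 1L
      }
    }
    out[r, c] <- n
  }
  out
}

# connected-component count by BFS (conn = 8 or 4)
oracle_components <- function(m, conn = 8L) {
  h <- nrow(m); w <- ncol(m)
  seen <- matrix(FALSE, h, w)
  ncomp <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!m[r0, c0] || seen[r0, c0]) next
    ncomp <- ncomp + 1L
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        if (conn == 4L && abs(dr) + abs(dc) != 1L) next
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w &&
            m[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue <- c(queue, list(c(rr, cc)))
        }
      }
    }
  }
  ncomp
}

# holes: 4-connected background components that do not touch the border
oracle_holes <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  oracle_components(!pad, 4L) - 1L  # outside background is one component
}

# pixel-level cycle rank: adjacency-pairs - pixels + components
# (valid for fixtures free of spurious 3-cliques)
oracle_cycle_rank <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pairs <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!m[r, c]) next
    for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
      rr <- r + off[1]; cc <- c + off[2]
      if (rr >= 1L && rr <= h && cc >= 1L && cc <= w && m[rr, cc]) {
        pairs <- pairs + 1L
      }
    }
  }
  pairs - sum(m) + oracle_components(m, 8L)
}

# brute-force element counts from pure pixel-neighbourhood inspection:
# extremities, nodes, junction clusters
oracle_counts <- function(m) {
  nc <- oracle_neighbors(m)
  ext <- sum(m & nc <= 1L)
  nodes <- m & nc >= 3L
  list(extremities = ext,
       nodes = sum(nodes),
       junctions = if (any(nodes)) oracle_components(nodes, 8L) else 0L,
       components = oracle_components(m, 8L),
       holes = oracle_holes(m),
       cycle_rank = oracle_cycle_rank(m))
}

# small random blob masks for conservation properties
random_blob <- function(seed, h = 48L, w = 48L, p = 0.45) {
  set.seed(seed)
  m <- matrix(stats::runif(h * w) < p, h, w)
  # one dilation pass to create solid structures
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(FALSE, h, w)
    rs <- max(1, 1 - dr):min(h, h - dr)
    cs <- max(1, 1 - dc):min(w, w - dc)
    sh[rs, cs] <- m[rs + dr, cs + dc]
    out <- out | sh
  }
  out
}
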