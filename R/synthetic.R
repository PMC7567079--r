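# Synthetic fundus generator. Vascular trees are grown on the pixel
# lattice under a strict adjacency margin: a new pixel may touch (in the
# 8-neighbourhood) only the pixel it extends. Junction, endpoint, loop and
# isolated-element counts are therefore recorded from the construction
# events themselves, and the rasterized centerline provably realises that
# topology -- ground truth is never re-measured from pixels.

#' Specification of a synthetic vascular tree image
#'
#' The defaults emulate a mouse fundus photograph at a typical small-animal
#' camera scale: a handful of primary vessels radiating from an optic-disc
#' region, stochastic bifurcations, a few anastomotic loops, short
#' disconnected fragments (capillary pieces below the resolving power of
#' the camera appear as isolated elements), vessels a few pixels wide
#' drawn dark on a brighter background, a radial background gradient and
#' mild additive noise.
#'
#' @param seed RNG seed for this image.
#' @param n_primary Number of primary vessels leaving the disc.
#' @param branch_prob Per-step bifurcation probability of a growing tip.
#' @param branch_angle_mean,branch_angle_sd Bifurcation angle (degrees).
#' @param angle_jitter_sd Per-step heading jitter (radians).
#' @param anastomosis_count Loops to close between tips of the same tree.
#' @param fragment_count Disconnected short elements to add.
#' @param vessel_width Numeric range (min, max) of rendered vessel widths
#'   in pixels; each strand draws its width from this range.
#' @param image_size Side of the square raster, >= 64 px.
#' @param noise_sd SD of additive Gaussian intensity noise (intensity in
#'   \[0, 1\]).
#' @param background_gradient Total drop of the radial background ramp.
#' @param render_blur_sd Gaussian blur (px) applied when rendering; 0
#'   draws hard-edged vessels.
#' @param stop_prob Per-step spontaneous termination probability of a tip.
#' @return Object of class \code{vasc_tree_spec}.
#' @export
vascular_tree_spec <- function(seed = 1L,
                               n_primary = 6L,
                               branch_prob = 0.055,
                               branch_angle_mean = 72,
                               branch_angle_sd = 12,
                               angle_jitter_sd = 0.12,
                               anastomosis_count = 4L,
                               fragment_count = 12L,
                               vessel_width = c(3, 5),
                               image_size = 384L,
                               noise_sd = 0.02,
                               background_gradient = 0.15,
                               render_blur_sd = 0.7,
                               stop_prob = 0.004) {
  if (image_size < 64L) stop("image_size must be >= 64", call. = FALSE)
  if (n_primary < 0L || anastomosis_count < 0L || fragment_count < 0L) {
    stop("counts must be >= 0", call. = FALSE)
  }
  if (n_primary == 0L && anastomosis_count > 0L) {
    stop("anastomoses require primary vessels (n_primary = 0)", call. = FALSE)
  }
  if (min(vessel_width) < 1) stop("vessel widths must be >= 1 px",
                                  call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_primary = as.integer(n_primary),
         branch_prob = branch_prob, branch_angle_mean = branch_angle_mean,
         branch_angle_sd = branch_angle_sd,
         angle_jitter_sd = angle_jitter_sd,
         anastomosis_count = as.integer(round(anastomosis_count)),
         fragment_count = as.integer(round(fragment_count)),
         vessel_width = vessel_width, image_size = as.integer(image_size),
         noise_sd = noise_sd, background_gradient = background_gradient,
         render_blur_sd = render_blur_sd, stop_prob = stop_prob),
    class = "vasc_tree_spec"
  )
}

# deterministic, platform-independent stream split: Lehmer-style mixing
# modulo the Mersenne prime 2^31 - 1 (all intermediates stay below 2^53,
# so the arithmetic is exact in doubles)
#' @noRd
derive_seed <- function(master, group_code, index) {
  M <- 2147483647
  h <- (abs(master) %% M)
  h <- (h * 48271 + group_code * 69621 + index * 16807 + 12345) %% M
  h <- (h * 48271) %% M
  h <- (h * 48271) %% M
  as.integer(h)
}

#' Generate the centerline topology of a synthetic vascular image
#'
#' Grows \code{n_primary} strands radially from an optic-disc circle by
#' one-pixel lattice steps with angular jitter; bifurcates with
#' probability \code{branch_prob} per step (both daughter directions must
#' be placeable, otherwise no junction is recorded); then adds
#' \code{fragment_count} free-floating short polylines and closes up to
#' \code{anastomosis_count} loops between terminated tips of the same
#' tree. Every placement respects the adjacency margin, so the raster's
#' skeleton topology equals the recorded ground truth exactly.
#'
#' @param spec A \code{\link{vascular_tree_spec}}.
#' @return List with \code{centerlines} (logical raster), \code{strands}
#'   (list of pixel-index vectors, for rendering) and \code{truth}, a
#'   \code{SyntheticGroundTruth} list: \code{junctions}, \code{endpoints},
#'   \code{loops}, \code{isolated_elements}, \code{total_length} (px,
#'   diagonal steps cost sqrt(2)) and \code{anastomoses_requested} vs
#'   \code{anastomoses_placed}.
#' @export
generate_topology <- function(spec) {
  stopifnot(inherits(spec, "vasc_tree_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  S <- spec$image_size
  occ <- matrix(FALSE, S, S)
  ctr <- (S + 1) / 2
  disc_r <- 0.08 * S
  max_r <- 0.47 * S
  total_length <- 0

  # strand bookkeeping
  strands <- list()   # each: pixels (idx vec), comp, root (start is endpoint)
  comp_junctions <- integer(0)
  n_junctions <- 0L
  tip_ends <- list()  # terminated tips eligible for anastomosis

  in_bounds <- function(r, c) r >= 2 && r <= S - 1 && c >= 2 && c <= S - 1
  occupied_nb <- function(r, c) {
    nr <- r + NB8[, 1L]; nc <- c + NB8[, 2L]
    ok <- nr >= 1 & nr <= S & nc >= 1 & nc <= S
    idx <- rc_to_idx(nr[ok], nc[ok], S)
    idx[occ[idx]]
  }
  # place q extending head p: q free, inside, every occupied neighbour == p
  can_place <- function(r, c, allowed) {
    if (!in_bounds(r, c)) return(FALSE)
    if (occ[rc_to_idx(r, c, S)]) return(FALSE)
    all(occupied_nb(r, c) %in% allowed)
  }
  # soft separation margin: no occupied pixel within Chebyshev distance
  # SEP of a new pixel, except the strand's own recent tail and pixels
  # near a declared pivot (a branch point or anastomosis endpoint, where
  # strands legitimately come close). Keeps distinct vessels far enough
  # apart that rendering at the stated widths cannot merge them.
  SEP <- 16L
  PIVOT_R <- 17L
  sep_ok <- function(r, c, recent, pivots) {
    rs <- max(1L, r - SEP):min(S, r + SEP)
    cs <- max(1L, c - SEP):min(S, c + SEP)
    win <- occ[rs, cs, drop = FALSE]
    if (!any(win)) return(TRUE)
    wi <- which(win)
    wr <- rs[((wi - 1L) %% length(rs)) + 1L]
    wc <- cs[((wi - 1L) %/% length(rs)) + 1L]
    widx <- rc_to_idx(wr, wc, S)
    stray <- !(widx %in% recent)
    if (!any(stray)) return(TRUE)
    if (!is.null(pivots) && nrow(pivots) > 0L) {
      for (pv in seq_len(nrow(pivots))) {
        near <- pmax(abs(wr - pivots[pv, 1L]), abs(wc - pivots[pv, 2L])) <= PIVOT_R
        stray <- stray & !near
      }
    }
    !any(stray)
  }
  RECENT_N <- 20L
  dir_angles <- atan2(NB8[, 1L], NB8[, 2L])
  pick_dir <- function(heading) {
    d <- abs(((dir_angles - heading + pi) %% (2 * pi)) - pi)
    order(d)[1:3]  # best direction and its two 45-degree neighbours
  }
  step_len <- function(k) if (sum(abs(NB8[k, ])) == 2L) sqrt(2) else 1

  tips <- list()
  add_strand <- function(r, c, comp, root) {
    occ[rc_to_idx(r, c, S)] <<- TRUE
    strands[[length(strands) + 1L]] <<- list(
      pixels = rc_to_idx(r, c, S), comp = comp, root = root,
      consumed = FALSE, kind = "tree", depth = 1L)
    length(strands)
  }

  # primary vessels on the optic-disc circle; all root positions are
  # shared as pivots so strands may start close together at the disc and
  # are forced apart only once they leave its vicinity
  if (spec$n_primary > 0L) {
    base <- stats::runif(1, 0, 2 * pi)
    for (i in seq_len(spec$n_primary)) {
      a <- base + 2 * pi * (i - 1) / spec$n_primary +
        stats::rnorm(1, 0, 0.3 / spec$n_primary)
      r0 <- round(ctr + disc_r * sin(a))
      c0 <- round(ctr + disc_r * cos(a))
      if (!in_bounds(r0, c0) || occ[rc_to_idx(r0, c0, S)] ||
          length(occupied_nb(r0, c0))) next
      comp <- length(comp_junctions) + 1L
      comp_junctions[comp] <- 0L
      sid <- add_strand(r0, c0, comp, root = TRUE)
      tips[[length(tips) + 1L]] <- list(
        r = r0, c = c0, heading = a, strand = sid, comp = comp,
        since_branch = 0L, depth = 1L,
        recent = rc_to_idx(r0, c0, S), pivots = NULL)
    }
    if (length(tips)) {
      root_rc <- do.call(rbind, lapply(tips, function(t) c(t$r, t$c)))
      for (i in seq_along(tips)) tips[[i]]$pivots <- root_rc
    }
  }

  terminate_tip <- function(tip) {
    s <- strands[[tip$strand]]
    if (length(s$pixels) >= 3L) {
      tip_ends[[length(tip_ends) + 1L]] <<- list(
        idx = s$pixels[length(s$pixels)],
        prev = s$pixels[length(s$pixels) - 1L],
        comp = tip$comp, strand = tip$strand)
    }
  }

  # growth loop
  while (length(tips)) {
    survivors <- list()
    for (tip in tips) {
      p_idx <- rc_to_idx(tip$r, tip$c, S)
      if (sqrt((tip$r - ctr)^2 + (tip$c - ctr)^2) >= max_r ||
          stats::runif(1) < spec$stop_prob) {
        terminate_tip(tip); next
      }
      if (is.null(tip$straight) || tip$straight <= 0L) {
        tip$heading <- tip$heading + stats::rnorm(1, 0, spec$angle_jitter_sd)
      } else {
        stats::rnorm(1)  # keep the RNG stream aligned across phases
        tip$straight <- tip$straight - 1L
      }
      placed <- FALSE
      for (k in pick_dir(tip$heading)) {
        nr <- tip$r + NB8[k, 1L]; nc <- tip$c + NB8[k, 2L]
        if (can_place(nr, nc, p_idx) &&
            sep_ok(nr, nc, tip$recent, tip$pivots)) {
          q_idx <- rc_to_idx(nr, nc, S)
          occ[q_idx] <- TRUE
          strands[[tip$strand]]$pixels <- c(strands[[tip$strand]]$pixels,
                                            q_idx)
          total_length <- total_length + step_len(k)
          branch_pivot <- p_idx  # the pixel that becomes the junction
          tip$r <- nr; tip$c <- nc
          tip$since_branch <- tip$since_branch + 1L
          tip$recent <- utils::tail(c(tip$recent, q_idx), RECENT_N)
          placed <- TRUE
          # bifurcation: the daughter is anchored at the *previous* head,
          # which then has neighbours {predecessor, continuation,
          # daughter} and really acquires degree 3
          if (tip$since_branch >= 10L &&
              stats::runif(1) < spec$branch_prob) {
            sgn <- sample(c(-1, 1), 1)
            ang <- (stats::rnorm(1, spec$branch_angle_mean,
                                 spec$branch_angle_sd)) * pi / 180
            child_heading <- tip$heading + sgn * ang
            pivot_rc <- idx_to_rc(branch_pivot, S)
            child_pivots <- matrix(pivot_rc, nrow = 1L)
            for (kk in pick_dir(child_heading)) {
              cr <- pivot_rc[1L] + NB8[kk, 1L]
              cc <- pivot_rc[2L] + NB8[kk, 2L]
              if (can_place(cr, cc, branch_pivot) &&
                  sep_ok(cr, cc, tip$recent, child_pivots)) {
                c_idx <- rc_to_idx(cr, cc, S)
                occ[c_idx] <- TRUE
                total_length <- total_length + step_len(kk)
                n_junctions <- n_junctions + 1L
                comp_junctions[tip$comp] <- comp_junctions[tip$comp] + 1L
                strands[[length(strands) + 1L]] <- list(
                  pixels = c_idx, comp = tip$comp, root = FALSE,
                  consumed = FALSE, kind = "tree", depth = tip$depth + 1L,
                  spawn_cost = step_len(kk))
                survivors[[length(survivors) + 1L]] <- list(
                  r = cr, c = cc, heading = child_heading,
                  strand = length(strands), comp = tip$comp,
                  since_branch = 0L, depth = tip$depth + 1L,
                  recent = utils::tail(c(tip$recent, c_idx), RECENT_N),
                  pivots = child_pivots, straight = 8L)
                tip$since_branch <- 0L
                tip$pivots <- child_pivots
                tip$straight <- 4L
                strands[[tip$strand]]$has_child <- TRUE
                break
              }
            }
          }
          break
        }
      }
      if (placed) survivors[[length(survivors) + 1L]] <- tip
      else terminate_tip(tip)
    }
    tips <- survivors
  }

  # prune sub-resolution daughters: a non-root tree strand shorter than
  # MIN_DAUGHTER px (and without children of its own) is below the
  # resolving power of the stated vessel widths -- it is erased and its
  # junction is not part of the stated scene
  MIN_DAUGHTER <- 16L
  keep <- rep(TRUE, length(strands))
  for (si in seq_along(strands)) {
    s_ <- strands[[si]]
    if (identical(s_$kind, "tree") && !isTRUE(s_$root) &&
        !isTRUE(s_$has_child) && length(s_$pixels) < MIN_DAUGHTER) {
      occ[s_$pixels] <- FALSE
      rc_px <- idx_to_rc(s_$pixels, S)
      dd <- abs(diff(rc_px))
      total_length <- total_length - s_$spawn_cost -
        (if (nrow(rc_px) > 1L) sum(ifelse(rowSums(dd) == 2L, sqrt(2), 1)) else 0)
      n_junctions <- n_junctions - 1L
      comp_junctions[s_$comp] <- comp_junctions[s_$comp] - 1L
      keep[si] <- FALSE
    }
  }
  if (!all(keep)) {
    keep_tips <- vapply(tip_ends, function(t) keep[t$strand], logical(1))
    tip_ends <- tip_ends[keep_tips]
    strands <- strands[keep]
    for (te in seq_along(tip_ends)) {
      tip_ends[[te]]$strand <- sum(keep[seq_len(tip_ends[[te]]$strand)])
    }
  }

  # disconnected fragments
  n_fragments_placed <- 0L
  if (spec$fragment_count > 0L) {
    for (f in seq_len(spec$fragment_count)) {
      done <- FALSE
      for (try in 1:40) {
        rr <- stats::runif(1, disc_r + 2, max_r)
        aa <- stats::runif(1, 0, 2 * pi)
        r0 <- round(ctr + rr * sin(aa)); c0 <- round(ctr + rr * cos(aa))
        if (!in_bounds(r0, c0) || occ[rc_to_idx(r0, c0, S)] ||
            length(occupied_nb(r0, c0)) ||
            !sep_ok(r0, c0, integer(0), NULL)) next
        len <- sample(5:14, 1)
        heading <- stats::runif(1, 0, 2 * pi)
        placed_px <- rc_to_idx(r0, c0, S)
        occ[placed_px] <- TRUE
        r <- r0; c <- c0; seg_len <- 0
        for (s in seq_len(len)) {
          heading <- heading + stats::rnorm(1, 0, spec$angle_jitter_sd)
          ok <- FALSE
          for (k in pick_dir(heading)) {
            nr <- r + NB8[k, 1L]; nc <- c + NB8[k, 2L]
            if (can_place(nr, nc, rc_to_idx(r, c, S)) &&
                sep_ok(nr, nc, placed_px, NULL)) {
              occ[rc_to_idx(nr, nc, S)] <- TRUE
              placed_px <- c(placed_px, rc_to_idx(nr, nc, S))
              seg_len <- seg_len + step_len(k)
              r <- nr; c <- nc; ok <- TRUE; break
            }
          }
          if (!ok) break
        }
        if (length(placed_px) >= 3L) {
          comp <- length(comp_junctions) + 1L
          comp_junctions[comp] <- 0L
          strands[[length(strands) + 1L]] <- list(
            pixels = placed_px, comp = comp, root = TRUE, consumed = FALSE,
            kind = "fragment", depth = 99L)
          total_length <- total_length + seg_len
          n_fragments_placed <- n_fragments_placed + 1L
          done <- TRUE
        } else {
          occ[placed_px] <- FALSE  # roll back a failed fragment
        }
        if (done) break
      }
    }
  }

  # anastomoses: close loops between terminated tips of the same tree
  n_loops <- 0L
  consumed_tip <- logical(length(tip_ends))
  if (spec$anastomosis_count > 0L && length(tip_ends) >= 2L) {
    rc_all <- idx_to_rc(vapply(tip_ends, function(t) as.integer(t$idx), integer(1)), S)
    pairs <- expand.grid(i = seq_along(tip_ends), j = seq_along(tip_ends))
    pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
    same <- vapply(seq_len(nrow(pairs)), function(k) {
      tip_ends[[pairs$i[k]]]$comp == tip_ends[[pairs$j[k]]]$comp
    }, logical(1))
    pairs <- pairs[same, , drop = FALSE]
    if (nrow(pairs)) {
      d <- pmax(abs(rc_all[pairs$i, 1L] - rc_all[pairs$j, 1L]),
                abs(rc_all[pairs$i, 2L] - rc_all[pairs$j, 2L]))
      keep <- d >= 48 & d <= S / 2
      pairs <- pairs[keep, , drop = FALSE]; d <- d[keep]
      ord <- order(d)
      for (k in ord) {
        if (n_loops >= spec$anastomosis_count) break
        i <- pairs$i[k]; j <- pairs$j[k]
        if (consumed_tip[i] || consumed_tip[j]) next
        A <- tip_ends[[i]]; B <- tip_ends[[j]]
        # guided walk from tip A toward tip B, same margin discipline as
        # growth; cells are occupied provisionally and rolled back if the
        # walk cannot reach B
        brc <- idx_to_rc(B$idx, S)
        cur <- idx_to_rc(A$idx, S)
        prev_idx <- A$idx
        arc <- integer(0)
        arc_len <- 0
        reached <- FALSE
        max_steps <- 4L * as.integer(d[k]) + 40L
        for (step in seq_len(max_steps)) {
          if (max(abs(cur - brc)) == 1L &&
              length(arc) >= 2L) { reached <- TRUE; break }
          bearing <- atan2(brc[1L] - cur[1L], brc[2L] - cur[2L])
          moved <- FALSE
          dd_ang <- abs(((dir_angles - bearing + pi) %% (2 * pi)) - pi)
          dirs <- if (length(arc) == 0L) order(dd_ang) else
            order(dd_ang)[1:5]  # allow sliding along obstacles
          arc_pivots <- rbind(idx_to_rc(A$idx, S), idx_to_rc(B$idx, S))
          for (kk in dirs) {
            nr <- cur[1L] + NB8[kk, 1L]; nc <- cur[2L] + NB8[kk, 2L]
            if (can_place(nr, nc, c(prev_idx, B$idx)) &&
                sep_ok(nr, nc, utils::tail(arc, RECENT_N), arc_pivots)) {
              q_idx <- rc_to_idx(nr, nc, S)
              occ[q_idx] <- TRUE
              arc <- c(arc, q_idx)
              arc_len <- arc_len + step_len(kk)
              prev_idx <- q_idx
              cur <- c(nr, nc)
              moved <- TRUE
              break
            }
          }
          if (!moved) break
        }
        if (!reached || length(arc) < 2L) {
          occ[arc] <- FALSE  # roll back the failed arc
          next
        }
        ids <- arc
        # closing step from the last arc cell onto tip B
        last_rc <- idx_to_rc(ids[length(ids)], S)
        total_length <- total_length + arc_len +
          (if (sum(abs(last_rc - brc)) == 2L) sqrt(2) else 1)
        strands[[length(strands) + 1L]] <- list(
          pixels = ids, comp = A$comp, root = FALSE, consumed = FALSE,
          is_arc = TRUE, kind = "arc", depth = 99L)
        strands[[A$strand]]$consumed <- TRUE
        strands[[B$strand]]$consumed <- TRUE
        consumed_tip[i] <- TRUE; consumed_tip[j] <- TRUE
        n_loops <- n_loops + 1L
      }
    }
  }

  # ground-truth counts from construction events. A strand's start is a
  # free end when the strand began in empty space (tree roots, fragments);
  # its terminal end is free unless an anastomosis consumed it.
  # Anastomosis arcs attach at both ends and contribute no endpoints.
  comp_pixels <- integer(length(comp_junctions))
  for (s in strands) {
    comp_pixels[s$comp] <- comp_pixels[s$comp] + length(s$pixels)
  }
  n_endpoints <- 0L
  for (s in strands) {
    np <- length(s$pixels)
    if (np == 0L) next
    if (comp_pixels[s$comp] == 1L) {
      n_endpoints <- n_endpoints + 1L  # degenerate single-pixel component
      next
    }
    start_free <- isTRUE(s$root)
    end_free <- !isTRUE(s$consumed) && !isTRUE(s$is_arc)
    n_endpoints <- n_endpoints + start_free + end_free
  }
  n_isolated <- sum(comp_junctions == 0L & comp_pixels >= 2L)

  truth <- list(
    junctions = n_junctions,
    endpoints = n_endpoints,
    loops = n_loops,
    isolated_elements = n_isolated,
    total_length = total_length,
    fragments_placed = n_fragments_placed,
    anastomoses_requested = spec$anastomosis_count,
    anastomoses_placed = n_loops
  )
  list(centerlines = occ,
       strands = lapply(strands, `[[`, "pixels"),
       strand_kind = vapply(strands, function(s)
         if (is.null(s$kind)) "tree" else s$kind, character(1)),
       strand_depth = vapply(strands, function(s)
         if (is.null(s$depth)) 1L else as.integer(s$depth), integer(1)),
       truth = truth,
       tip_ends = tip_ends)
}

#' @noRd
bresenham_line <- function(a, b) {
  r0 <- a[1L]; c0 <- a[2L]; r1 <- b[1L]; c1 <- b[2L]
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dc - dr
  out <- matrix(NA_integer_, dr + dc + 1L, 2L)
  n <- 0L
  repeat {
    n <- n + 1L
    out[n, ] <- c(r0, c0)
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c0 <- c0 + sc }
    if (e2 < dc) { err <- err + dc; r0 <- r0 + sr }
  }
  out[seq_len(n), , drop = FALSE]
}

#' Render a grayscale fundus-like image from centerline topology
#'
#' Vessels are drawn dark on a brighter background (fundus polarity),
#' dilated to their per-strand width, lightly blurred, then a radial
#' background gradient and additive Gaussian noise are applied and the
#' result is clipped to \[0, 1\]. Rendering never alters the recorded
#' ground truth: truth lives at the topology stage, so rasterization and
#' noise effects are measured by the pipeline, not hidden.
#'
#' @param topology Result of \code{\link{generate_topology}}.
#' @param spec The same \code{\link{vascular_tree_spec}}.
#' @return Numeric intensity matrix in \[0, 1\].
#' @export
render_fundus <- function(topology, spec) {
  S <- spec$image_size
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(derive_seed(spec$seed, 7L, 1L))

  # width taper: primary vessels at the top of the stated range, deeper
  # generations and capillary-like fragments/arcs at the bottom
  wmin <- min(spec$vessel_width); wmax <- max(spec$vessel_width)
  depth <- topology$strand_depth
  kind <- topology$strand_kind
  widths <- pmax(wmin, wmax * 0.85^(pmax(depth, 1L) - 1L))
  widths[kind != "tree"] <- wmin
  widths <- widths + stats::runif(length(widths), -0.2, 0.2)
  widths <- pmin(pmax(widths, wmin), wmax)
  radius <- pmax(0, (widths - 1) / 2)
  rad_round <- round(radius * 2) / 2  # half-pixel radius classes
  vessel <- matrix(FALSE, S, S)
  for (rr in sort(unique(rad_round))) {
    sel <- which(rad_round == rr)
    m <- matrix(FALSE, S, S)
    m[unlist(topology$strands[sel])] <- TRUE
    vessel <- vessel | dilate_disk(m, rr)
  }

  ctr <- (S + 1) / 2
  d <- sqrt(outer((seq_len(S) - ctr)^2, (seq_len(S) - ctr)^2, `+`))
  bg <- 0.85 - spec$background_gradient * (d / max(d))^2
  img <- bg
  img[vessel] <- 0.30
  if (spec$render_blur_sd > 0) img <- gaussian_blur(img, spec$render_blur_sd)
  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(S * S, 0, spec$noise_sd), S, S)
  }
  pmin(pmax(img, 0), 1)
}

#' Generate one synthetic fundus image with ground truth
#'
#' Convenience wrapper: \code{\link{generate_topology}} plus
#' \code{\link{render_fundus}}.
#'
#' @param spec A \code{\link{vascular_tree_spec}}.
#' @return List with \code{image}, \code{centerlines}, \code{truth} and
#'   \code{spec}.
#' @export
generate_fundus <- function(spec = vascular_tree_spec()) {
  topo <- generate_topology(spec)
  list(image = render_fundus(topo, spec),
       centerlines = topo$centerlines,
       strands = topo$strands,
       truth = topo$truth,
       spec = spec)
}

#' Default diabetic-like effect: more disjunction, fewer closed loops
#'
#' Multiplicative shifts applied to the control spec to emulate the
#' diabetic phenotype seen in fundus analysis: the network appears more
#' disjointed (more isolated elements, tips that fail to anastomose stay
#' free and are counted as branches), with fewer and smaller meshes.
#'
#' @return Named list of multiplicative factors on spec fields.
#' @export
disjunction_effect <- function() {
  list(fragment_count = 2.0, anastomosis_count = 0.25)
}

#' Generate a two-group cohort of synthetic fundus images
#'
#' Group A uses \code{control_spec} as is; group B applies the
#' multiplicative \code{effect} shifts to it. Every image gets its own
#' seed derived deterministically from \code{seed} by an integer-hash
#' stream split, so cohorts are bit-reproducible across platforms.
#'
#' @param n_per_group Images per group, >= 2.
#' @param control_spec Base \code{\link{vascular_tree_spec}}.
#' @param effect Named list of multiplicative factors applied to numeric
#'   spec fields for group B (default \code{\link{disjunction_effect}}).
#' @param seed Master seed.
#' @param render If FALSE (default) only topology + truth are generated,
#'   which is enough for feature work on noise-free centerlines; set TRUE
#'   to also render images.
#' @return List with elements \code{control} and \code{case}, each a list
#'   of per-image results (as \code{\link{generate_fundus}} /
#'   \code{\link{generate_topology}}), and \code{specs}.
#' @export
generate_cohort <- function(n_per_group, control_spec = vascular_tree_spec(),
                            effect = disjunction_effect(), seed = 1L,
                            render = FALSE) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  case_spec <- control_spec
  for (nm in names(effect)) {
    if (!nm %in% names(case_spec)) {
      stop("effect names unknown spec field: ", nm, call. = FALSE)
    }
    val <- case_spec[[nm]] * effect[[nm]]
    if (nm %in% c("n_primary", "anastomosis_count", "fragment_count",
                  "image_size")) {
      val <- as.integer(round(val))
    }
    case_spec[[nm]] <- val
  }
  gen_group <- function(base_spec, code) {
    lapply(seq_len(n_per_group), function(i) {
      sp <- base_spec
      sp$seed <- derive_seed(seed, code, i)
      if (render) generate_fundus(sp) else {
        out <- generate_topology(sp)
        out$spec <- sp
        out
      }
    })
  }
  list(control = gen_group(control_spec, 1L),
       case = gen_group(case_spec, 2L),
       specs = list(control = control_spec, case = case_spec))
}

#' Feature tables for a generated cohort
#'
#' Computes the 20-metric feature set for every image of both groups,
#' either from the noise-free centerline rasters (\code{source =
#' "centerline"}, deterministic and render-independent) or by running the
#' full image pipeline on rendered images (\code{source = "pipeline"},
#' requires \code{render = TRUE} in \code{\link{generate_cohort}}).
#'
#' @param cohort From \code{\link{generate_cohort}}.
#' @param source \code{"centerline"} or \code{"pipeline"}.
#' @param config A \code{\link{vasc_config}}.
#' @return List of two feature tables (\code{control}, \code{case}).
#' @export
cohort_feature_tables <- function(cohort, source = c("centerline", "pipeline"),
                                  config = vasc_config()) {
  source <- match.arg(source)
  one_group <- function(group, label) {
    rows <- lapply(seq_along(group), function(i) {
      f <- if (source == "centerline") {
        skeleton_features(group[[i]]$centerlines, config)
      } else {
        if (is.null(group[[i]]$image)) {
          stop("cohort was generated without render = TRUE", call. = FALSE)
        }
        run_pipeline(group[[i]]$image, config)
      }
      cbind(data.frame(subject_id = sprintf("%s_%02d", label, i),
                       group_label = label, timepoint_label = "t0"),
            as.data.frame(f))
    })
    do.call(rbind, rows)
  }
  list(control = one_group(cohort$control, "control"),
       case = one_group(cohort$case, "case"))
}
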