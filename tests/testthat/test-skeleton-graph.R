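test_that("pixel classification matches the neighbour-count rule", {
  line <- fix_line()
  cls <- classify_pixels(line)
  expect_equal(sum(cls == 1L), 2L)  # two endpoints
  expect_equal(sum(cls == 2L), 3L)  # three interior slabs
  expect_equal(sum(cls == 3L), 0L)

  # rasterized plus sign: the centre has 4 neighbours and the four arm
  # pixels diagonal-adjacent to it have >= 3, forming one 5-pixel cluster
  plus <- fix_plus()
  cls <- classify_pixels(plus)
  expect_equal(sum(cls == 3L), 5L)
  expect_equal(sum(cls == 1L), 4L)
  expect_equal(nrow(cluster_junctions(cls)), 1L)

  # a closed diamond ring: every pixel has exactly 2 neighbours
  ring <- fix_ring()
  cls <- classify_pixels(ring)
  expect_equal(sum(cls == 2L), 8L)
  expect_equal(sum(cls != 2L & ring), 0L)

  # degenerate isolated pixel is an extremity
  m <- mk(3, 3); m[2, 2] <- TRUE
  expect_equal(classify_pixels(m)[2, 2], 1L)

  # agreement with the brute-force neighbour oracle on random blobs
  for (seed in 1:5) {
    b <- random_blob(seed)
    sk <- skeletonize_mask(b)
    nc <- oracle_neighbors(sk)
    cls <- classify_pixels(sk)
    expect_identical(cls == 1L, sk & nc <= 1L)
    expect_identical(cls == 3L, sk & nc >= 3L)
  }
})

test_that("junction clustering follows 8-connectivity", {
  # no node pixels -> no junctions
  expect_equal(nrow(cluster_junctions(classify_pixels(fix_line()))), 0L)

  # two diagonal-adjacent node pixels form one junction of size 2
  cm <- matrix(0L, 5, 5)
  cm[2, 2] <- 3L; cm[3, 3] <- 3L
  jn <- cluster_junctions(cm)
  expect_equal(nrow(jn), 1L)
  expect_equal(jn$size, 2L)
  expect_equal(jn$r, 2.5)
  expect_equal(jn$c, 2.5)

  # H shape: two junction clusters, one per vertical stroke
  jn <- cluster_junctions(classify_pixels(fix_h()))
  expect_equal(nrow(jn), 2L)
})

test_that("edge tracing lengths follow the geodesic step convention", {
  g <- build_skeleton_graph(fix_line())
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$length, 4.0)

  diagonal <- mk(5, 5); diagonal[cbind(2:4, 2:4)] <- TRUE
  g <- build_skeleton_graph(diagonal)
  expect_equal(g$edges$length, 2 * sqrt(2))

  # pixel-count emulation via diagonal_step = 1
  g <- build_skeleton_graph(diagonal, diagonal_step = 1)
  expect_equal(g$edges$length, 2)

  # closed ring traces as one loop edge including the closing step
  g <- build_skeleton_graph(fix_ring())
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$a_type, "loop")
  expect_equal(g$edges$length, 8 * sqrt(2))

  # theta: 2 junctions, 3 edges between them
  g <- build_skeleton_graph(fix_theta())
  expect_equal(nrow(g$junctions), 2L)
  expect_equal(nrow(g$edges), 3L)
  expect_true(all(g$edges$a_type == "junction" &
                  g$edges$b_type == "junction"))
})

test_that("pixel conservation and handshake hold on random skeletons", {
  for (seed in c(1:6, 101:106)) {
    sk <- if (seed > 100) {
      generate_topology(vascular_tree_spec(
        seed = seed, image_size = 128, anastomosis_count = 0L))$centerlines
    } else {
      skeletonize_mask(random_blob(seed))
    }
    g <- build_skeleton_graph(sk)
    cls <- g$class_map
    interior <- unlist(lapply(g$edges$path, function(p) {
      p[cls[p] == 2L]
    }))
    # every slab pixel is interior to exactly one edge
    expect_equal(sort(unique(interior)), sort(which(cls == 2L)))
    expect_equal(anyDuplicated(interior), 0L)
    # handshake: junction degree equals number of edge endpoint references
    if (nrow(g$junctions)) {
      refs <- c(g$edges$a_id[g$edges$a_type == "junction"],
                g$edges$b_id[g$edges$b_type == "junction"])
      for (j in g$junctions$id) {
        jp <- g$junctions$pixels[[j]]
        # degree of the cluster: skeleton neighbours outside the cluster
        deg <- 0L
        for (p in jp) {
          rc <- arrayInd(p, dim(sk))
          for (dr in -1:1) for (dc in -1:1) {
            if (dr == 0 && dc == 0) next
            rr <- rc[1] + dr; cc <- rc[2] + dc
            if (rr < 1 || rr > nrow(sk) || cc < 1 || cc > ncol(sk)) next
            q <- (cc - 1L) * nrow(sk) + rr
            if (sk[q] && !(q %in% jp) && cls[q] != 3L) deg <- deg + 1L
          }
        }
        expect_equal(sum(refs == j), deg)
      }
    }
  }
})

test_that("cycle rank of the graph matches the hole count of the raster", {
  for (seed in 201:208) {
    topo <- generate_topology(vascular_tree_spec(
      seed = seed, image_size = 192))
    sk <- topo$centerlines
    g <- build_skeleton_graph(sk)
    # vertices: junctions + extremities; edges: traced paths; loop edges
    # contribute one independent cycle each
    v <- nrow(g$junctions) + sum(g$class_map == 1L)
    e <- nrow(g$edges)
    n_comp <- max(0L, max(g$components))
    loops_raster <- oracle_holes(sk)
    # cycle rank: E - V + C, with each vertexless ring (traced as a single
    # loop edge) contributing exactly one cycle
    expect_equal(e - v + n_comp - sum(g$edges$a_type == "loop"),
                 loops_raster)
  }
})

test_that("an inconsistent class map is rejected", {
  cm <- matrix(0L, 3, 5)
  cm[2, 2:4] <- c(2L, 2L, 2L)  # slab labelled pixels forming a bare line
  jn <- cluster_junctions(cm)
  expect_error(trace_edges(cm, jn), "thinning contract")
})
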