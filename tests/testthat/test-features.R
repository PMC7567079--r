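test_that("element classification follows the taxonomy", {
  # lone line: one isolated element, nothing else
  g <- build_skeleton_graph(fix_line())
  expect_equal(classify_elements(g), "isolated")

  # plus sign: four branches
  g <- build_skeleton_graph(fix_plus())
  expect_equal(sort(classify_elements(g)),
               rep("branch", 4))

  # junction-free ring: isolated element
  g <- build_skeleton_graph(fix_ring())
  expect_equal(classify_elements(g), "isolated")

  # theta: three segments; with a tail: three segments and one branch
  g <- build_skeleton_graph(fix_theta())
  expect_equal(table(classify_elements(g))[["segment"]], 3L)
  g <- build_skeleton_graph(fix_theta_tail())
  cl <- classify_elements(g)
  expect_equal(sum(cl == "segment"), 3L)
  expect_equal(sum(cl == "branch"), 1L)
})

test_that("master structure resolves by fixpoint pruning", {
  # a pure tree prunes away entirely
  g <- build_skeleton_graph(fix_h())
  cl <- classify_elements(g)
  ms <- find_master_structure(g, cl)
  expect_equal(sum(ms$master_edges), 0L)
  expect_length(ms$master_junctions, 0L)
  expect_equal(nrow(find_meshes(g, ms)), 0L)

  # theta: all three segments are master, both junctions are master
  g <- build_skeleton_graph(fix_theta())
  cl <- classify_elements(g)
  ms <- find_master_structure(g, cl)
  expect_equal(sum(ms$master_edges), 3L)
  expect_length(ms$master_junctions, 2L)

  # a pendant tail does not change the master structure
  g2 <- build_skeleton_graph(fix_theta_tail())
  ms2 <- find_master_structure(g2, classify_elements(g2))
  expect_equal(sum(ms2$master_edges), 3L)
  expect_length(ms2$master_junctions, 2L)
})

test_that("meshes are the enclosed faces of the master subgraph", {
  # junction-free ring: no master structure, hence no meshes under the
  # default scope, but one bounded face under mesh_scope = "all"
  f <- skeleton_features(fix_ring(), vasc_config(min_mesh_px = 0))
  expect_equal(f$meshes, 0)
  expect_equal(f$isolated_segments, 1)
  f_all <- skeleton_features(fix_ring(),
                             vasc_config(mesh_scope = "all",
                                         min_mesh_px = 0))
  expect_equal(f_all$meshes, 1)
  # diamond of "radius" 2 encloses 5 background pixels
  expect_equal(f_all$mesh_area, 5)

  # theta: two meshes; their areas sum to the ring interior minus the
  # chord pixels (flood-fill oracle on the fixture)
  g <- build_skeleton_graph(fix_theta())
  ms <- find_master_structure(g, classify_elements(g))
  me <- find_meshes(g, ms)
  expect_equal(nrow(me), 2L)
  expect_equal(oracle_holes(fix_theta()), 2L)
  # direct oracle: mesh areas sum to the enclosed background pixel count
  enclosed <- sum(me$area)
  m <- fix_theta()
  # enclosed pixels = all background pixels unreachable from the border
  reach <- matrix(FALSE, nrow(m), ncol(m))
  queue <- list()
  for (r in 1:nrow(m)) for (c in 1:ncol(m)) {
    if ((r %in% c(1, nrow(m)) || c %in% c(1, ncol(m))) && !m[r, c]) {
      queue <- c(queue, list(c(r, c))); reach[r, c] <- TRUE
    }
  }
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (off in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- p[1] + off[1]; cc <- p[2] + off[2]
      if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m) &&
          !m[rr, cc] && !reach[rr, cc]) {
        reach[rr, cc] <- TRUE
        queue <- c(queue, list(c(rr, cc)))
      }
    }
  }
  expect_equal(enclosed, sum(!m & !reach))
})

test_that("feature identities and degenerate cases hold", {
  # empty raster: all 20 features are zero
  f <- skeleton_features(mk(10, 10))
  expect_true(all(unlist(f) == 0))
  expect_setequal(attr(f, "zero_denominator"),
                  c("mean_mesh_size", "mesh_index", "branching_interval"))

  # plus sign: 4 branches, no segments, branching interval 0
  f <- skeleton_features(fix_plus())
  expect_equal(f$branches, 4)
  expect_equal(f$segments, 0)
  expect_equal(f$pieces, 4)
  # interval is 0 through a zero numerator (no segments), so it is not
  # flagged as a zero-denominator case (the denominator is 4 branches)
  expect_equal(f$branching_interval, 0)
  expect_false("branching_interval" %in% attr(f, "zero_denominator"))

  # tailed theta: mesh_index = master length / 3, branching interval =
  # segment length / 1
  f <- skeleton_features(fix_theta_tail())
  expect_equal(f$master_segments, 3)
  expect_equal(f$mesh_index, f$master_segment_length / 3)
  expect_equal(f$branches, 1)
  expect_equal(f$branching_interval, f$segment_length / 1)
})

test_that("counts match the brute-force oracle on the fixture library", {
  fixtures <- list(line = fix_line(), plus = fix_plus(), ring = fix_ring(),
                   h = fix_h(), theta = fix_theta(),
                   theta_tail = fix_theta_tail())
  for (nm in names(fixtures)) {
    m <- fixtures[[nm]]
    f <- skeleton_features(m, vasc_config(min_mesh_px = 0))
    o <- oracle_counts(m)
    expect_equal(f$extremities, o$extremities, info = nm)
    expect_equal(f$nodes, o$nodes, info = nm)
    expect_equal(f$junctions, o$junctions, info = nm)
    # meshes under scope "all" equal the raster hole count
    f_all <- skeleton_features(m, vasc_config(mesh_scope = "all",
                                              min_mesh_px = 0))
    expect_equal(f_all$meshes, o$holes, info = nm)
    # the pixel-adjacency cycle-rank formula is exact only when junction
    # clusters contain no 3-cliques: check it on the clique-free fixtures
    if (nm %in% c("line", "ring")) {
      expect_equal(o$holes, o$cycle_rank, info = nm)
    }
  }
})

test_that("deleting a branch never changes meshes or master structure", {
  cfg <- vasc_config(min_mesh_px = 0)
  for (seed in 301:305) {
    sk <- generate_topology(vascular_tree_spec(
      seed = seed, image_size = 192))$centerlines
    g <- build_skeleton_graph(sk)
    cl <- classify_elements(g)
    br <- which(cl == "branch")
    if (length(br) == 0L) next
    f0 <- skeleton_features(sk, cfg)
    # remove one branch: its interior slabs and its extremity endpoint
    e <- br[1L]
    path <- g$edges$path[[e]]
    drop <- path[g$class_map[path] != 3L]
    sk2 <- sk; sk2[drop] <- FALSE
    f1 <- skeleton_features(sk2, cfg)
    # the master subgraph's pixels are unchanged: same meshes, same area,
    # same master junctions (removing a branch may fuse two master
    # segments that met at a degree-3 junction, so the count itself is
    # not asserted)
    expect_equal(f1$meshes, f0$meshes)
    expect_equal(f1$mesh_area, f0$mesh_area)
    expect_equal(f1$master_junctions, f0$master_junctions)
    expect_equal(f1$branches, f0$branches - 1)
  }
})
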