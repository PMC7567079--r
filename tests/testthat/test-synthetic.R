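test_that("tree specs validate their inputs", {
  expect_error(vascular_tree_spec(image_size = 32), "image_size")
  expect_error(vascular_tree_spec(n_primary = 0, anastomosis_count = 2),
               "primary")
  expect_error(vascular_tree_spec(vessel_width = c(0.5, 2)), "width")
  expect_error(vascular_tree_spec(noise_sd = -0.1), "noise_sd")
})

test_that("unbranched primaries are isolated radial lines", {
  spec <- vascular_tree_spec(seed = 4, n_primary = 4L, branch_prob = 0,
                             anastomosis_count = 0L, fragment_count = 0L,
                             image_size = 128L)
  topo <- generate_topology(spec)
  tr <- topo$truth
  expect_equal(tr$junctions, 0L)
  expect_equal(tr$endpoints, 8L)
  expect_equal(tr$loops, 0L)
  expect_equal(tr$isolated_elements, 4L)
  expect_equal(oracle_components(topo$centerlines, 8L), 4L)
})

test_that("generation is deterministic and leaves the RNG state alone", {
  spec <- vascular_tree_spec(seed = 9, image_size = 128L)
  set.seed(123)
  a <- generate_topology(spec)
  r1 <- runif(1)
  set.seed(123)
  b <- generate_topology(spec)
  r2 <- runif(1)
  expect_identical(a$centerlines, b$centerlines)
  expect_identical(a$truth, b$truth)
  expect_identical(r1, r2)  # caller's RNG stream undisturbed

  g1 <- generate_fundus(spec)
  g2 <- generate_fundus(spec)
  expect_identical(g1$image, g2$image)
})

test_that("anastomoses add exactly the recorded number of loops", {
  # same seed with and without anastomoses: growth is identical, the loop
  # count rises by exactly the number of placed arcs
  spec0 <- vascular_tree_spec(seed = 2, anastomosis_count = 0L)
  speck <- vascular_tree_spec(seed = 2, anastomosis_count = 4L)
  t0 <- generate_topology(spec0)$truth
  tk <- generate_topology(speck)$truth
  expect_equal(t0$loops, 0L)
  expect_gte(tk$anastomoses_placed, 1L)
  expect_equal(tk$loops - t0$loops, tk$anastomoses_placed)
  expect_equal(tk$junctions, t0$junctions)
  expect_equal(tk$endpoints, t0$endpoints - 2L * tk$anastomoses_placed)
})

test_that("rendering realises the stated scene without touching truth", {
  # identity render: width 1, no blur, no noise, flat background
  spec <- vascular_tree_spec(seed = 6, image_size = 128L,
                             vessel_width = c(1, 1), noise_sd = 0,
                             background_gradient = 0, render_blur_sd = 0)
  topo <- generate_topology(spec)
  img <- render_fundus(topo, spec)
  expect_true(all(img[topo$centerlines] == 0.30))
  expect_true(all(img[!topo$centerlines] == 0.85))

  # noise changes pixels, not truth
  spec_noisy <- vascular_tree_spec(seed = 6, image_size = 128L,
                                   vessel_width = c(1, 1), noise_sd = 0.05)
  t1 <- generate_topology(spec_noisy)$truth
  expect_identical(t1, topo$truth)
})

test_that("ground truth equals features on the centerline raster", {
  # varied spec corners, including degenerate ones
  specs <- list(
    vascular_tree_spec(seed = 101, image_size = 128L),
    vascular_tree_spec(seed = 102, image_size = 160L, n_primary = 3L),
    vascular_tree_spec(seed = 103, image_size = 128L, branch_prob = 0.1,
                       fragment_count = 0L),
    vascular_tree_spec(seed = 104, image_size = 192L,
                       fragment_count = 25L),
    vascular_tree_spec(seed = 105, image_size = 256L,
                       anastomosis_count = 6L)
  )
  for (sp in specs) {
    topo <- generate_topology(sp)
    f <- skeleton_features(topo$centerlines)
    tr <- topo$truth
    expect_equal(f$junctions, tr$junctions)
    expect_equal(f$extremities, tr$endpoints)
    expect_equal(f$meshes, tr$loops)
    expect_equal(f$isolated_segments, tr$isolated_elements)
    expect_equal(f$total_length, tr$total_length)
  }
})

test_that("cohorts derive per-image seeds deterministically", {
  c1 <- generate_cohort(3, vascular_tree_spec(image_size = 128L), seed = 5)
  c2 <- generate_cohort(3, vascular_tree_spec(image_size = 128L), seed = 5)
  expect_identical(lapply(c1$control, `[[`, "truth"),
                   lapply(c2$control, `[[`, "truth"))
  expect_identical(lapply(c1$case, `[[`, "truth"),
                   lapply(c2$case, `[[`, "truth"))
  # control and case images use distinct seed streams
  expect_false(identical(c1$control[[1]]$truth, c1$case[[1]]$truth))
  # identity effect leaves the case spec equal to the control spec
  cid <- generate_cohort(2, vascular_tree_spec(image_size = 128L),
                         effect = list(), seed = 1)
  expect_identical(cid$specs$control, cid$specs$case)
  # the disjunction effect shifts the intended knobs
  expect_equal(c1$specs$case$fragment_count,
               as.integer(round(2.0 * c1$specs$control$fragment_count)))
  expect_lt(c1$specs$case$anastomosis_count,
            c1$specs$control$anastomosis_count)
  expect_error(generate_cohort(1), "n_per_group")
  expect_error(generate_cohort(3, effect = list(bogus_field = 2)), "bogus")
})
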