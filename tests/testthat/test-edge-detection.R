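test_that("canny handles degenerate and analytic cases", {
  # constant image: zero gradient everywhere, empty mask, no error
  expect_false(any(canny_edges(matrix(0.5, 20, 20), 1, 0.1, 0.3)))

  # vertical step edge: a single 1-px-wide vertical run within 1 px of
  # the step location
  img <- matrix(0, 32, 48); img[, 25:48] <- 1
  e <- canny_edges(img, 1, 0.6, 0.9)
  cols <- unique(which(e, arr.ind = TRUE)[, 2])
  expect_length(cols, 1L)
  expect_lte(abs(cols - 24.5), 1)
  # 1 px wide: one response per row in the interior
  expect_true(all(rowSums(e[3:30, ]) == 1))

  # a dark ridge yields two flanking contours, and every response pixel
  # is a directional local maximum of the gradient magnitude (brute force)
  img <- matrix(1, 40, 60); img[18:23, ] <- 0
  e <- canny_edges(img, 1.4, 0.2, 0.5)
  rows <- sort(unique(which(e, arr.ind = TRUE)[, 1]))
  expect_true(length(rows) == 2L && rows[1] < 18 + 3 && rows[2] > 23 - 3)
  sm <- retvasc:::gaussian_blur(img, 1.4)
  gr <- matrix(0, 40, 60); gc <- matrix(0, 40, 60)
  gr[2:39, ] <- (sm[3:40, ] - sm[1:38, ]) / 2
  gc[, 2:59] <- (sm[, 3:60] - sm[, 1:58]) / 2
  mag <- sqrt(gr^2 + gc^2)
  for (p in which(e)) {
    rc <- arrayInd(p, c(40L, 60L))
    dir <- c(gr[p], gc[p]) / mag[p]
    step <- round(dir)
    r1 <- rc[1] + step[1]; c1 <- rc[2] + step[2]
    r2 <- rc[1] - step[1]; c2 <- rc[2] - step[2]
    ok1 <- r1 < 1 || r1 > 40 || c1 < 1 || c1 > 60 || mag[p] >= mag[r1, c1]
    ok2 <- r2 < 1 || r2 > 40 || c2 < 1 || c2 > 60 || mag[p] >= mag[r2, c2]
    expect_true(ok1 && ok2)
  }
})

test_that("canny is invariant to affine intensity rescaling", {
  set.seed(11)
  topo <- generate_topology(vascular_tree_spec(seed = 11, image_size = 128,
                                               fragment_count = 3L))
  spec <- vascular_tree_spec(seed = 11, image_size = 128,
                             fragment_count = 3L)
  img <- render_fundus(topo, spec)
  a <- canny_edges(img, 1.4, 0.1, 0.3)
  b <- canny_edges(0.2 + 0.5 * img, 1.4, 0.1, 0.3)
  expect_identical(a, b)
})

test_that("raising the high quantile never adds strong seed pixels", {
  img <- render_fundus(
    topo <- generate_topology(vascular_tree_spec(seed = 5, image_size = 128)),
    vascular_tree_spec(seed = 5, image_size = 128))
  lowq <- 0.05
  masks <- lapply(c(0.3, 0.5, 0.7), function(hq) {
    canny_edges(img, 1.4, lowq, hq)
  })
  # with a fixed low threshold, a higher high threshold keeps a subset of
  # hysteresis-selected components
  expect_false(any(masks[[3]] & !masks[[2]]))
  expect_false(any(masks[[2]] & !masks[[1]]))
})

test_that("clean_mask filters, closes and crops as specified", {
  # 3-px speckle below min_object_px disappears
  m <- mk(12, 12); m[3, 3:5] <- TRUE
  expect_false(any(clean_mask(m, min_object_px = 10L)))

  # min_object_px = 0 and no field mask: closing only
  m2 <- clean_mask(m, min_object_px = 0L, close_radius = 1L)
  expect_true(all(m2[m]))

  # two 1-px lines one pixel apart fuse into one solid 3-px band
  m <- mk(5, 7)
  m[2, 2:6] <- TRUE; m[4, 2:6] <- TRUE
  cm <- clean_mask(m, min_object_px = 0L, close_radius = 1L)
  expect_true(all(cm[2:4, 2:6]))
  expect_equal(oracle_components(cm, 8L), 1L)

  # circular field mask clears everything outside the disc
  m <- matrix(TRUE, 21, 21)
  cm <- clean_mask(m, min_object_px = 0L, circular_mask_fraction = 0.5,
                   close_radius = 0L)
  expect_false(cm[1, 1])
  expect_true(cm[11, 11])
  expect_false(any(cm & outer((1:21 - 11)^2, (1:21 - 11)^2, `+`) >
                     (0.5 * 21 / 2)^2))

  # sliver filling closes thin enclosed gaps but keeps large holes
  m <- matrix(TRUE, 20, 20)
  m[8:9, 5:15] <- FALSE       # thin sliver, inscribed radius 1
  m2 <- matrix(TRUE, 30, 30)
  m2[8:20, 8:20] <- FALSE     # large hole
  expect_true(all(clean_mask(m, 0L, close_radius = 0L, fill_sliver_px = 2L)))
  out2 <- clean_mask(m2, 0L, close_radius = 0L, fill_sliver_px = 2L)
  expect_false(any(out2[8:20, 8:20]))
})

test_that("skeletonization is thin and topology-preserving", {
  # a 1-px line is already thin: unchanged
  line <- fix_line()
  expect_identical(skeletonize_mask(line), line)

  # empty mask
  expect_false(any(skeletonize_mask(mk(8, 8))))

  # solid square annulus of width 5: single 1-px ring with one hole
  m <- mk(30, 30); m[6:25, 6:25] <- TRUE; m[11:20, 11:20] <- FALSE
  sk <- skeletonize_mask(m)
  expect_equal(oracle_components(sk, 8L), 1L)
  expect_equal(oracle_holes(sk), 1L)
  # thinness: no 2x2 all-foreground block
  expect_equal(sum(sk[-30, -30] & sk[-1, -30] & sk[-30, -1] & sk[-1, -1]),
               0L)

  # component and hole conservation on random blobs (flood-fill oracle)
  for (seed in 1:12) {
    b <- random_blob(seed)
    sk <- skeletonize_mask(b)
    expect_equal(oracle_components(sk, 8L), oracle_components(b, 8L))
    expect_equal(oracle_holes(sk), oracle_holes(b))
    expect_true(all(b[sk]))  # skeleton is a subset of the mask
  }
})

test_that("spur pruning removes junction spurs but not free elements", {
  # line with a 2-px spur at mid-length
  m <- mk(9, 15); m[5, 2:14] <- TRUE; m[3:4, 8] <- TRUE
  pr <- prune_spurs(m, 4L)
  expect_false(any(pr[3:4, 8]))
  expect_true(all(pr[5, 2:14]))
  # a free-standing 3-px element is untouched
  m2 <- mk(7, 7); m2[3, 2:4] <- TRUE
  expect_identical(prune_spurs(m2, 4L), m2)
  # a terminal path longer than max_len survives (4 slab pixels above the
  # junction base: pruned at max_len 4, kept at max_len 3)
  m3 <- mk(12, 15); m3[6, 2:14] <- TRUE; m3[1:5, 8] <- TRUE
  expect_true(all(prune_spurs(m3, 3L)[1:4, 8]))
  expect_false(any(prune_spurs(m3, 4L)[1:4, 8]))
})
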