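test_that("fixed thresholding follows the >= convention", {
  img <- matrix(0, 4, 4)
  expect_false(any(threshold_channel(img, 1)$grid))
  img2 <- matrix(c(0, 10), 4, 4)
  m <- threshold_channel(img2, 5)
  expect_identical(m$grid, img2 == 10)
  expect_error(threshold_channel(matrix(-1, 2, 2), 1), "non-negative")
})

test_that("otsu matches exhaustive between-class variance search", {
  # two-level image: any threshold in (2, 8] must give the same mask
  img <- matrix(c(2, 8, 2, 8, 8, 2), 2, 3)
  m <- threshold_channel(img, "otsu")
  expect_identical(m$grid, threshold_channel(img, 5)$grid)

  # random multi-level image vs brute-force search over candidate cuts
  set.seed(42)
  img <- matrix(sample(c(1, 3, 7, 9, 15), 100, replace = TRUE,
                       prob = c(0.3, 0.2, 0.1, 0.2, 0.2)), 10, 10)
  m <- threshold_channel(img, "otsu")
  v <- as.vector(img)
  cands <- sort(unique(v))[-1]
  bcv <- vapply(cands, function(t) {
    lo <- v[v < t]; hi <- v[v >= t]
    length(lo) / length(v) * length(hi) / length(v) *
      (mean(lo) - mean(hi))^2
  }, 0)
  best <- cands[which.max(bcv)]
  expect_identical(m$grid, matrix(v >= best, 10, 10))

  expect_error(threshold_channel(matrix(3, 5, 5), "otsu"), "constant")
})

test_that("detect_cells places centroids by the pixel-center convention", {
  g <- matrix(FALSE, 20, 20)
  g[11:13, 11:13] <- TRUE  # 0-based rows/cols 10..12
  cells <- detect_cells(binary_mask(g, 0.5), min_area_px = 1)
  expect_identical(nrow(cells), 1L)
  expect_equal(cells$x_um, 5.75)
  expect_equal(cells$y_um, 5.75)

  empty <- detect_cells(binary_mask(matrix(FALSE, 5, 5), 1))
  expect_identical(nrow(empty), 0L)
})

test_that("connectivity semantics: diagonal touch joins under 8, not 4", {
  g <- matrix(FALSE, 6, 6)
  g[2, 2] <- TRUE
  g[3, 3] <- TRUE
  c8 <- detect_cells(binary_mask(g, 1), min_area_px = 1, connectivity = 8)
  c4 <- detect_cells(binary_mask(g, 1), min_area_px = 1, connectivity = 4)
  expect_identical(nrow(c8), 1L)
  expect_identical(nrow(c4), 2L)
  expect_identical(floodfill_components(g, 8)$n, 1L)
  expect_identical(floodfill_components(g, 4)$n, 2L)
})

test_that("component labelling matches a flood-fill oracle on random masks", {
  set.seed(7)
  for (rep in 1:5) {
    g <- matrix(runif(30 * 30) < 0.35, 30, 30)
    for (conn in c(4, 8)) {
      cells <- detect_cells(binary_mask(g, 1), min_area_px = 1,
                            connectivity = conn)
      oracle <- floodfill_components(g, conn)
      expect_identical(nrow(cells), oracle$n)
      # areas must agree as multisets
      expect_identical(sort(cells$area_px),
                       sort(as.integer(table(oracle$labels[oracle$labels > 0]))))
    }
  }
})

test_that("detection is invariant to whole-pixel translation", {
  set.seed(8)
  g <- matrix(FALSE, 40, 40)
  g[5:7, 5:7] <- TRUE
  g[20:22, 30:32] <- TRUE
  shifted <- matrix(FALSE, 40, 40)
  shifted[3:40, 2:40] <- g[1:38, 1:39]
  a <- detect_cells(binary_mask(g, 1), min_area_px = 1)
  b <- detect_cells(binary_mask(shifted, 1), min_area_px = 1)
  expect_identical(nrow(a), nrow(b))
  expect_equal(sort(b$x_um - a$x_um), c(1, 1))
  expect_equal(sort(b$y_um - a$y_um), c(2, 2))
})

test_that("min_area_px filters small components", {
  g <- matrix(FALSE, 10, 10)
  g[2, 2] <- TRUE            # area 1
  g[5:7, 5:7] <- TRUE        # area 9
  cells <- detect_cells(binary_mask(g, 1), min_area_px = 4)
  expect_identical(nrow(cells), 1L)
  expect_identical(cells$area_px, 9L)
})

test_that("render_masks stamps disks at pixel centers", {
  cells <- cell_table(data.frame(id = 1L, x_um = 10, y_um = 10,
                                 PGRN = FALSE),
                      window_um = c(20, 20), channels = "PGRN")
  stack <- render_masks(cells, render_config(pixel_size_um = 1,
                                             r_nucleus_um = 2,
                                             r_marker_um = 3))
  # brute-force enumeration of pixel centers within 2 um of (10, 10)
  expected <- matrix(FALSE, 20, 20)
  for (i in 0:19) for (j in 0:19) {
    expected[i + 1, j + 1] <-
      (j + 0.5 - 10)^2 + (i + 0.5 - 10)^2 <= 4
  }
  expect_identical(stack$channels$DAPI, expected)
  # PGRN-negative cell leaves the PGRN channel empty
  expect_false(any(stack$channels$PGRN))

  empty <- cell_table(data.frame(id = integer(0), x_um = numeric(0),
                                 y_um = numeric(0)),
                      window_um = c(20, 20), channels = character(0))
  s2 <- render_masks(empty, render_config())
  expect_false(any(s2$channels$DAPI))
})

test_that("render_masks rejects cells outside the field", {
  cells <- cell_table(data.frame(id = 7L, x_um = 30, y_um = 5),
                      channels = character(0))
  expect_error(render_masks(cells, render_config(image_shape_px = c(20, 20))),
               "ids 7")
})

test_that("assign_markers applies the overlap-fraction rule exactly", {
  # nucleus of 10 px in a known spot
  g <- matrix(FALSE, 12, 12)
  g[4:8, 4:5] <- TRUE  # 10 pixels
  cells <- detect_cells(binary_mask(g, 1), min_area_px = 1)
  marker <- matrix(FALSE, 12, 12)
  marker[4:6, 4] <- TRUE  # 3 of the 10 nucleus pixels
  stack <- mask_stack(list(DAPI = g, M = marker), 1)
  pos <- assign_markers(cells, stack,
                        overlap_rule(dilation_um = 0,
                                     min_overlap_fraction = 0.25))
  neg <- assign_markers(cells, stack,
                        overlap_rule(dilation_um = 0,
                                     min_overlap_fraction = 0.35))
  expect_true(pos$M)
  expect_false(neg$M)

  # marker superset of captured region is positive at any fraction <= 1
  full <- mask_stack(list(DAPI = g, M = matrix(TRUE, 12, 12)), 1)
  expect_true(assign_markers(cells, full,
                             overlap_rule(0, 1))$M)
  # all-false channel leaves every cell negative
  none <- mask_stack(list(DAPI = g, M = matrix(FALSE, 12, 12)), 1)
  expect_false(assign_markers(cells, none, overlap_rule())$M)

  expect_error(assign_markers(cells, stack, channels = "missing"),
               "missing")
})

test_that("positive_fraction counts over all cells and rejects empties", {
  cells <- toy_cells()
  expect_equal(positive_fraction(cells, "PGRN"), 2 / 6)
  expect_equal(positive_fraction(cells, "GzmB"), 1 / 6)
  none <- cells[cells$PanCK & cells$CD8, ]
  expect_error(positive_fraction(none, "PGRN"), "zero cells")
  # invariance to order and duplication
  shuf <- cells[sample(nrow(cells)), ]
  expect_equal(positive_fraction(shuf, "PGRN"), 2 / 6)
  dup <- rbind(as.data.frame(cells), transform(as.data.frame(cells),
                                               id = id + 100))
  dup <- cell_table(dup, channels = default_channels())
  expect_equal(positive_fraction(dup, "PGRN"), 2 / 6)
})

test_that("mask stack round-trips through PNG + JSON sidecar", {
  cells <- generate_tissue(sim_config(window_um = c(100, 100),
                                      lambda_stroma = 2e-3,
                                      nest_parent_intensity = 0,
                                      lambda_cd8 = 1e-3, seed = 4))
  stack <- render_masks(cells, render_config())
  dir <- withr::local_tempdir()
  write_mask_stack(stack, dir)
  back <- read_mask_stack(dir)
  expect_identical(back$channels, stack$channels)
  expect_equal(back$pixel_size_um, stack$pixel_size_um)
})
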