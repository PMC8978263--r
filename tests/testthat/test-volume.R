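test_that("sphere occupancy converges to the analytic volume with finer spacing", {
  vol_true <- 4 / 3 * pi * 27          # r = 3 mm
  errs <- vapply(c(0.55, 0.35, 0.15), function(sp) {
    n <- ceiling(8 / sp)
    grid <- GridSpec(c(n, n, n), sp)
    st <- Structure("sphere", list(center = rep(n * sp / 2, 3), radius = 3),
                    tissueLibrary("blood"), 2)
    occ <- rasterizeStructure(st, grid)
    abs(sum(occ) * sp^3 - vol_true) / vol_true
  }, numeric(1))
  expect_lt(errs[3], 0.02)
  expect_true(all(diff(errs) < 0))     # error decreases with spacing
})

test_that("grid-aligned cuboids rasterize exactly; off-grid spheres vanish", {
  grid <- GridSpec(c(10, 10, 10), 0.5)
  st <- Structure("cuboid", list(corner = c(1, 1, 1), extent = c(2, 1.5, 1)),
                  tissueLibrary("blood"), 2)
  occ <- rasterizeStructure(st, grid)
  expect_true(all(occ %in% c(0, 1)))
  expect_equal(sum(occ) * 0.5^3, 2 * 1.5 * 1)

  out <- Structure("sphere", list(center = c(50, 50, 50), radius = 2),
                   tissueLibrary("blood"), 2)
  expect_equal(sum(rasterizeStructure(out, grid)), 0)

  bad <- st
  expect_error(Structure("donut", list(), tissueLibrary("blood")),
               "unsupported")
})

test_that("parallelepiped and elliptical tube rasterize to their analytic volumes", {
  grid <- GridSpec(c(40, 40, 40), 0.25)
  pp <- Structure("parallelepiped",
                  list(corner = c(2, 2, 2), e1 = c(3, 0.5, 0),
                       e2 = c(0, 3, 0.5), e3 = c(0.5, 0, 3)),
                  tissueLibrary("blood"), 2)
  v <- sum(rasterizeStructure(pp, grid)) * 0.25^3
  v_true <- abs(det(cbind(c(3, 0.5, 0), c(0, 3, 0.5), c(0.5, 0, 3))))
  expect_lt(abs(v - v_true) / v_true, 0.02)

  tube <- Structure("elliptical_tube",
                    list(start = c(5, 1, 5), end = c(5, 9, 5),
                         radius_a = 1.5, radius_b = 1),
                    tissueLibrary("blood"), 2)
  vt <- sum(rasterizeStructure(tube, grid)) * 0.25^3
  expect_lt(abs(vt - pi * 1.5 * 1 * 8) / (pi * 1.5 * 1 * 8), 0.02)
})

test_that("model-based creation shares capacity by priority and is order-independent", {
  grid <- GridSpec(c(12, 12, 12), 0.5)
  sph <- Structure("sphere", list(center = c(3, 3, 3), radius = 1.2),
                   tissueLibrary("blood", oxygenation = 1), priority = 2)
  cub <- Structure("cuboid", list(corner = c(1.5, 1.5, 1.5),
                                  extent = c(3, 3, 3)),
                   tissueLibrary("muscle"), priority = 1)
  bg <- Structure("background", composition = tissueLibrary("water"))
  v1 <- createModelBasedVolume(list(sph, cub, bg), grid, 800)
  v2 <- createModelBasedVolume(list(bg, cub, sph), grid, 800)

  # voxel fully inside both gets the higher-priority (sphere) properties
  cc <- voxelCenters(grid)
  ix <- which.min(abs(cc$x - 3))
  blood <- mixComposition(tissueLibrary("blood", oxygenation = 1), 800)
  expect_equal(v1@mua[["800"]][ix, ix, ix], blood$mua, tolerance = 1e-10)
  expect_equal(v1@segmentation[ix, ix, ix], 1)

  # permuting distinct priorities leaves all property grids unchanged
  expect_equal(v1@mua[["800"]], v2@mua[["800"]])
  expect_equal(v1@sos, v2@sos)

  # occupancy claims sum to 1: background + structures blend, so a voxel
  # with fractional sphere occupancy interpolates mua linearly
  occ <- rasterizeStructure(sph, grid)
  water <- mixComposition(tissueLibrary("water"), 800)
  frac_idx <- which(occ > 0.2 & occ < 0.8)[1]
  cub_occ <- rasterizeStructure(cub, grid)[frac_idx]
  muscle <- mixComposition(tissueLibrary("muscle"), 800)
  rest <- 1 - occ[frac_idx]
  expected <- occ[frac_idx] * blood$mua +
    min(cub_occ, rest) * muscle$mua +
    (rest - min(cub_occ, rest)) * water$mua
  expect_equal(v1@mua[["800"]][frac_idx], expected, tolerance = 1e-10)

  expect_error(createModelBasedVolume(list(sph, cub), grid, 800),
               "background")
})

test_that("empty scenes give uniform background properties", {
  grid <- GridSpec(c(6, 6, 6), 0.5)
  v <- createModelBasedVolume(
    list(Structure("background", composition = tissueLibrary("muscle"))),
    grid, c(700, 900))
  m7 <- mixComposition(tissueLibrary("muscle"), 700)
  expect_true(all(abs(v@mua[["700"]] - m7$mua) < 1e-12))
  expect_true(all(v@segmentation == 1))
  expect_equal(sort(names(v@mua)), c("700", "900"))
})

test_that("segmentation-based volumes map labels verbatim without blending", {
  grid <- GridSpec(c(8, 8, 8), 0.5)
  mask <- array(1L, dim = c(8, 8, 8))
  mask[, , 5:8] <- 2L
  lm <- list("1" = tissueLibrary("dermis"), "2" = tissueLibrary("muscle"))
  v <- createSegmentationBasedVolume(mask, lm, grid, 800)
  d <- mixComposition(tissueLibrary("dermis"), 800)
  m <- mixComposition(tissueLibrary("muscle"), 800)
  expect_true(all(v@mua[["800"]][, , 1:4] == d$mua))
  expect_true(all(v@mua[["800"]][, , 5:8] == m$mua))
  expect_equal(length(unique(as.vector(v@mua[["800"]]))), 2L) # sharp interface
  expect_equal(v@segmentation, array(as.numeric(mask), dim(mask)))

  mask[1, 1, 1] <- 7L
  expect_error(createSegmentationBasedVolume(mask, lm, grid, 800), "7")
  expect_error(createSegmentationBasedVolume(mask[1:4, , ], lm, grid, 800),
               "shape")
})

test_that("segmentation masks round-trip through raw binary files", {
  mask <- array(sample(1:3, 60, replace = TRUE), dim = c(3, 4, 5))
  f <- tempfile(fileext = ".bin")
  writeBin(as.integer(mask), f, size = 4L)
  r <- readSegmentationMask(f, shape = c(3, 4, 5))
  expect_equal(r, array(as.integer(mask), dim(mask)))
})

test_that("vessel trees are deterministic and degenerate to straight lines", {
  bounds <- rbind(c(0, 0, 0), c(20, 20, 20))
  p_straight <- list(max_bend_deg = 0, bifurcation_prob = 0, step_mm = 1)
  t1 <- growVesselTree(c(10, 10, 10), c(0, 0, 1), 1, p_straight, 5, bounds)
  # all segments collinear along +z
  expect_true(all(abs(t1$x1 - t1$x0) < 1e-12))
  expect_true(all(t1$z1 - t1$z0 > 0.999))
  # straight exit path: floor(distance to box exit / step) +/- 1 segments
  expect_lte(abs(nrow(t1) - 10), 1)

  t2 <- growVesselTree(c(10, 10, 10), c(0, 0, 1), 1, p_straight, 5, bounds)
  expect_identical(t1, t2)

  t3 <- growVesselTree(c(10, 10, 2), c(0, 0, 1), 1.5,
                       list(bifurcation_prob = 0.3, max_bend_deg = 20),
                       7, bounds)
  t4 <- growVesselTree(c(10, 10, 2), c(0, 0, 1), 1.5,
                       list(bifurcation_prob = 0.3, max_bend_deg = 20),
                       7, bounds)
  expect_identical(t3, t4)
  expect_gt(nrow(t3), 5)

  expect_warning(growVesselTree(c(1, 1, 1), c(0, 0, 2), 1, p_straight, 1,
                                bounds), "unit")
  expect_error(growVesselTree(c(1, 1, 1), c(0, 0, 1), 1,
                              list(step_mm = 0), 1, bounds), "step")
  expect_error(growVesselTree(c(1, 1, 1), c(0, 0, 1), 0.1,
                              list(min_radius_mm = 0.5), 1, bounds),
               "min_radius")
})

test_that("vessel-tree structures rasterize and claim voxels", {
  grid <- GridSpec(c(24, 24, 24), 0.5)
  bounds <- rbind(c(0, 0, 0), c(12, 12, 12))
  segs <- growVesselTree(c(6, 6, 1), c(0, 0, 1), 1,
                         list(bifurcation_prob = 0.2, max_bend_deg = 15,
                              min_radius_mm = 0.4), 3, bounds)
  st <- Structure("vessel_tree", list(segments = segs),
                  tissueLibrary("blood"), 2)
  occ <- rasterizeStructure(st, grid)
  expect_gt(sum(occ > 0.5), 10)
})

test_that("deformation fields are bounded, deterministic, and shift adhering layers", {
  grid <- GridSpec(c(30, 30, 30), 0.5)
  d0 <- makeDeformation(0, 5, 1, grid)
  expect_equal(evalDeformation(d0, c(1, 5, 10), c(1, 5, 10)), c(0, 0, 0))

  d <- makeDeformation(2, 5, 3, grid)
  cc <- voxelCenters(grid)
  g <- expand.grid(x = cc$x, y = cc$y)
  off <- evalDeformation(d, g$x, g$y)
  expect_lte(max(abs(off)), 2 + 1e-9)
  expect_gt(max(off) - min(off), 0.5)   # actually deforms

  d2 <- makeDeformation(2, 5, 3, grid)
  expect_equal(evalDeformation(d2, g$x, g$y), off)

  # a layer with the adhere flag follows the height field: top surface
  # depth varies by at most 2 * amplitude
  layer <- Structure("layer", list(z_start = 4, z_end = 8),
                     tissueLibrary("dermis"), 1, partial_volume = FALSE,
                     adhere_to_deformation = TRUE)
  occ <- rasterizeStructure(layer, grid, deformation = d)
  top <- apply(occ, c(1, 2), function(col) {
    w <- which(col > 0)
    if (length(w) == 0) NA_real_ else cc$z[w[1]]
  })
  expect_lte(max(top, na.rm = TRUE) - min(top, na.rm = TRUE), 4 + 0.5)
  expect_gt(max(top, na.rm = TRUE) - min(top, na.rm = TRUE), 0.4)
})
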