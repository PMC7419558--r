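test_that("FBP localizes a noise-free sphere within 2 voxels in-plane", {
  ctr <- c(21L, 19L, 24L)
  ph <- sphere_phantom(c(40L, 40L, 48L), ctr, r_vox = 6)
  place <- default_geometry(ph, 51, pitch_mm = 0.5)
  pset <- project_noiseless(ph, place$geometry,
                            phantom_origin_mm = place$phantom_origin_mm)
  grid <- default_recon_grid(ph, place$phantom_origin_mm,
                             in_plane = 0.5, slice = 0.5)
  vol <- fbp_reconstruct(pset, grid)
  peak <- arrayInd(which.max(vol$voxels), dim(vol$voxels))
  expect_lte(max(abs(peak[1:2] - ctr[1:2])), 2)  # same 0.5 mm sampling
})

test_that("reconstruction is linear and all-zero input gives zero output", {
  geom <- acquisition_geometry(3, det_shape = c(40, 40), pitch_mm = 0.5)
  grid <- recon_grid(origin = c(0, 0, 0), voxel = c(0.5, 0.5, 0.5),
                     dims = c(20, 20, 10))
  zero <- structure(list(images = rep(list(matrix(0, 40, 40)), 3),
                         I0 = NULL, geometry = geom, noise_meta = NULL),
                    class = "projection_set")
  vz <- fbp_reconstruct(zero, grid, line_integrals = TRUE)
  expect_equal(max(abs(vz$voxels)), 0)

  set.seed(5)
  li <- rep(list(matrix(runif(1600), 40, 40)), 3)
  p1 <- structure(list(images = li, I0 = NULL, geometry = geom,
                       noise_meta = NULL), class = "projection_set")
  p3 <- p1
  p3$images <- lapply(li, function(m) 3 * m)
  v1 <- fbp_reconstruct(p1, grid, line_integrals = TRUE)
  v3 <- fbp_reconstruct(p3, grid, line_integrals = TRUE)
  expect_equal(v3$voxels, 3 * v1$voxels, tolerance = 1e-12)
  # missing air reference
  expect_error(fbp_reconstruct(zero, grid), "I0|reference")
})

test_that("out-of-plane artifact energy decreases from P=3 to P=25", {
  ctr <- c(16L, 16L, 24L)
  ph <- sphere_phantom(c(32L, 32L, 48L), ctr, r_vox = 5)
  zvar <- vapply(c(3L, 25L), function(p) {
    place <- default_geometry(ph, p, pitch_mm = 0.5)
    pset <- project_noiseless(ph, place$geometry,
                              phantom_origin_mm = place$phantom_origin_mm)
    grid <- default_recon_grid(ph, place$phantom_origin_mm, 0.5, 0.5)
    vol <- fbp_reconstruct(pset, grid)
    prof <- vol$voxels[ctr[1], ctr[2], ]
    out_of_plane <- prof[abs(seq_along(prof) - ctr[3]) > 8]
    var(out_of_plane)
  }, numeric(1))
  expect_lt(zvar[2], zvar[1])
})

test_that("butterworth3d has unit DC gain and 1/sqrt(2) at the cutoff", {
  cst <- array(4.2, dim = c(16, 16, 8))
  expect_equal(butterworth3d(cst, 0.25, 4), cst, tolerance = 1e-9)

  amp_ratio <- function(freq, cutoff, order) {
    n <- 64L
    x <- array(0, dim = c(n, 8, 4))
    s <- sin(2 * pi * freq * (0:(n - 1)))
    for (j in 1:8) for (k in 1:4) x[, j, k] <- s
    y <- butterworth3d(x, cutoff, order)
    max(abs(y[, 1, 1])) / max(abs(x[, 1, 1]))
  }
  expect_equal(amp_ratio(0.25, 0.25, 4), 1 / sqrt(2), tolerance = 0.01)
  expect_equal(amp_ratio(0.40625, 0.25, 4),
               1 / sqrt(1 + (0.40625 / 0.25)^8), tolerance = 0.01)
  expect_error(butterworth3d(cst, 0.6), "cutoff")
  expect_error(butterworth3d(cst, 0), "cutoff")
})

test_that("slab extraction groups slices and attaches truth by depth", {
  grid <- recon_grid(origin = c(0, 0, 0), voxel = c(0.27, 0.27, 0.2),
                     dims = c(12, 10, 250))
  vol <- structure(list(voxels = array(1.5, dim = c(12, 10, 250)),
                        grid = grid, geometry = NULL, provenance = NULL),
                   class = "recon_volume")
  slabs <- slab_volume(vol, thickness = 1)
  expect_length(slabs, 50)   # 50 mm depth -> 50 one-mm slabs
  expect_true(all(vapply(slabs, function(s) all(s$pixels == 1.5),
                         logical(1))))
  # lesion centre at depth 12.4 mm -> 0-based slab index 12
  slabs2 <- slab_volume(vol, thickness = 1,
                        lesion = list(center_mm = c(1, 1, 12.4),
                                      diameter_mm = 8))
  flagged <- which(vapply(slabs2, function(s) s$truth$present, logical(1)))
  expect_equal(slabs2[[flagged]]$slab_index, 12L)
  expect_error(slab_volume(vol, thickness = 0), "thickness")
})

test_that("mean and max slabbing operators differ as expected", {
  grid <- recon_grid(origin = c(0, 0, 0), voxel = c(0.5, 0.5, 0.5),
                     dims = c(4, 4, 4))
  vox <- array(rep(1:4, each = 16), dim = c(4, 4, 4))
  vol <- structure(list(voxels = vox, grid = grid), class = "recon_volume")
  expect_equal(slab_volume(vol, 1)[[1]]$pixels, matrix(1.5, 4, 4))
  expect_equal(slab_volume(vol, 1, method = "max")[[1]]$pixels,
               matrix(2, 4, 4))
})

test_that("breast mask comes from phantom support and conserves area", {
  ph <- generate_phantom(0.3, c(40L, 40L, 24L), seed = 3, voxel_size = 0.5)
  grid <- recon_grid(origin = c(0, 0, 0), voxel = c(0.6, 0.6, 0.5),
                     dims = c(34, 34, 24))
  mask <- build_breast_mask(ph, grid, phantom_origin_mm = c(0, 0, 0))
  foot <- apply(ph$labels != 0L, c(1, 2), any)
  area_phantom <- sum(foot) * 0.5^2
  area_mask <- sum(mask) * 0.6^2
  expect_lt(abs(area_mask - area_phantom) / area_phantom, 0.02)
  # full-field phantom -> full mask
  full <- uniform_phantom(c(10L, 10L, 4L), "adipose", voxel_size = 0.5)
  g2 <- recon_grid(origin = c(0, 0, 0), voxel = c(0.5, 0.5, 0.5),
                   dims = c(10, 10, 4))
  expect_true(all(build_breast_mask(full, g2, c(0, 0, 0))))
  # all-air phantom -> degenerate error
  air <- uniform_phantom(c(10L, 10L, 4L), "air", voxel_size = 0.5)
  expect_error(build_breast_mask(air, g2, c(0, 0, 0)), "support")
})

test_that("the simulated case pipeline is deterministic per seed", {
  opts <- reduced_study_options(grid_shape = c(32L, 32L, 48L))
  ph <- generate_phantom(0.3, opts$grid_shape, seed = 4, voxel_size = 0.5,
                         target_compartment_mm3 = opts$compartment_mm3)
  a <- simulate_case(ph, 3, FALSE, lesion_seed = 2, noise_seed = 9,
                     opts = opts)
  b <- simulate_case(ph, 3, FALSE, lesion_seed = 2, noise_seed = 9,
                     opts = opts)
  expect_identical(a$slab_present$pixels, b$slab_present$pixels)
  expect_identical(a$slab_absent$pixels, b$slab_absent$pixels)
  expect_equal(a$cnr, b$cnr)
})
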