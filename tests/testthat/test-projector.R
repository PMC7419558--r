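test_that("siddon_trace handles axis-aligned and oblique rays exactly", {
  s <- 1
  tr <- siddon_trace(c(-5, 2.5, 2.5), c(15, 2.5, 2.5),
                     origin = c(0, 0, 0), voxel = c(s, s, s),
                     dims = c(10, 5, 5))
  expect_equal(nrow(tr$idx), 10)
  expect_equal(tr$len, rep(s, 10))
  expect_equal(sum(tr$len), 10 * s)
  expect_equal(tr$idx[, 2], rep(3L, 10))
  # entries ordered along the ray
  expect_true(all(diff(tr$idx[, 1]) == 1))

  # 45-degree in-plane ray through a single-voxel-thick grid
  tr2 <- siddon_trace(c(-1, -1, 0.5), c(6, 6, 0.5),
                      origin = c(0, 0, 0), voxel = c(1, 1, 1),
                      dims = c(5, 5, 1))
  expect_equal(sum(tr2$len), 5 * sqrt(2), tolerance = 1e-12)
  expect_true(all(abs(tr2$len[tr2$len > 1e-9] - sqrt(2)) < 1e-9))

  expect_error(siddon_trace(c(1, 1, 1), c(1, 1, 1),
                            c(0, 0, 0), c(1, 1, 1), c(5, 5, 5)),
               "zero-length")
})

test_that("siddon path lengths conserve the analytic box chord", {
  set.seed(7)
  origin <- c(-3, 1, 0); voxel <- c(0.7, 0.4, 1.1); dims <- c(9L, 13L, 6L)
  lo <- origin; hi <- origin + voxel * dims
  for (k in 1:100) {
    a <- lo + (hi - lo) / 2 + runif(3, -30, 30)
    b <- lo + (hi - lo) / 2 + runif(3, -30, 30)
    if (sum((a - b)^2) == 0) next
    tr <- siddon_trace(a, b, origin, voxel, dims)
    expect_equal(sum(tr$len), box_chord_length(a, b, lo, hi),
                 tolerance = 1e-9)
    expect_true(all(tr$len > 0))
  }
})

test_that("noiseless projection obeys Beer-Lambert everywhere", {
  ph <- uniform_phantom(c(30L, 30L, 20L), "fibroglandular", voxel_size = 0.5)
  place <- default_geometry(ph, 1, pitch_mm = 0.5)
  geom <- place$geometry
  pset <- project_noiseless(ph, geom, phantom_origin_mm = place$phantom_origin_mm,
                            spectrum = mono_spectrum(20))
  mu <- unname(mu_matrix(default_material_table(), 20)["fibroglandular", 1])
  img <- pset$images[[1]]
  src <- source_positions(geom)[1, ]
  org <- place$phantom_origin_mm
  lo <- org; hi <- org + 0.5 * c(30, 30, 20)
  nu <- geom$det_shape[1]; nv <- geom$det_shape[2]
  checked <- 0
  for (u in seq(1, nu, by = 5)) {
    for (v in seq(1, nv, by = 5)) {
      det <- c(geom$det_origin_mm[1] + (u - 1) * geom$pitch_mm[1],
               geom$det_origin_mm[2] + (v - 1) * geom$pitch_mm[2], 0)
      chord <- box_chord_length(src, det, lo, hi)
      expect_equal(img[u, v], pset$I0 * exp(-mu * chord),
                   tolerance = 1e-9)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
})

test_that("all-air phantoms give the unattenuated reference and layered
           phantoms multiply exponentials", {
  air <- uniform_phantom(c(16L, 16L, 10L), "air", voxel_size = 0.5)
  place <- default_geometry(air, 1, pitch_mm = 0.5)
  pa <- project_noiseless(air, place$geometry,
                          phantom_origin_mm = place$phantom_origin_mm)
  expect_lt(max(abs(pa$images[[1]] / pa$I0 - 1)), 1e-4)

  # two stacked uniform layers = product of the two exponentials
  two <- uniform_phantom(c(16L, 16L, 10L), "adipose", voxel_size = 0.5)
  two$labels[, , 6:10] <- 2L
  p2 <- project_noiseless(two, place$geometry,
                          phantom_origin_mm = place$phantom_origin_mm)
  lay1 <- uniform_phantom(c(16L, 16L, 5L), "adipose", voxel_size = 0.5)
  lay2 <- uniform_phantom(c(16L, 16L, 5L), "fibroglandular", voxel_size = 0.5)
  o <- place$phantom_origin_mm
  pl1 <- project_noiseless(lay1, place$geometry, phantom_origin_mm = o)
  pl2 <- project_noiseless(lay2, place$geometry,
                           phantom_origin_mm = o + c(0, 0, 2.5))
  prod_att <- (pl1$images[[1]] / pl1$I0) * (pl2$images[[1]] / pl2$I0)
  expect_equal(p2$images[[1]] / p2$I0, prod_att, tolerance = 1e-9)
})

test_that("detector cascade is exact when disabled and statistically sound
           when enabled", {
  geom <- acquisition_geometry(1, det_shape = c(60, 60), pitch_mm = 0.5)
  flat <- matrix(400, 60, 60)
  pset <- structure(list(images = list(flat), I0 = 400, per_energy = NULL,
                         geometry = geom, noise_meta = NULL),
                    class = "projection_set")
  out <- apply_detector(pset, blur_fwhm_mm = 0, gain = 2, electronic_sd = 0,
                        seed = 1, poisson = FALSE)
  expect_equal(out$images[[1]], 2 * flat)

  # Poisson + Gaussian: pixel-ensemble mean and variance on a flat field
  noisy <- apply_detector(pset, blur_fwhm_mm = 0, gain = 1.5,
                          electronic_sd = 7, seed = 2)
  vals <- as.vector(noisy$images[[1]])
  n <- length(vals)
  expect_lt(abs(mean(vals) - 1.5 * 400), 3 * sd(vals) / sqrt(n))
  expected_var <- 1.5^2 * 400 + 7^2
  expect_lt(abs(var(vals) - expected_var) / expected_var, 0.10)

  # seeded determinism
  noisy2 <- apply_detector(pset, blur_fwhm_mm = 0, gain = 1.5,
                           electronic_sd = 7, seed = 2)
  expect_identical(noisy$images, noisy2$images)
  expect_error(apply_detector(pset, gain = 0), "gain")
})

test_that("dose splits evenly and per-view noise scales with P", {
  expect_equal(per_view_exposure(1.5, 3), 0.5)
  expect_equal(per_view_exposure(1.5, 1), 1.5)
  expect_error(per_view_exposure(1.5, 0), "P")
  # monotone per-view fluence in P
  fl <- vapply(c(3, 7, 11, 25, 45), function(p) per_view_exposure(1.5, p),
               numeric(1))
  expect_true(all(diff(fl) < 0))
  # flat-field per-pixel Poisson variance doubles when P doubles
  geom <- acquisition_geometry(1, det_shape = c(70, 70), pitch_mm = 0.5)
  mk <- function(mu) structure(list(images = list(matrix(mu, 70, 70)),
                                    I0 = mu, per_energy = NULL,
                                    geometry = geom, noise_meta = NULL),
                               class = "projection_set")
  v1 <- var(as.vector(apply_detector(mk(800), 0, 1, 0, seed = 3)$images[[1]]))
  v2 <- var(as.vector(apply_detector(mk(400), 0, 1, 0, seed = 4)$images[[1]]))
  expect_equal(v1 / v2, 2, tolerance = 0.15)
})

test_that("projection angles are symmetric and equally spaced", {
  geom <- acquisition_geometry(11, arc_span_deg = 60)
  src <- source_positions(geom)
  ang <- atan2(src[, 1] - geom$rot_center_mm[1],
               src[, 3] - (geom$sdd_mm - geom$scd_mm)) * 180 / pi
  expect_equal(ang, seq(-30, 30, length.out = 11), tolerance = 1e-9)
  expect_equal(source_positions(acquisition_geometry(1))[, 1],
               acquisition_geometry(1)$rot_center_mm[1])
})
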