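test_that("DoG maxima find somata and ignore flat images", {
  cfg <- detector_config(cell_size_um = 10)
  expect_equal(nrow(dog_maxima(matrix(100, 120, 120), cfg)), 0)

  # one rendered soma: exactly one peak within one downsampled pixel
  cells <- data.frame(x_um = 60, y_um = 56, z_um = 12, radius_um = 5,
                      peak = 1200, channel = "red")
  sp <- phantom_spec(c(120, 120, 24), voxel_um = c(1, 1, 3), cells = cells,
                     noise = list(poisson = FALSE, read_sigma = 0))
  v <- render_phantom(sp)$channels$red
  img <- unclass(v)[, , 5]                      # plane through the centre
  pk <- dog_maxima(img, cfg)
  expect_equal(nrow(pk), 1)
  expect_lte(max(abs(c(pk$i - 61, pk$j - 57))), cfg$downsample)

  # two somata separated by > 2 cell sizes: two peaks
  cells2 <- rbind(cells,
                  data.frame(x_um = 60, y_um = 90, z_um = 12, radius_um = 5,
                             peak = 1200, channel = "red"))
  sp2 <- phantom_spec(c(120, 120, 24), voxel_um = c(1, 1, 3), cells = cells2,
                      noise = list(poisson = FALSE, read_sigma = 0))
  img2 <- unclass(render_phantom(sp2)$channels$red)[, , 5]
  expect_equal(nrow(dog_maxima(img2, cfg)), 2)
})

test_that("patch threshold implements the peak/border average", {
  cfg <- detector_config(cell_size_um = 10)
  img <- matrix(100, 60, 60)
  img[31, 31] <- 200
  pt <- patch_threshold(img, c(31, 31), cfg)
  expect_equal(pt$threshold, 150)       # (200 + 100) / 2
  expect_false(pt$clipped)
  # peak at the border level: degenerate
  flat <- matrix(100, 60, 60)
  expect_true(patch_threshold(flat, c(31, 31), cfg)$degenerate)
  # clipped at the image edge
  expect_true(patch_threshold(img, c(2, 31), cfg)$clipped)

  # rendered soma: mask area within 25% of the analytic half-max area
  cells <- data.frame(x_um = 40, y_um = 40, z_um = 6, radius_um = 5,
                      peak = 1200, channel = "red")
  sp <- phantom_spec(c(80, 80, 12), voxel_um = c(1, 1, 3), cells = cells,
                     background_level = 100,
                     noise = list(poisson = FALSE, read_sigma = 0))
  img3 <- unclass(render_phantom(sp)$channels$red)[, , 3]
  pk <- arrayInd(which.max(img3), dim(img3))
  pt3 <- patch_threshold(img3, pk, cfg)
  # Gaussian sigma 2.5: area above half the (background-subtracted) peak
  analytic <- pi * (2.5^2 * 2 * log(2 * 1200 / (1200 - 100)))
  expect_lt(abs(sum(pt3$mask) - analytic) / analytic, 0.25)
})

test_that("seeded watershed splits merged blobs along the valley", {
  # single blob, single seed: the whole mask
  m <- matrix(FALSE, 40, 40); m[15:25, 15:25] <- TRUE
  patch <- matrix(0, 40, 40); patch[15:25, 15:25] <- 500
  lab <- watershed_segment(patch, m, c(20, 20))
  expect_equal(sum(lab == 1), sum(m))

  # two merged Gaussians, two seeds: split areas within 20% of halves
  p2 <- matrix(0, 60, 40)
  for (i in 1:60) for (j in 1:40)
    p2[i, j] <- 900 * exp(-((i - 22)^2 + (j - 20)^2) / 30) +
                900 * exp(-((i - 38)^2 + (j - 20)^2) / 30)
  m2 <- p2 > 200
  lab2 <- watershed_segment(p2, m2, rbind(c(22, 20), c(38, 20)))
  a1 <- sum(lab2 == 1); a2 <- sum(lab2 == 2)
  expect_equal(a1 + a2, sum(m2))
  expect_lt(abs(a1 - a2) / sum(m2), 0.2)

  # seed outside the mask: empty segment
  lab3 <- watershed_segment(patch, m, c(5, 5))
  expect_equal(sum(lab3), 0)
})

test_that("3D linking turns plane segments into sane cell records", {
  # hard sphere of diameter 14 um at 3.5 um plane spacing
  hs <- hard_sphere_volume(radius_um = 7, voxel = c(1, 1, 3.5))
  rec <- detect_cells(hs$vol, detector_config(cell_size_um = 14))
  expect_equal(nrow(rec), 1)
  expect_gte(rec$n_sections, 4)
  expect_lte(rec$n_sections, 5)
  vol_true <- 4 / 3 * pi * 7^3
  expect_lt(abs(rec$volume_um3 - vol_true) / vol_true, 0.2)
  expect_lt(max(abs(c(rec$x_um, rec$y_um, rec$z_um) - hs$centre)), 2.5)

  # two distant cells: two records
  cells <- data.frame(x_um = c(30, 90), y_um = c(30, 90), z_um = c(24, 48),
                      radius_um = 5, peak = 1200, channel = "red")
  sp <- phantom_spec(c(120, 120, 72), voxel_um = c(1, 1, 3), cells = cells,
                     noise = list(poisson = FALSE, read_sigma = 0))
  r2 <- detect_cells(render_phantom(sp)$channels$red,
                     detector_config(cell_size_um = 10))
  expect_equal(nrow(r2), 2)

  # a single-plane speck fails the volume validation
  speck <- array(100, c(80, 80, 10))
  speck[40:42, 40:42, 5] <- 1500
  r3 <- detect_cells(vol3d(speck, c(1, 1, 3)),
                     detector_config(cell_size_um = 10))
  if (nrow(r3)) expect_false(any(r3$valid))
})

test_that("validation windows work and detection is gain-invariant", {
  cfg <- detector_config(volume_range_um3 = c(100, 4000),
                         eccentricity_range = c(0, 0.95),
                         intensity_range = c(0, Inf))
  recs <- data.frame(id = 1:3,
                     x_um = 0, y_um = 0, z_um = 0,
                     volume_um3 = c(500, 50, 500),
                     eccentricity = c(0.5, 0.5, 0.99),
                     intensity = c(300, 300, 300),
                     n_sections = 3L, clipped = FALSE)
  v <- validate_cells(recs, cfg)
  expect_equal(v$valid, c(TRUE, FALSE, FALSE))

  # global gain leaves the detected count unchanged (threshold formula
  # and DoG floor are gain-equivariant)
  sp <- soma_phantom(n_cells = 40, seed = 5)
  ph <- render_phantom(sp)
  v1 <- ph$channels$red
  v2 <- vol3d(unclass(v1) * 3, voxel_of(v1))
  n1 <- nrow(detect_cells(v1, detector_config()))
  n2 <- nrow(detect_cells(v2, detector_config()))
  expect_equal(n1, n2)
  expect_equal(n1, 40)
})

test_that("colocalization pairs mutual nearest neighbours only", {
  mk <- function(xyz) data.frame(x_um = xyz[, 1], y_um = xyz[, 2],
                                 z_um = xyz[, 3])
  set.seed(10)
  A <- cbind(runif(50, 0, 400), runif(50, 0, 400), runif(50, 0, 100))
  # identical coordinates: all paired
  cl <- colocalize(mk(A), mk(A), radius_um = 5)
  expect_equal(cl$n_double, 50)
  # disjoint far sets: none paired
  B <- A + 600
  expect_equal(colocalize(mk(A), mk(B), radius_um = 5)$n_double, 0)
  # known overlap fraction recovered from generator truth
  res <- dual_channel_recovery(render_phantom(
    mea_phantom(n_red = 120, n_green = 120, n_double = 60, seed = 2)),
    radius_um = 5)
  expect_equal(res$n_double / res$n_red, 0.5, tolerance = 0.03)
})

test_that("atlas downscaling and affine refinement behave", {
  v <- vol3d(array(7, c(50, 50, 50)), c(1, 1, 1))
  d <- downscale_for_atlas(v, 25)
  expect_equal(dim(d), c(2, 2, 2))
  expect_true(all(abs(unclass(d) - 7) < 1e-12))
  expect_equal(voxel_of(d), c(25, 25, 25))

  recs <- data.frame(x_um = c(1, 2), y_um = c(3, 4), z_um = c(5, 6))
  idm <- cbind(diag(3), 0)
  expect_equal(apply_affine(recs, idm), recs)
  tr <- cbind(diag(3), c(10, -5, 2))
  out <- apply_affine(recs, tr)
  expect_equal(out$x_um, recs$x_um + 10)
  expect_equal(out$y_um, recs$y_um - 5)
  expect_equal(out$z_um, recs$z_um + 2)
  expect_error(apply_affine(recs, cbind(matrix(0, 3, 3), 1)), "singular")
})
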