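test_that("phantom rendering is deterministic and validates its inputs", {
  # empty spec: constant background
  sp <- phantom_spec(c(40, 40, 24), background_level = 80,
                     noise = list(poisson = FALSE, read_sigma = 0))
  ph <- render_phantom(sp)
  expect_true(all(ph$channels$red == 80))

  # one noiseless cell: intensity argmax at the centre (+-1 voxel)
  cells <- data.frame(x_um = 20, y_um = 18, z_um = 12, radius_um = 5,
                      peak = 1000, channel = "red")
  sp1 <- phantom_spec(c(40, 40, 24), voxel_um = c(1, 1, 3), cells = cells,
                      noise = list(poisson = FALSE, read_sigma = 0))
  v <- render_phantom(sp1)$channels$red
  am <- arrayInd(which.max(v), dim(v))
  expect_lte(max(abs((am - 1) * c(1, 1, 3) - c(20, 18, 12))), 3)

  # bookkeeping: N seeded cells recorded exactly
  sp50 <- soma_phantom(n_cells = 50, seed = 3)
  ph50 <- render_phantom(sp50)
  expect_equal(nrow(ph50$truth$cells), 50)

  # same seed => bit-identical volumes (with noise on)
  a <- render_phantom(pvn_phantom(n_red = 30, n_green = 10, n_double = 10,
                                  seed = 9))
  b <- render_phantom(pvn_phantom(n_red = 30, n_green = 10, n_double = 10,
                                  seed = 9))
  expect_identical(unclass(a$channels$red), unclass(b$channels$red))
  expect_identical(unclass(a$channels$green), unclass(b$channels$green))

  # invalid specs rejected
  bad <- data.frame(x_um = 99, y_um = 0, z_um = 0, radius_um = 5,
                    peak = 1, channel = "red")
  expect_error(phantom_spec(c(40, 40, 24), cells = bad), "outside")
})

test_that("lattice placement guarantees the minimum separation", {
  set.seed(7)
  p <- place_cells_lattice(200, c(10, 10, 10), c(290, 290, 120),
                           pitch_um = 22, jitter_um = 2)
  expect_equal(nrow(p), 200)
  dmin <- min(dist(p))
  expect_gte(dmin, 18)
  expect_error(place_cells_lattice(1e6, c(0, 0, 0), c(100, 100, 100)),
               "sites")
})

test_that("synchronized acquisition round-trips the phantom volume", {
  bv <- bead_volume(seed = 1)
  g <- test_geometry()
  cols <- simulate_acquisition(bv$vol, g, overlap = 0.10)
  expect_gte(length(cols), 1)
  v1 <- stack_column(cols[[1]], axial_step_um = 1)
  pts <- as.matrix(expand.grid(x = 10:110, y = 5:75, z = 10:50))
  ref <- interp_trilinear(bv$vol, pts)
  got <- interp_trilinear(v1, pts)
  psnr <- 10 * log10(max(ref)^2 / mean((ref - got)^2))
  expect_gt(psnr, 40)
  # photon conservation within interpolation error
  expect_lt(abs(sum(got) / sum(ref) - 1), 0.01)
})

test_that("a stationary stage yields identical frames", {
  bv <- bead_volume(dims = c(60, 60, 40), n_beads = 5, seed = 2)
  g <- test_geometry(frame_shape = c(100L, 100L))
  cols <- simulate_acquisition(bv$vol, g, frame_step_um = 0, n_frames = 4L)
  fr <- cols[[1]]$frames
  for (f in 2:4) expect_identical(fr[f, , ], fr[1, , ])
})

test_that("unsynchronized mode smears frames along the scan axis", {
  bv <- bead_volume(dims = c(120, 60, 50), n_beads = 1, sigma2 = 4,
                    peak = 5000, background = 0, seed = 4)
  g <- test_geometry(frame_shape = c(140L, 100L),
                     stage_speed_um_s = 1000)   # 5 um travel per frame
  sync <- simulate_acquisition(bv$vol, g, mode = "synchronized")
  unsync <- simulate_acquisition(bv$vol, g, mode = "unsynchronized")
  vs <- stack_column(sync[[1]], axial_step_um = 1)
  vu <- stack_column(unsync[[1]], axial_step_um = 1)
  # second moment along x of the deskewed bead broadens by ~ the box
  # kernel variance (frame travel^2 / 12)
  spread_x <- function(v) {
    a <- pmax(unclass(v), 0)
    xs <- (seq_len(dim(a)[1]) - 1) * attr(v, "voxel_um")[1]
    w <- apply(a, 1, sum)
    mu <- sum(xs * w) / sum(w)
    sum((xs - mu)^2 * w) / sum(w)
  }
  broadening <- spread_x(vu) - spread_x(vs)
  expect_gt(broadening, 0.5 * 5^2 / 12)
  expect_lt(broadening, 2.0 * 5^2 / 12)
  # blur extent matches the geometry calculator
  expect_equal(motion_blur_extent(g = g, mode = "unsynchronized"), 5)
})

test_that("cutting into slices preserves content and counts", {
  bv <- bead_volume(dims = c(80, 80, 60), n_beads = 8, seed = 3)
  # amplitude 0: slices concatenate back exactly
  sl0 <- cut_and_deform_slices(bv$vol, slice_thickness_um = 20,
                               deform_amplitude_um = 0, seed = 1)
  expect_equal(length(sl0$slices), 3)
  back <- array(0, dim(bv$vol))
  k0 <- 0
  for (s in seq_along(sl0$slices)) {
    nz <- dim(sl0$slices[[s]])[3]
    back[, , (k0 + 1):(k0 + nz)] <- unclass(sl0$slices[[s]])
    k0 <- k0 + nz
  }
  expect_identical(back, array(as.numeric(bv$vol), dim(bv$vol)))
  # 1500-um phantom at 300 um -> 5 slices
  vol5 <- vol3d(array(0, c(4, 4, 500)), c(1, 1, 3))
  expect_equal(length(cut_and_deform_slices(vol5, slice_thickness_um = 300,
                                            deform_amplitude_um = 0)$slices), 5)
  # thickness > depth -> single slice
  expect_equal(length(cut_and_deform_slices(bv$vol, slice_thickness_um = 500,
                                            deform_amplitude_um = 0)$slices), 1)
})

test_that("recorded deformation fields invert to sub-0.5-um residuals", {
  bv <- bead_volume(dims = c(80, 80, 60), n_beads = 4, seed = 6)
  sl <- cut_and_deform_slices(bv$vol, slice_thickness_um = 200,
                              deform_amplitude_um = 6, seed = 2)
  set.seed(8)
  pts <- cbind(runif(200, 10, 70), runif(200, 10, 70))
  q <- deform_points(sl$fields[[1]], pts)
  p_back <- undeform_points(sl$fields[[1]], q)
  expect_lt(max(sqrt(rowSums((p_back - pts)^2))), 0.5)
  # deformation actually moved the points
  expect_gt(mean(sqrt(rowSums((q - pts)^2))), 1)
})
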