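test_that("surface planes are recovered from tilted slabs", {
  # constructed tilt a = 0.01, b = -0.02 (um height per um in x / y)
  dims <- c(80, 80, 40); vx <- c(1, 1, 1)
  a <- array(0, dims)
  for (i in 1:80) for (j in 1:80) {
    z0 <- 8 + 0.01 * i - 0.02 * j
    ks <- ceiling(z0):(ceiling(z0) + 20)
    a[i, j, ks] <- 600
  }
  sl <- vol3d(a, vx)
  sm <- fit_surface(sl, "low")
  expect_lt(abs(sm$coef[1] - 0.01), 1e-3 + 0.02)  # quantized surface
  expect_lt(abs(sm$coef[2] + 0.02), 1e-3 + 0.02)
  # sub-voxel accuracy is limited by z quantization; the plane must
  # still predict the height map to half a voxel rms
  expect_lt(sqrt(mean(sm$residual_map^2, na.rm = TRUE)), 0.5 * vx[3] + 0.3)

  # already-flat slab: a = b = 0, c = surface level
  flat <- array(0, c(40, 40, 30)); flat[, , 10:25] <- 500
  smf <- fit_surface(vol3d(flat, c(1, 1, 1)), "low")
  expect_equal(unname(smf$coef[1:2]), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(smf$coef[3]), 9, tolerance = 1e-6)

  # masked hole leaves the fit unchanged
  mask <- matrix(FALSE, 40, 40); mask[15:25, 15:25] <- TRUE
  smm <- fit_surface(vol3d(flat, c(1, 1, 1)), "low", mask = mask)
  expect_equal(smm$coef, smf$coef, tolerance = 1e-9)
  # fewer than 3 columns crossing the threshold: error
  expect_error(fit_surface(vol3d(array(0, c(6, 6, 6)), c(1, 1, 1)), "low",
                           threshold = 100), "support")
})

test_that("flattening brings tilted faces to constant planes", {
  # flat input: identity
  flat <- array(0, c(30, 30, 24)); flat[, , 6:18] <- 700
  v <- vol3d(flat, c(1, 1, 1))
  out <- flatten_slice(v, fit_surface(v, "high"), fit_surface(v, "low"))
  expect_equal(array(as.numeric(out), dim(out)), flat, tolerance = 1e-9)

  # tilted slab with an embedded bead sheet: bead z constant after
  dims <- c(60, 60, 40)
  a <- array(0, dims)
  tilt <- function(i, j) 6 + 0.15 * i
  for (i in 1:60) for (j in 1:60) {
    z0 <- tilt(i, j)
    ks <- round(z0):(round(z0) + 20)
    a[i, j, ks] <- 400
    a[i, j, round(z0) + 10] <- 2000       # marker sheet mid-slab
  }
  v2 <- vol3d(a, c(1, 1, 1))
  # explicit tissue threshold: the bright marker sheet would otherwise
  # dominate an automatic bimodal split
  f2 <- flatten_slice(v2, fit_surface(v2, "high", threshold = 200),
                      fit_surface(v2, "low", threshold = 200))
  zpk <- apply(unclass(f2)[10:50, 10:50, ], c(1, 2), which.max)
  expect_lte(diff(range(zpk)), 2)         # within one voxel of constant
  # mass conserved within 1%
  expect_lt(abs(sum(f2) / sum(a) - 1), 0.01)
})

test_that("block matching recovers translations and smooth warps", {
  set.seed(6)
  img <- matrix(100, 200, 200)
  for (r in 1:80) {
    c0 <- sample(20:180, 2)
    for (dx in -5:5) for (dy in -5:5)
      img[c0[1] + dx, c0[2] + dy] <-
        img[c0[1] + dx, c0[2] + dy] + runif(1, 400, 900) * exp(-(dx^2 + dy^2) / 8)
  }
  # identical faces: zero displacement
  s0 <- extract_correspondences(img, img, grid_step_um = 20)
  expect_gt(nrow(s0), 10)
  # integer part exact; sub-pixel refinement may add < 1/4 px on the
  # asymmetric NCC surface
  expect_lt(max(abs(c(s0$xb - s0$xa, s0$yb - s0$ya))), 0.25)
  expect_true(all(s0$confidence > 0.99))

  # 4-um translation: median displacement 4 +- 0.5
  fb <- matrix(100, 200, 200); fb[1:196, ] <- img[5:200, ]
  s4 <- extract_correspondences(img, fb, grid_step_um = 16, search_um = 8)
  expect_lt(abs(stats::median(s4$xb - s4$xa) + 4), 0.5)
  expect_lt(abs(stats::median(s4$yb - s4$ya)), 0.5)

  # known smooth warp: endpoint error below 20% of the amplitude
  set.seed(7)
  fld <- visor:::random_sin_field(200, 200, c(1, 1), 6)
  fw <- visor:::warp_plane(img, fld)
  sw <- extract_correspondences(img, fw, grid_step_um = 14, search_um = 10)
  sw <- sw[sw$confidence > 0.6, ]
  # where did each source point actually go?
  tru <- deform_points(fld, cbind(sw$xa, sw$ya))
  err <- sqrt((sw$xb - tru[, 1])^2 + (sw$yb - tru[, 2])^2)
  expect_lt(stats::median(err), 0.2 * 6)

  # textureless faces: empty set with warning
  expect_warning(e <- extract_correspondences(matrix(5, 80, 80),
                                              matrix(5, 80, 80)),
                 "textureless")
  expect_equal(nrow(e), 0)
})

test_that("joint adjustment shrinks outliers and is contractive", {
  # zero displacements stay zero
  z <- data.frame(xa = runif(20, 0, 100), ya = runif(20, 0, 100),
                  xb = NA, yb = NA, confidence = 1)
  z$xb <- z$xa; z$yb <- z$ya
  az <- adjust_correspondences(list(z))[[1]]
  expect_lt(max(abs(c(az$xb - az$xa, az$yb - az$ya))), 1e-9)

  # single outlier among consistent neighbours: verified against a
  # closed-form dense solve of the same quadratic objective
  set.seed(9)
  n <- 25
  s <- data.frame(xa = as.vector(outer(seq(0, 80, 20), rep(1, 5))),
                  ya = as.vector(outer(rep(1, 5), seq(0, 80, 20))),
                  confidence = 1)
  s$xb <- s$xa + 2; s$yb <- s$ya           # uniform field dx = 2
  s$xb[13] <- s$xa[13] + 12                # central outlier
  adj <- adjust_correspondences(list(s), lambda_smooth = 1,
                                lambda_small = 0.1, k = 4)[[1]]
  d13 <- adj$xb[13] - adj$xa[13]
  expect_lt(d13, 9)                        # pulled toward the field
  expect_gt(d13, 2)
  # smoothing is contractive in the first-difference seminorm
  tv <- function(d) sum(diff(sort(d))^2)
  expect_lte(sum((adj$xb - adj$xa - mean(adj$xb - adj$xa))^2),
             sum((s$xb - s$xa - mean(s$xb - s$xa))^2) + 1e-9)

  # lambda_small -> infinity kills all displacements
  ainf <- adjust_correspondences(list(s), lambda_smooth = 0,
                                 lambda_small = 1e9)[[1]]
  expect_lt(max(abs(ainf$xb - ainf$xa)), 1e-5)
})

test_that("similarity MLS reproduces similarity transforms exactly", {
  set.seed(3)
  p <- matrix(runif(24, 0, 100), ncol = 2)
  th <- 0.4; sc <- 1.15
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  tr <- c(7, -2)
  q <- t(sc * R %*% t(p)) + rep(tr, each = nrow(p))
  v <- matrix(runif(600, -20, 120), ncol = 2)
  got <- mls_transform(v, p, q)
  want <- t(sc * R %*% t(v)) + rep(tr, each = nrow(v))
  expect_lt(max(abs(got - want)), 0.1)
  expect_lt(max(abs(got - want)), 1e-9)    # exact, not merely close

  # single control point: global translation
  g1 <- mls_transform(v, matrix(c(10, 10), 1), matrix(c(15, 12), 1))
  expect_equal(g1, v + rep(c(5, 2), each = nrow(v)))

  # control points map exactly to their targets
  gp <- mls_transform(p, p, q)
  expect_lt(max(abs(gp - q)), 1e-9)

  # coincident conflicting controls rejected
  expect_error(mls_transform(v, rbind(c(1, 1), c(1, 1)),
                             rbind(c(2, 2), c(9, 9))), "conflicting")

  # zero displacement on an image: identity
  img <- matrix(runif(64 * 64), 64)
  expect_identical(mls_warp(img, matrix(c(30, 30), 1), matrix(c(0, 0), 1)),
                   img)
})

test_that("reconstruction is the identity on undeformed stacks", {
  bv <- bead_volume(dims = c(80, 80, 48), n_beads = 10, seed = 12)
  sl <- cut_and_deform_slices(bv$vol, slice_thickness_um = 16,
                              deform_amplitude_um = 0, seed = 1)
  rec <- reconstruct_brain(sl)
  expect_equal(dim(rec$volume), dim(bv$vol))
  expect_lt(max(abs(unclass(rec$volume) - unclass(bv$vol))), 1e-6)
})
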